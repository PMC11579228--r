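two_group_df <- function(a, b, labels = c("male", "female")) {
  tibble::tibble(value = c(a, b),
                 group = factor(rep(labels, c(length(a), length(b))),
                                levels = labels))
}

test_that("pooled t-test matches the closed form and stats::t.test", {
  df <- two_group_df(c(1, 2, 3), c(1, 2, 3))
  res <- pooled_t_test(df, value, group)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 4)

  df2 <- two_group_df(c(1, 2, 3), c(101, 102, 103))
  res2 <- pooled_t_test(df2, value, group)
  expect_lt(res2$statistic, 0)         # first group mean is lower
  expect_lt(res2$p_value, 1e-6)

  set.seed(11)
  for (rep in 1:5) {
    a <- stats::rnorm(20); b <- stats::rnorm(25, 0.3)
    df3 <- two_group_df(a, b)
    res3 <- pooled_t_test(df3, value, group)
    # summary-statistic closed form
    sp <- sqrt(((19) * stats::var(a) + (24) * stats::var(b)) / 43)
    t_manual <- (mean(a) - mean(b)) / (sp * sqrt(1 / 20 + 1 / 25))
    expect_equal(res3$statistic, t_manual, tolerance = 1e-12)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(res3$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res3$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(res3$df, 43)
  }
  expect_error(pooled_t_test(two_group_df(c(1, 1), c(1, 1)), value, group),
               "pooled variance")
})

test_that("chi-squared on any 2x2 equals the algebraic closed form", {
  set.seed(12)
  for (rep in 1:10) {
    m <- matrix(sample(1:60, 4), 2)
    res <- chisq_test(m)
    a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
    n <- sum(m)
    expected <- n * (a * d - b * cc)^2 /
      ((a + b) * (cc + d) * (a + cc) * (b + d))
    expect_equal(res$statistic, expected, tolerance = 1e-12)
    expect_equal(res$df, 1)
  }
})

test_that("chi-squared drops all-zero categories and applies no correction", {
  # all-zero first column: df falls to (2-1)(2-1) = 1
  tab <- tibble::tibble(sex = c("male", "female"),
                        non_interoceptive = c(0L, 0L),
                        unclassified = c(76L, 94L),
                        interoceptive = c(27L, 69L))
  res <- chisq_test(tab)
  expect_equal(res$df, 1)
  expect_equal(res$n, 266)
  # identical row proportions: exactly zero
  res0 <- chisq_test(matrix(c(10, 20, 30, 20, 40, 60), 2, byrow = TRUE))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$df, 2)
  expect_error(chisq_test(matrix(c(5, 0, 7, 0), 2)), "2x2")
  expect_error(chisq_test(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("rank-sum Z agrees with an exhaustive permutation oracle", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  b <- c(2.8, 6.3, 4.4, 7.0)
  df <- two_group_df(a, b)
  res <- rank_sum_test(df, value, group)
  # exact permutation distribution of U for n=4/4, no ties
  pooled <- c(a, b)
  combos <- utils::combn(8, 4)
  u_all <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - 4 * 5 / 2
  })
  u_obs <- sum(rank(pooled)[1:4]) - 10
  p_exact <- mean(abs(u_all - 8) >= abs(u_obs - 8))  # center n1*n2/2 = 8
  expect_equal(res$u, u_obs)
  # normal approximation and exact p agree in order of magnitude and side
  expect_lt(abs(res$p_value - p_exact), 0.08)
  expect_equal(res$z_signed < 0, u_obs < 8)

  # literally identical samples: Z = 0
  same <- two_group_df(c(1, 2, 3), c(1, 2, 3))
  expect_equal(rank_sum_test(same, value, group)$statistic, 0)

  # translation invariance
  shifted <- two_group_df(a + 100, b + 100)
  res_sh <- rank_sum_test(shifted, value, group)
  expect_equal(res_sh$u, res$u)
  expect_equal(res_sh$z_signed, res$z_signed)

  expect_error(rank_sum_test(two_group_df(c(2, 2), c(2, 2)), value, group),
               "tied")
})

test_that("rank-sum tie correction matches wilcox.test's normal approximation", {
  set.seed(13)
  a <- sample(1:6, 15, replace = TRUE)
  b <- sample(2:8, 12, replace = TRUE)
  df <- two_group_df(a, b)
  res <- rank_sum_test(df, value, group)
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = FALSE))
  expect_equal(res$u, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("spearman correlation uses mid-ranks and the t approximation", {
  df <- tibble::tibble(x = 1:10, y = (1:10)^3)
  expect_equal(spearman_test(df, x, y)$estimate, 1)
  df_rev <- tibble::tibble(x = 1:10, y = rev(1:10))
  expect_equal(spearman_test(df_rev, x, y)$estimate, -1)

  # tied example against brute-force mid-rank Pearson
  xv <- c(1, 2, 2, 4, 5, 5, 5, 8)
  yv <- c(3, 1, 4, 4, 6, 2, 7, 7)
  df_t <- tibble::tibble(x = xv, y = yv)
  res <- spearman_test(df_t, x, y)
  rx <- rank(xv); ry <- rank(yv)
  rho_manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(res$estimate, rho_manual, tolerance = 1e-12)
  ref <- suppressWarnings(stats::cor.test(xv, yv, method = "spearman",
                                          exact = FALSE))
  expect_equal(res$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(res$df, 6)

  expect_error(spearman_test(tibble::tibble(x = c(1, 1, 1), y = 1:3), x, y),
               "constant")
})

test_that("residualization satisfies the OLS normal equations", {
  set.seed(14)
  n <- 60
  df <- tibble::tibble(
    y = stats::rnorm(n), c1 = stats::rnorm(n), c2 = stats::rnorm(n),
    group = rep(c("male", "female"), n / 2)
  )
  res <- residualize(df, y, c("c1", "c2"))
  expect_equal(mean(res$.resid), 0, tolerance = 1e-12)
  expect_equal(sum(res$.resid * res$c1), 0, tolerance = 1e-8)
  expect_equal(sum(res$.resid * res$c2), 0, tolerance = 1e-8)

  # covariate orthogonal to centered y: residuals are just y - mean(y)
  df2 <- tibble::tibble(y = c(1, 2, 3, 4), z = c(1, -1, -1, 1))
  r2 <- residualize(df2, y, "z")
  expect_equal(r2$.resid, df2$y - mean(df2$y), tolerance = 1e-12)

  expect_error(residualize(dplyr::mutate(df, c3 = c1), y, c("c1", "c3")),
               "collinear")
})

test_that("residual t-test is calibrated under a null sex split", {
  set.seed(15)
  reps <- 400
  p <- vapply(seq_len(reps), function(i) {
    n <- 80
    hr <- stats::rnorm(n, 75, 8)
    df <- tibble::tibble(
      y = 2 * hr + stats::rnorm(n, 0, 5),
      hr = hr,
      sex = sample(rep(c("male", "female"), n / 2))
    )
    res <- residualize(df, y, "hr")
    pooled_t_test(res, .resid, sex)$p_value
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("one-way ANOVA matches the SS decomposition and t^2 at k = 2", {
  df0 <- tibble::tibble(value = rep(c(5, 5, 5, 5), 4),
                        group = rep(letters[1:4], each = 4) |> factor())
  df0$value <- df0$value + rep(c(0.1, -0.1), 8)   # identical groups
  expect_equal(oneway_anova(df0, value, group)$statistic, 0, tolerance = 1e-12)

  set.seed(16)
  df <- tibble::tibble(value = stats::rnorm(40),
                       group = factor(rep(1:4, each = 10)))
  res <- oneway_anova(df, value, group)
  ref <- stats::oneway.test(value ~ group, data = df, var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(res$df1, 3)
  expect_equal(res$df2, 36)

  df2 <- two_group_df(stats::rnorm(12), stats::rnorm(15, 0.4))
  f <- oneway_anova(df2, value, group)$statistic
  t_ <- pooled_t_test(df2, value, group)$statistic
  expect_equal(f, t_^2, tolerance = 1e-10)
})

test_that("analytic power behaves at the null limit and against power.t.test", {
  expect_lt(abs(power_two_sample(1e-10, 50, 50) - 0.05), 1e-6)
  # equal-n case cross-checked against stats::power.t.test
  # power.t.test drops the opposite-tail term (~1e-6 here)
  ref <- stats::power.t.test(n = 60, delta = 0.5, sd = 1, sig.level = 0.05)
  expect_equal(power_two_sample(0.5, 60, 60), ref$power, tolerance = 1e-5)
  expect_error(power_two_sample(0.5, 50, 50, alpha = 1.2), "alpha")
  # monotone in n and d
  expect_gt(power_two_sample(0.5, 100, 100), power_two_sample(0.5, 50, 50))
  expect_gt(power_two_sample(0.8, 50, 50), power_two_sample(0.5, 50, 50))
})

test_that("tests are invariant to group-label swap up to the statistic's sign", {
  set.seed(17)
  a <- stats::rnorm(15); b <- stats::rnorm(18, 0.5)
  d1 <- two_group_df(a, b)
  d2 <- two_group_df(b, a, labels = c("female", "male"))
  t1 <- pooled_t_test(d1, value, group); t2 <- pooled_t_test(d2, value, group)
  expect_equal(t1$statistic, -t2$statistic, tolerance = 1e-12)
  expect_equal(t1$p_value, t2$p_value, tolerance = 1e-12)
  r1 <- rank_sum_test(d1, value, group); r2 <- rank_sum_test(d2, value, group)
  expect_equal(r1$z_signed, -r2$z_signed, tolerance = 1e-12)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
})
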