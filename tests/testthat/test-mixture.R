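test_that("EM recovers the generating parameters of a clear mixture", {
  set.seed(101)
  scores <- simulate_scores(1000)
  fit <- fit_gmm2(scores, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$means[1] - 0.22), 0.02)
  expect_lt(abs(fit$means[2] - 0.55), 0.02)
  expect_lt(abs(fit$weights[1] - 0.55), 0.05)
  expect_equal(sum(fit$weights), 1)
  expect_equal(fit$components, c("non_interoceptive", "interoceptive"))
  expect_true(fit$means[2] > fit$means[1])
})

test_that("EM log-likelihood trace is monotone non-decreasing", {
  set.seed(102)
  for (rep in 1:5) {
    fit <- fit_gmm2(simulate_scores(200), seed = rep)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("mirroring the data mirrors the component means and swaps labels", {
  set.seed(103)
  x <- simulate_scores(500)
  f1 <- fit_gmm2(x, seed = 9)
  f2 <- fit_gmm2(1 - x, seed = 9)
  expect_equal(sort(f2$means), sort(1 - f1$means), tolerance = 1e-3)
  expect_equal(f2$sds[c(2, 1)], f1$sds, tolerance = 1e-3)
  expect_equal(f2$weights[c(2, 1)], f1$weights, tolerance = 1e-3)
})

test_that("the fit is deterministic given scores, seed and config", {
  set.seed(104)
  x <- simulate_scores(300)
  expect_identical(fit_gmm2(x, seed = 5), fit_gmm2(x, seed = 5))
})

test_that("fit_gmm2 agrees with an independent EM implementation (mclust)", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")   # Mclust needs its namespace attached
  set.seed(105)
  x <- simulate_scores(800)
  fit <- fit_gmm2(x, seed = 2)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$means, sort(unname(mc$parameters$mean)), tolerance = 0.01)
  expect_equal(fit$log_likelihood, mc$loglik, tolerance = 1e-3)
})

test_that("degenerate and tiny inputs are rejected", {
  expect_error(fit_gmm2(rep(0.4, 50)), "degenerate")
  expect_error(fit_gmm2(stats::runif(10)), "at least 20")
})

test_that("belonging z-scores and tail probabilities match the normal law", {
  fit <- structure(list(components = c("non_interoceptive", "interoceptive"),
                        weights = c(0.5, 0.5), means = c(0.2, 0.6),
                        sds = c(0.1, 0.1)), class = "pat_gmm")
  # at the interoceptive mean: z = 0, tail p = 1
  b <- belonging(0.6, fit)
  expect_equal(b$z_interoceptive, 0)
  expect_equal(b$p_interoceptive, 1)
  expect_equal(b$z_non_interoceptive, 4)
  expect_equal(b$p_non_interoceptive, 2 * stats::pnorm(-4))
  cls <- classify(b)
  expect_equal(cls$bayes_factor, 1 / (2 * stats::pnorm(-4)))
  expect_lt(abs(cls$bayes_factor - 1.58e4), 0.02e4)
  expect_equal(cls$direction, "interoceptive")

  # equidistant score: BF exactly 1, unclassified everywhere
  cls_mid <- classify(belonging(0.4, fit))
  expect_equal(cls_mid$bayes_factor, 1)
  expect_equal(cls_mid$label_bf3, "unclassified")

  # posterior method includes weights and sums to one
  fit$weights <- c(0.8, 0.2)
  bp <- belonging(0.4, fit, method = "posterior")
  expect_equal(bp$p_interoceptive + bp$p_non_interoceptive, 1)
  expect_equal(bp$p_interoceptive / bp$p_non_interoceptive, 0.25)
})

test_that("labels bracket the thresholds with strict inequalities", {
  lab <- function(p_int, p_non) {
    classify(tibble::tibble(p_interoceptive = p_int,
                            p_non_interoceptive = p_non))
  }
  c1 <- lab(0.29, 0.1)    # BF = 2.9
  expect_equal(unlist(c1[, c("label_bf3", "label_bf10", "label_bf30")],
                      use.names = FALSE),
               rep("unclassified", 3))
  c2 <- lab(1.2e-3, 1e-4) # BF = 12
  expect_equal(c2$label_bf3, "interoceptive")
  expect_equal(c2$label_bf10, "interoceptive")
  expect_equal(c2$label_bf30, "unclassified")
  c3 <- lab(0.1, 3)       # BF = 30 exactly: strict bound fails
  expect_equal(c3$bayes_factor, 30)
  expect_equal(c3$label_bf30, "unclassified")
  expect_equal(c3$label_bf10, "non_interoceptive")
})

test_that("tail-method Bayes factor grows with distance from the midpoint", {
  fit <- structure(list(components = c("non_interoceptive", "interoceptive"),
                        weights = c(0.5, 0.5), means = c(0.2, 0.6),
                        sds = c(0.1, 0.1)), class = "pat_gmm")
  grid <- seq(0.4, 0.9, by = 0.01)
  bf <- classify(belonging(grid, fit))$bayes_factor
  expect_true(all(diff(bf) > 0))
})

test_that("label nesting holds across a fitted cohort", {
  set.seed(106)
  x <- simulate_scores(400)
  cls <- classify(belonging(x, fit_gmm2(x, seed = 3)))
  classified30 <- cls$label_bf30 != "unclassified"
  expect_true(all(cls$label_bf10[classified30] == cls$label_bf30[classified30]))
  classified10 <- cls$label_bf10 != "unclassified"
  expect_true(all(cls$label_bf3[classified10] == cls$label_bf10[classified10]))
})

test_that("classification_table tallies sex by label with full marginals", {
  labels <- c("interoceptive", "unclassified", "unclassified",
              "non_interoceptive", "interoceptive")
  sex <- c("male", "male", "female", "female", "female")
  tab <- classification_table(labels, sex)
  expect_equal(tab$sex, c("male", "female"))
  expect_equal(tab$non_interoceptive, c(0, 1))
  expect_equal(tab$unclassified, c(1, 1))
  expect_equal(tab$interoceptive, c(1, 1))
  expect_equal(sum(tab[, -1]), length(labels))
  expect_error(classification_table(labels, sex[-1]), "aligned")

  # brute-force tally on a simulated cohort
  set.seed(107)
  lab <- sample(c("non_interoceptive", "unclassified", "interoceptive"),
                200, replace = TRUE)
  sx <- sample(c("male", "female"), 200, replace = TRUE)
  tab2 <- classification_table(lab, sx)
  for (i in 1:2) {
    for (lv in c("non_interoceptive", "unclassified", "interoceptive")) {
      expect_equal(tab2[[lv]][i], sum(lab == lv & sx == tab2$sex[i]))
    }
  }
})

test_that("tidy and glance summarise a fit broom-style", {
  set.seed(108)
  fit <- fit_gmm2(simulate_scores(200), seed = 4)
  td <- tidy(fit)
  expect_equal(names(td), c("component", "weight", "mean", "sd"))
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_equal(gl$n, 200)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
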