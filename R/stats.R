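#' Two-sample Student t-test with pooled variance
#'
#' Classical pooled-variance (equal-variance) independent-samples t-test
#' with `df = n_a + n_b - 2` and a two-tailed p-value, as used for the
#' consistency and confidence comparisons.
#'
#' @param data A data frame.
#' @param value <[`data-masking`][rlang::args_data_masking]> Numeric outcome
#'   column.
#' @param by <[`data-masking`][rlang::args_data_masking]> Two-level grouping
#'   column.
#' @return One-row tibble: `test`, `statistic` (t, group 1 minus group 2 in
#'   the factor order of `by`), `df`, `p_value`, plus per-group `n`, `mean`,
#'   `sd` and the group labels.
#' @export
pooled_t_test <- function(data, value, by) {
  g <- two_groups(data, {{ value }}, {{ by }})
  n1 <- length(g$a); n2 <- length(g$b)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(g$a) + (n2 - 1) * stats::var(g$b)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_stat <- (mean(g$a) - mean(g$b)) / se
  df <- n1 + n2 - 2
  tibble::tibble(
    test = "pooled_t", statistic = t_stat, df = df,
    p_value = 2 * stats::pt(-abs(t_stat), df),
    group_a = g$labels[1], group_b = g$labels[2],
    n_a = n1, n_b = n2,
    mean_a = mean(g$a), mean_b = mean(g$b),
    sd_a = stats::sd(g$a), sd_b = stats::sd(g$b)
  )
}

two_groups <- function(data, value, by) {
  v <- dplyr::pull(data, {{ value }})
  grp <- dplyr::pull(data, {{ by }})
  keep <- !is.na(v) & !is.na(grp)
  v <- v[keep]; grp <- grp[keep]
  levels <- if (is.factor(grp)) levels(droplevels(grp)) else unique(grp)
  if (length(levels) != 2) {
    stop("grouping column must have exactly 2 levels, got ",
         length(levels), call. = FALSE)
  }
  list(a = v[grp == levels[1]], b = v[grp == levels[2]], labels = as.character(levels))
}

#' Pearson chi-squared test on a contingency table, dropping empty categories
#'
#' Rows and columns whose counts are entirely zero are removed before the
#' statistic is computed (a Bayes-factor level at which nobody is labelled
#' non-interoceptive contributes an all-zero column, and the published
#' statistics are computed on the reduced table); no continuity correction
#' is applied.
#'
#' @param counts A numeric matrix of counts, or a data frame whose numeric
#'   columns are the count columns (e.g. the output of
#'   [classification_table()]).
#' @param drop_empty Drop all-zero rows/columns first (default `TRUE`).
#' @return One-row tibble: `test`, `statistic` (X-squared), `df`, `p_value`,
#'   `n`.
#' @export
chisq_test <- function(counts, drop_empty = TRUE) {
  if (is.data.frame(counts)) {
    counts <- as.matrix(counts[vapply(counts, is.numeric, logical(1))])
  }
  m <- as.matrix(counts)
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (drop_empty) {
    m <- m[rowSums(m) > 0, , drop = FALSE]
    m <- m[, colSums(m) > 0, drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("contingency table reduces below 2x2 after dropping empty categories",
         call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(
    test = "pearson_chisq",
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    n = sum(m)
  )
}

#' Mann-Whitney rank-sum test with tie-corrected normal approximation
#'
#' Computes the Mann-Whitney U statistic from mid-ranks and its
#' tie-corrected normal approximation
#' `Var(U) = n1*n2/12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))`.
#' The reported `statistic` is `|Z|` (group-comparison tables print
#' non-negative Z); the signed value is kept in `z_signed`, positive when
#' the first group tends larger.
#'
#' @inheritParams pooled_t_test
#' @param continuity Apply a 0.5 continuity correction (default `FALSE`).
#' @return One-row tibble: `test`, `statistic` (|Z|), `z_signed`, `u`,
#'   `p_value`, group ns and labels.
#' @export
rank_sum_test <- function(data, value, by, continuity = FALSE) {
  g <- two_groups(data, {{ value }}, {{ by }})
  n1 <- length(g$a); n2 <- length(g$b); n <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("each group needs n >= 1", call. = FALSE)
  r <- rank(c(g$a, g$b))                       # mid-ranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 # U for group 1
  ties <- table(c(g$a, g$b))
  tie_term <- sum(ties^3 - ties)
  var_u <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (var_u <= 0) stop("all values tied across both groups", call. = FALSE)
  centered <- u - n1 * n2 / 2
  if (continuity) centered <- sign(centered) * max(0, abs(centered) - 0.5)
  z <- centered / sqrt(var_u)
  tibble::tibble(
    test = "mann_whitney", statistic = abs(z), z_signed = z, u = u,
    p_value = 2 * stats::pnorm(-abs(z)),
    group_a = g$labels[1], group_b = g$labels[2], n_a = n1, n_b = n2
  )
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks; two-tailed p from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df.
#'
#' @param data A data frame.
#' @param x,y <[`data-masking`][rlang::args_data_masking]> Paired numeric
#'   columns.
#' @return One-row tibble: `test`, `estimate` (rho), `df`, `p_value`, `n`.
#' @export
spearman_test <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("constant input: rank correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rank(xv), rank(yv))
  p <- if (abs(rho) >= 1) 0 else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t_stat), n - 2)
  }
  tibble::tibble(test = "spearman", estimate = rho, df = n - 2,
                 p_value = p, n = n)
}

#' Regress covariates out of an outcome
#'
#' Ordinary least squares of the outcome on the covariates (with intercept);
#' the residuals replace the outcome for downstream group comparisons, so a
#' pooled t-test on the residuals has `df = n - 2` exactly as when the raw
#' outcome is compared.
#'
#' @param data A data frame.
#' @param y <[`data-masking`][rlang::args_data_masking]> Outcome column.
#' @param covariates Character vector of covariate column names.
#' @return The input tibble with a `.resid` column added (rows with missing
#'   outcome or covariates are dropped).
#' @export
residualize <- function(data, y, covariates) {
  y_name <- rlang::as_name(rlang::enquo(y))
  if (length(covariates) == 0) stop("no covariates given", call. = FALSE)
  cols <- c(y_name, covariates)
  df <- tidyr::drop_na(dplyr::select(data, dplyr::all_of(names(data))),
                       dplyr::all_of(cols))
  fml <- stats::as.formula(paste(y_name, "~",
                                 paste(covariates, collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  if (fit$rank < length(covariates) + 1) {
    stop("rank-deficient design: covariates are collinear", call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(df), .resid = unname(stats::residuals(fit)))
}

#' One-way analysis of variance
#'
#' @inheritParams pooled_t_test
#' @return One-row tibble: `test`, `statistic` (F), `df1`, `df2`, `p_value`,
#'   `n_groups`, `n`.
#' @export
oneway_anova <- function(data, value, by) {
  v <- dplyr::pull(data, {{ value }})
  grp <- dplyr::pull(data, {{ by }})
  keep <- !is.na(v) & !is.na(grp)
  v <- v[keep]; grp <- factor(grp[keep])
  k <- nlevels(grp); n <- length(v)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(grp) < 2)) stop("each group needs n >= 2", call. = FALSE)
  grand <- mean(v)
  ss_between <- sum(tapply(v, grp, function(g) length(g) * (mean(g) - grand)^2))
  ss_within <- sum(tapply(v, grp, function(g) sum((g - mean(g))^2)))
  df1 <- k - 1; df2 <- n - k
  if (ss_within == 0 && ss_between == 0) {
    stop("no variance within or between groups", call. = FALSE)
  }
  f_stat <- (ss_between / df1) / (ss_within / df2)
  tibble::tibble(test = "oneway_anova", statistic = f_stat, df1 = df1,
                 df2 = df2, p_value = stats::pf(f_stat, df1, df2,
                                                lower.tail = FALSE),
                 n_groups = k, n = n)
}

#' Analytic power of the two-sided pooled t-test
#'
#' Power via the noncentral t distribution with noncentrality
#' `ncp = d * sqrt(n_a * n_b / (n_a + n_b))` and `df = n_a + n_b - 2`,
#' allowing unequal group sizes.
#'
#' @param d Cohen's d effect size (> 0).
#' @param n_a,n_b Group sizes (>= 2 each).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power as a single number in `[0, 1]`.
#' @export
power_two_sample <- function(d, n_a, n_b, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (n_a < 2 || n_b < 2) stop("each group needs n >= 2", call. = FALSE)
  df <- n_a + n_b - 2
  ncp <- d * sqrt(n_a * n_b / (n_a + n_b))
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-crit, df, ncp = ncp)
}
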