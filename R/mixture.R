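#' Fit a two-component Gaussian mixture to consistency scores by EM
#'
#' Models the cohort's consistency scores as a mixture of a low-scoring
#' (non-interoceptive) and a high-scoring (interoceptive) normal component
#' and fits weights, means and standard deviations by
#' expectation-maximisation. The component with the larger mean is labelled
#' interoceptive. Several restarts are run (the first from a
#' quantile-based initialisation, the rest randomised) and the fit with the
#' best log-likelihood is kept.
#'
#' @param scores Numeric vector of at least 20 scores in `[0, 1]`.
#' @param tol Convergence tolerance on the absolute log-likelihood change
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations per restart (default 1000).
#' @param restarts Number of EM restarts (default 10).
#' @param seed Optional integer; makes the randomised restarts (and hence
#'   the fit) fully reproducible without disturbing the caller's RNG.
#' @param sigma_floor Lower bound on component standard deviations
#'   (default 1e-3), preventing collapse onto a single point.
#' @return An object of class `pat_gmm`: list with `weights`, `means`, `sds`
#'   (each length 2, ordered non-interoceptive then interoceptive),
#'   `log_likelihood`, `loglik_trace`, `n_iterations`, `converged`, `n`.
#' @export
fit_gmm2 <- function(scores, tol = 1e-8, max_iter = 1000, restarts = 10,
                     seed = NULL, sigma_floor = 1e-3) {
  scores <- as.numeric(scores)
  if (length(scores) < 20) {
    stop("fit_gmm2() needs at least 20 scores", call. = FALSE)
  }
  if (stats::sd(scores) == 0) {
    stop("degenerate data: all scores identical", call. = FALSE)
  }

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }

  s <- stats::sd(scores)
  inits <- vector("list", restarts)
  inits[[1]] <- list(w = c(0.5, 0.5),
                     mu = unname(stats::quantile(scores, c(0.25, 0.75))),
                     sd = c(s / 2, s / 2))
  if (restarts > 1) {
    for (r in 2:restarts) {
      mu <- sort(sample(scores, 2))
      if (diff(mu) < 1e-6) mu <- mu + c(-s / 4, s / 4)
      w1 <- stats::runif(1, 0.3, 0.7)
      inits[[r]] <- list(w = c(w1, 1 - w1), mu = mu,
                         sd = pmax(sigma_floor, stats::runif(2, s / 4, s)))
    }
  }

  best <- NULL
  for (init in inits) {
    fit <- em_gmm2(scores, init, tol = tol, max_iter = max_iter,
                   sigma_floor = sigma_floor)
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }

  ord <- order(best$mu)  # smaller mean first: non-interoceptive
  structure(
    list(
      components = c("non_interoceptive", "interoceptive"),
      weights = best$w[ord],
      means = best$mu[ord],
      sds = best$sd[ord],
      log_likelihood = best$log_likelihood,
      loglik_trace = best$trace,
      n_iterations = best$iter,
      converged = best$converged,
      n = length(scores)
    ),
    class = "pat_gmm"
  )
}

em_gmm2 <- function(x, init, tol, max_iter, sigma_floor) {
  w <- init$w; mu <- init$mu; sd_ <- pmax(init$sd, sigma_floor)
  n <- length(x)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    # E-step in log space
    lp <- cbind(log(w[1]) + stats::dnorm(x, mu[1], sd_[1], log = TRUE),
                log(w[2]) + stats::dnorm(x, mu[2], sd_[2], log = TRUE))
    m <- pmax(lp[, 1], lp[, 2])
    lse <- m + log(exp(lp[, 1] - m) + exp(lp[, 2] - m))
    ll <- sum(lse)
    trace <- c(trace, ll)
    gamma2 <- exp(lp[, 2] - lse)
    gamma1 <- 1 - gamma2
    # M-step
    n1 <- sum(gamma1); n2 <- n - n1
    w <- c(n1, n2) / n
    mu <- c(sum(gamma1 * x) / n1, sum(gamma2 * x) / n2)
    sd_ <- sqrt(c(sum(gamma1 * (x - mu[1])^2) / n1,
                  sum(gamma2 * (x - mu[2])^2) / n2))
    sd_ <- pmax(sd_, sigma_floor)
    if (abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(w = w, mu = mu, sd = sd_, log_likelihood = trace[length(trace)],
       trace = trace, iter = iter, converged = converged)
}

#' @export
print.pat_gmm <- function(x, ...) {
  cat("<pat_gmm> two-component Gaussian mixture (EM), n =", x$n, "\n")
  for (k in 1:2) {
    cat(sprintf("  %-17s w = %.3f, mean = %.4f, sd = %.4f\n",
                x$components[k], x$weights[k], x$means[k], x$sds[k]))
  }
  cat(sprintf("  logLik = %.4f after %d iterations (%s)\n",
              x$log_likelihood, x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Tidy a mixture fit into one row per component
#' @param x A `pat_gmm` fit.
#' @param ... Unused.
#' @return Tibble: `component`, `weight`, `mean`, `sd`.
#' @method tidy pat_gmm
#' @export
tidy.pat_gmm <- function(x, ...) {
  tibble::tibble(component = x$components, weight = x$weights,
                 mean = x$means, sd = x$sds)
}

#' One-row model-level summary of a mixture fit
#' @param x A `pat_gmm` fit.
#' @param ... Unused.
#' @return Tibble: `log_likelihood`, `n_iterations`, `converged`, `n`.
#' @method glance pat_gmm
#' @export
glance.pat_gmm <- function(x, ...) {
  tibble::tibble(log_likelihood = x$log_likelihood,
                 n_iterations = x$n_iterations,
                 converged = x$converged, n = x$n)
}

#' Per-participant z-scores and belonging probabilities
#'
#' Computes, for each score, the z-score under each fitted component and a
#' probability of belonging to it. The default `"tail"` method uses the
#' two-sided normal tail `P(|Z| >= |z_k|)` of the component z-score, so a
#' score at a component's mean belongs to it with probability 1. The
#' `"posterior"` method instead uses weighted component densities normalised
#' to sum to 1 (posterior responsibilities).
#'
#' @param scores Numeric scores.
#' @param fit A `pat_gmm` from [fit_gmm2()].
#' @param method `"tail"` (default) or `"posterior"`.
#' @return Tibble with `score`, `z_non_interoceptive`, `z_interoceptive`,
#'   `p_non_interoceptive`, `p_interoceptive`, `method`.
#' @export
belonging <- function(scores, fit, method = c("tail", "posterior")) {
  method <- match.arg(method)
  if (any(fit$sds <= 0)) stop("fit has a zero-sd component", call. = FALSE)
  z1 <- (scores - fit$means[1]) / fit$sds[1]
  z2 <- (scores - fit$means[2]) / fit$sds[2]
  if (method == "tail") {
    p1 <- 2 * stats::pnorm(-abs(z1))
    p2 <- 2 * stats::pnorm(-abs(z2))
  } else {
    d1 <- fit$weights[1] * stats::dnorm(scores, fit$means[1], fit$sds[1])
    d2 <- fit$weights[2] * stats::dnorm(scores, fit$means[2], fit$sds[2])
    p1 <- d1 / (d1 + d2)
    p2 <- d2 / (d1 + d2)
  }
  tibble::tibble(
    score = scores,
    z_non_interoceptive = z1, z_interoceptive = z2,
    p_non_interoceptive = p1, p_interoceptive = p2,
    method = method
  )
}

#' Bayes-factor classification at evidence thresholds 3, 10, 30
#'
#' The Bayes factor is the ratio of the larger to the smaller belonging
#' probability, so it is always >= 1, with a direction naming the favoured
#' component. At each threshold the participant is labelled with the
#' favoured component if the Bayes factor strictly exceeds the threshold,
#' and `"unclassified"` otherwise; the three labels are therefore nested.
#'
#' @param bel A tibble from [belonging()].
#' @param p_floor Probabilities are clamped at this floor before forming the
#'   ratio (default 1e-300) so an underflowed tail never divides by zero.
#' @return The input with `bayes_factor`, `direction`, `label_bf3`,
#'   `label_bf10`, `label_bf30` columns added.
#' @export
classify <- function(bel, p_floor = 1e-300) {
  p_int <- pmax(bel$p_interoceptive, p_floor)
  p_non <- pmax(bel$p_non_interoceptive, p_floor)
  bf <- pmax(p_int, p_non) / pmin(p_int, p_non)
  direction <- ifelse(p_int >= p_non, "interoceptive", "non_interoceptive")
  label_at <- function(threshold) ifelse(bf > threshold, direction, "unclassified")
  dplyr::mutate(bel,
    bayes_factor = bf,
    direction = direction,
    label_bf3 = label_at(3),
    label_bf10 = label_at(10),
    label_bf30 = label_at(30)
  )
}

#' Sex-by-classification contingency counts
#'
#' @param labels Character vector with values in
#'   `{"non_interoceptive", "unclassified", "interoceptive"}`.
#' @param sex Character vector (same length) with values `male` / `female`.
#' @return A tibble with one row per sex and count columns
#'   `non_interoceptive`, `unclassified`, `interoceptive`.
#' @export
classification_table <- function(labels, sex) {
  if (length(labels) != length(sex)) {
    stop("labels and sex must be aligned by participant", call. = FALSE)
  }
  lab <- factor(labels, levels = c("non_interoceptive", "unclassified",
                                   "interoceptive"))
  sx <- factor(sex, levels = c("male", "female"))
  counts <- table(sx, lab)
  tibble::tibble(
    sex = rownames(counts),
    non_interoceptive = as.integer(counts[, "non_interoceptive"]),
    unclassified = as.integer(counts[, "unclassified"]),
    interoceptive = as.integer(counts[, "interoceptive"])
  )
}

#' Density plot of scores with the fitted mixture components
#'
#' @param object A `pat_gmm` fit.
#' @param scores Optional scores to histogram beneath the component curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pat_gmm
#' @export
autoplot.pat_gmm <- function(object, scores = NULL, ...) {
  grid <- seq(0, 1, length.out = 400)
  dens <- purrr::map_dfr(1:2, function(k) {
    tibble::tibble(
      score = grid,
      density = object$weights[k] *
        stats::dnorm(grid, object$means[k], object$sds[k]),
      component = object$components[k]
    )
  })
  p <- ggplot2::ggplot()
  if (!is.null(scores)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(score = scores),
      ggplot2::aes(x = .data$score, y = ggplot2::after_stat(density)),
      bins = 30, fill = "grey85", colour = "grey60"
    )
  }
  p +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(x = .data$score, y = .data$density,
                   colour = .data$component),
      linewidth = 1
    ) +
    ggplot2::labs(x = "consistency score", y = "density",
                  colour = "component") +
    ggplot2::theme_minimal()
}
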