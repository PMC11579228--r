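#' Density plot of consistency scores by sex
#'
#' Mirrors the usual presentation of the score distributions: one density
#' per sex with group means marked.
#'
#' @param frame A cohort frame (needs `consistency_score` and `sex`).
#' @return A ggplot object.
#' @export
plot_consistency_by_sex <- function(frame) {
  means <- frame |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(m = mean(.data$consistency_score), .groups = "drop")
  ggplot2::ggplot(frame, ggplot2::aes(x = .data$consistency_score,
                                      fill = .data$sex)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$m,
                                     colour = .data$sex),
                        linetype = "dashed") +
    ggplot2::labs(x = "consistency score", y = "density") +
    ggplot2::theme_minimal()
}

#' Exclusion-ledger bar chart
#'
#' @param frame A cohort frame from [build_cohort()].
#' @return A ggplot object.
#' @export
plot_exclusions <- function(frame) {
  ledger <- exclusion_ledger(frame)
  ggplot2::ggplot(ledger, ggplot2::aes(x = .data$reason)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "exclusion reason", y = "participants") +
    ggplot2::theme_minimal()
}
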