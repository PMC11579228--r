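#' Published sex-by-classification count tables
#'
#' Loads the bundled contingency tables of Bayes-factor classifications by
#' sex reported for a pooled phase-adjustment-task cohort, across the four
#' analysis samples (`full`, `full_matched`, `screened`,
#' `screened_matched`) and the three evidence thresholds. These serve as
#' worked-example inputs for [chisq_test()].
#'
#' @return A tibble: `sample`, `bf_level`, `sex`, `non_interoceptive`,
#'   `unclassified`, `interoceptive`.
#' @export
reference_classification_counts <- function() {
  path <- system.file("extdata", "classification_counts.csv",
                      package = "phasetask", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
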