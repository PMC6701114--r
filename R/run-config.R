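#' Configuration of a screening run
#'
#' @param reference_cohort Cohort absorbed into the intercept under treatment
#'   coding; interaction p-values are "with respect to" this cohort
#'   (typically healthy controls).
#' @param threshold_type Filter the top table on the raw partial-F p-value
#'   (`"raw_p"`) or the Benjamini-Hochberg adjusted one (`"fdr_p"`).
#' @param threshold_value Strict inclusion cutoff in `(0, 1]`; a row is kept
#'   when its (adjusted) p-value is strictly below it.
#' @param min_nonzero Prevalence filter for microbial features (see
#'   [prevalence_filter()]); `0` disables it.
#' @param immune_transform `"none"` or `"sqrt"`, applied to all immune
#'   readouts before fitting.
#' @param metric_columns Which optional metric columns the top table carries,
#'   a subset of `c("F", "p", "pAdj", "interaction_p", "max_influence")`.
#' @param seed Integer seed used wherever the run needs randomness (report
#'   network layout).
#' @return A list of class `run_config`.
#' @export
run_config <- function(reference_cohort,
                       threshold_type = c("fdr_p", "raw_p"),
                       threshold_value = 0.05,
                       min_nonzero = 0L,
                       immune_transform = c("none", "sqrt"),
                       metric_columns = c("F", "p", "pAdj", "interaction_p",
                                          "max_influence"),
                       seed = 1L) {
  threshold_type <- match.arg(threshold_type)
  immune_transform <- match.arg(immune_transform)
  metric_columns <- match.arg(metric_columns, several.ok = TRUE)
  if (!is.numeric(threshold_value) || length(threshold_value) != 1 ||
      is.na(threshold_value) || threshold_value <= 0 || threshold_value > 1) {
    os_config_error("`threshold_value` must be a single number in (0, 1]")
  }
  if (!is.character(reference_cohort) || length(reference_cohort) != 1) {
    os_config_error("`reference_cohort` must be a single cohort label")
  }
  structure(
    list(
      reference_cohort = reference_cohort,
      threshold_type = threshold_type,
      threshold_value = threshold_value,
      min_nonzero = as.integer(min_nonzero),
      immune_transform = immune_transform,
      metric_columns = metric_columns,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

check_config_against_table <- function(config, table) {
  if (!config$reference_cohort %in% table$data$cohort) {
    os_config_error(sprintf(
      "reference cohort '%s' is not a cohort label of the table",
      config$reference_cohort
    ))
  }
  invisible(config)
}
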