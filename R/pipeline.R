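#' Run the full screening pipeline on a merged table
#'
#' Applies the configured prevalence filter and immune transform, fits every
#' microbe-immune pair, adjusts and thresholds into a top table, and bundles
#' the result into a [screen_document][as_screen_document()].
#'
#' @param merged A [merged_table].
#' @param config A [run_config()].
#' @param quiet Suppress the per-stage log messages (features retained, fits
#'   attempted, degenerate pairs, rows surfaced)?
#' @return A list with `merged` (post filter/transform), `screen`
#'   (`pair_screen`), `top_table`, `network` (`network_summary`), and
#'   `document` (`screen_document`).
#' @examples
#' sim <- generate_dataset(synthetic_spec(
#'   cohorts = c(A = 10, B = 10), n_microbes = 5, n_immune = 2,
#'   planted = list(planted_pair(1, 1, slopes = c(A = 0.4), noise_sd = 0.02)),
#'   seed = 7
#' ))
#' res <- run_screen(sim$table, run_config("A", "fdr_p", 0.05), quiet = TRUE)
#' res$top_table
#' @export
run_screen <- function(merged, config, quiet = FALSE) {
  stopifnot(inherits(merged, "merged_table"), inherits(config, "run_config"))
  check_config_against_table(config, merged)
  log_line <- function(...) if (!quiet) message(sprintf(...))

  if (config$min_nonzero > 0) {
    merged <- prevalence_filter(merged, config$min_nonzero)
  }
  log_line("features retained: %d microbes, %d immune readouts",
           length(ome_features(merged, "microbe")),
           length(ome_features(merged, "immune")))
  merged <- apply_transform(merged, "immune", config$immune_transform)

  screen <- screen_pairs(merged, config)
  log_line("fits attempted: %d (%d degenerate)",
           nrow(screen), sum(screen$degenerate))
  top <- build_top_table(screen, config)
  log_line("rows surfaced: %d at %s < %g",
           nrow(top), config$threshold_type, config$threshold_value)
  list(
    merged = merged,
    screen = screen,
    top_table = top,
    network = network_summary(top),
    document = as_screen_document(top, merged, config)
  )
}
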