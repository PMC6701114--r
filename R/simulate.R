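#' Specify a synthetic two-ome dataset
#'
#' The generator emulates the data shapes the screen targets: a small human
#' cohort study (2-4 cohorts, a few dozen samples) with zero-inflated
#' microbial relative abundances in `[0, 1]` and positive continuous immune
#' readouts, plus optional planted pair-specific per-cohort linear
#' associations with known slopes. Defaults mirror a 4-cohort, 37-sample,
#' 70-microbe, 6-readout design.
#'
#' Null microbes are zero-inflated Beta draws: with probability
#' `zero_inflation_prob` a sample's value is exactly 0, otherwise
#' `Beta(beta_shape1, beta_shape2)`. Immune readouts are i.i.d. lognormal
#' with per-feature `meanlog`/`sdlog` (recycled); the screen is equivariant
#' to the readout scale, so the default is a unit-scale lognormal. Planted
#' microbes are per-cohort linear functions of their immune partner plus
#' Gaussian noise, clipped into `[0, 1]` with the clipped fraction reported.
#'
#' @param cohorts Named integer vector of per-cohort sample counts; the
#'   first label is conventionally the reference.
#' @param n_microbes,n_immune Feature counts per ome.
#' @param planted List of [planted_pair()] records.
#' @param zero_inflation_prob Probability a null microbe value is exactly 0.
#' @param beta_shape1,beta_shape2 Beta parameters of nonzero null abundances.
#' @param immune_meanlog,immune_sdlog Lognormal parameters, recycled over
#'   immune features.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(cohorts = c(HC = 10L, CD = 9L, SpA = 9L, UC = 9L),
                           n_microbes = 70L, n_immune = 6L,
                           planted = list(),
                           zero_inflation_prob = 0.3,
                           beta_shape1 = 2, beta_shape2 = 18,
                           immune_meanlog = 0, immune_sdlog = 0.5,
                           seed = 1L) {
  if (is.null(names(cohorts)) || any(names(cohorts) == "")) {
    os_config_error("`cohorts` must be a named vector of sample counts")
  }
  if (length(cohorts) < 2) {
    os_config_error("need at least 2 cohorts")
  }
  if (zero_inflation_prob < 0 || zero_inflation_prob >= 1) {
    os_config_error("`zero_inflation_prob` must lie in [0, 1)")
  }
  for (pl in planted) {
    if (pl$microbe < 1 || pl$microbe > n_microbes ||
        pl$immune < 1 || pl$immune > n_immune) {
      os_config_error("planted pair indices out of range")
    }
    if (!all(is.finite(unlist(pl$slopes)))) {
      os_config_error("planted slopes must be finite")
    }
    if (!all(names(pl$slopes) %in% names(cohorts))) {
      os_config_error("planted slope map names unknown cohort(s)")
    }
  }
  structure(
    list(
      cohorts = cohorts, n_microbes = as.integer(n_microbes),
      n_immune = as.integer(n_immune), planted = planted,
      zero_inflation_prob = zero_inflation_prob,
      beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
      immune_meanlog = immune_meanlog, immune_sdlog = immune_sdlog,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Describe one planted association
#'
#' @param microbe,immune 1-based feature indices within their ome.
#' @param slopes Named per-cohort slope map (cohorts omitted get slope 0).
#' @param intercept Baseline abundance at readout 0.
#' @param noise_sd Gaussian noise standard deviation on the abundance scale.
#' @return A list usable in [synthetic_spec()]'s `planted`.
#' @export
planted_pair <- function(microbe, immune, slopes, intercept = 0.05,
                         noise_sd = 0.02) {
  list(microbe = microbe, immune = immune, slopes = slopes,
       intercept = intercept, noise_sd = noise_sd)
}

#' Generate a synthetic merged table with known structure
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `table` (a [merged_table]) and `truth`, a tibble with
#'   one row per planted pair (`microbe`, `immune`, `intercept`, `noise_sd`,
#'   `clip_fraction`, and a `slopes` list-column). The truth record is
#'   sufficient to score any screen run on the table for realized power and
#'   false-discovery proportion (see [screen_performance()]).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  n <- sum(spec$cohorts)
  cohort <- rep(names(spec$cohorts), times = spec$cohorts)
  sample_id <- sprintf("s%03d", seq_len(n))
  mb_names <- sprintf("mb_%03d", seq_len(spec$n_microbes))
  ir_names <- sprintf("ir_%02d", seq_len(spec$n_immune))

  meanlog <- rep_len(spec$immune_meanlog, spec$n_immune)
  sdlog <- rep_len(spec$immune_sdlog, spec$n_immune)
  immune <- vapply(seq_len(spec$n_immune), function(j) {
    rlnorm(n, meanlog = meanlog[j], sdlog = sdlog[j])
  }, numeric(n))
  colnames(immune) <- ir_names

  microbe <- vapply(seq_len(spec$n_microbes), function(j) {
    nonzero <- rbinom(n, 1, 1 - spec$zero_inflation_prob)
    nonzero * rbeta(n, spec$beta_shape1, spec$beta_shape2)
  }, numeric(n))
  colnames(microbe) <- mb_names

  truth <- purrr::map_dfr(spec$planted, function(pl) {
    slopes <- setNames(rep(0, length(spec$cohorts)), names(spec$cohorts))
    slopes[names(pl$slopes)] <- unlist(pl$slopes)
    x <- immune[, pl$immune]
    mu <- pl$intercept + slopes[cohort] * x
    y <- mu + rnorm(n, sd = pl$noise_sd)
    clip_fraction <- mean(y < 0 | y > 1)
    if (clip_fraction > 0.5) {
      os_abort(sprintf(
        "planted pair (%s, %s): %.0f%% of values clipped; effect sizes unrealistic for the unit interval",
        mb_names[pl$microbe], ir_names[pl$immune], 100 * clip_fraction
      ), "omescreen_generation_error")
    }
    microbe[, pl$microbe] <<- pmin(1, pmax(0, y))
    tibble(
      microbe = mb_names[pl$microbe], immune = ir_names[pl$immune],
      intercept = pl$intercept, noise_sd = pl$noise_sd,
      clip_fraction = clip_fraction, slopes = list(slopes)
    )
  })

  data <- dplyr::bind_cols(
    tibble(sample_id = sample_id, cohort = cohort),
    as_tibble(microbe), as_tibble(immune)
  )
  features <- dplyr::bind_rows(
    tibble(feature = mb_names, ome = "microbe", units = "relative abundance"),
    tibble(feature = ir_names, ome = "immune", units = "pg/ml")
  )
  list(table = merged_table(data, features), truth = truth)
}

#' Generate a dataset with no planted associations
#'
#' Convenience wrapper for type-I-error calibration: every microbe-immune
#' pair is null.
#'
#' @param spec A [synthetic_spec()]; any planted pairs are dropped.
#' @return A [merged_table].
#' @export
null_dataset <- function(spec) {
  spec$planted <- list()
  generate_dataset(spec)$table
}

#' Score a screen against the generator's truth record
#'
#' @param table A `top_table` from [build_top_table()].
#' @param truth The truth tibble from [generate_dataset()].
#' @return One-row tibble: true/false positive counts, misses, realized
#'   power, and realized false-discovery proportion (0 when nothing was
#'   surfaced).
#' @export
screen_performance <- function(table, truth) {
  surfaced <- paste(table$microbe, table$immune, sep = "\r")
  planted <- paste(truth$microbe, truth$immune, sep = "\r")
  tp <- sum(surfaced %in% planted)
  fp <- length(surfaced) - tp
  tibble(
    n_surfaced = length(surfaced), n_planted = length(planted),
    tp = tp, fp = fp, fn = length(planted) - tp,
    power = if (length(planted) == 0) NA_real_ else tp / length(planted),
    fdp = if (length(surfaced) == 0) 0 else fp / length(surfaced)
  )
}
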