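#' Fit the interaction model for one microbe-immune pair
#'
#' Fits the full ordinary-least-squares model
#' `microbe ~ cohort + readout + cohort:readout` (treatment coding, the
#' designated reference cohort absorbed into the intercept) and the reduced
#' model `microbe ~ cohort`, and compares them with a partial F-test. The
#' F-test asks whether the immune readout — with a possibly different slope
#' per cohort — adds explanatory value over cohort membership alone. The
#' microbe is always the response and the immune readout the predictor.
#'
#' Samples missing either value are dropped pairwise. With `K` cohorts and
#' `n` retained samples, the full model has `2K` parameters and the reduced
#' `K`, so the partial F statistic has `(K, n - 2K)` degrees of freedom.
#'
#' @param y Microbe relative abundances (response).
#' @param x Immune readout values (predictor).
#' @param cohorts Per-sample cohort labels.
#' @param reference The reference cohort label.
#' @param microbe,immune Feature names recorded in the result.
#' @return An object of class `pair_fit` with elements `beta` (named
#'   coefficient vector), `rss_full`, `rss_reduced`, `df_full`,
#'   `df_reduced`, `F`, `p`, `interaction_p` (named by non-reference
#'   cohort), `dffits`, `max_influence`, and the per-sample `data` used.
#' @seealso [interaction_pvalues()], [pair_dffits()], [cohort_lines()]
#' @examples
#' set.seed(1)
#' x <- rlnorm(30)
#' cohort <- rep(c("HC", "CD"), each = 15)
#' y <- pmin(1, pmax(0, 0.2 + ifelse(cohort == "CD", 0.3, 0) * x +
#'   rnorm(30, sd = 0.05)))
#' fit <- fit_pair(y, x, cohort, reference = "HC")
#' glance(fit)
#' @export
fit_pair <- function(y, x, cohorts, reference,
                     microbe = "microbe", immune = "immune") {
  stopifnot(length(y) == length(x), length(y) == length(cohorts))
  keep <- !is.na(y) & !is.na(x) & !is.na(cohorts)
  y <- y[keep]; x <- x[keep]; cohorts <- as.character(cohorts)[keep]
  n <- length(y)

  labels <- sort(unique(cohorts))
  if (!reference %in% labels) {
    os_contract_error(sprintf(
      "reference cohort '%s' absent from pair %s:%s", reference, microbe, immune
    ))
  }
  labels <- c(reference, setdiff(labels, reference))
  k <- length(labels)

  counts <- table(cohorts)
  if (any(counts < 2)) {
    os_insufficient_error(sprintf(
      "pair %s:%s: cohort '%s' has fewer than 2 samples",
      microbe, immune, names(counts)[which(counts < 2)[1]]
    ))
  }
  if (n < 2 * k + 1) {
    os_insufficient_error(sprintf(
      "pair %s:%s: %d samples cannot support a %d-parameter model",
      microbe, immune, n, 2 * k
    ))
  }
  if (all(y == y[1])) {
    os_degenerate_error(sprintf(
      "pair %s:%s: constant response", microbe, immune
    ))
  }

  df <- data.frame(y = y, x = x, cohort = factor(cohorts, levels = labels))
  full <- lm(y ~ cohort * x, data = df)
  if (anyNA(coef(full))) {
    os_degenerate_error(sprintf(
      "pair %s:%s: singular full design (readout constant within a cohort)",
      microbe, immune
    ))
  }
  reduced <- lm(y ~ cohort, data = df)

  rss_full <- sum(residuals(full)^2)
  rss_reduced <- sum(residuals(reduced)^2)
  df_full <- n - 2L * k
  df_reduced <- n - k

  # exact-zero RSS up to QR roundoff, relative to the total sum of squares
  tss <- sum((y - mean(y))^2)
  reduced_perfect <- rss_reduced <= 1e-12 * tss
  perfect <- !reduced_perfect && rss_full <= 1e-12 * rss_reduced
  if (reduced_perfect) {
    # both nested models fit exactly: the readout adds nothing
    f_stat <- 0
    p <- 1
  } else if (perfect) {
    f_stat <- Inf
    p <- 0
  } else {
    f_stat <- max(0, (rss_reduced - rss_full) / k / (rss_full / df_full))
    p <- pf(f_stat, k, df_full, lower.tail = FALSE)
  }

  coefs <- if (perfect || reduced_perfect) {
    # summary.lm warns about exact fits; the t-tests are unset below anyway
    suppressWarnings(summary(full)$coefficients)
  } else {
    summary(full)$coefficients
  }
  inter_rows <- paste0("cohort", labels[-1], ":x")
  interaction_p <- setNames(coefs[inter_rows, "Pr(>|t|)"], labels[-1])
  if (perfect || reduced_perfect) interaction_p[] <- NA_real_

  fit <- structure(
    list(
      microbe = microbe, immune = immune, n = n,
      cohort_labels = labels, reference = reference,
      beta = coef(full), coef_table = coefs,
      rss_full = rss_full, rss_reduced = rss_reduced,
      df_full = df_full, df_reduced = df_reduced,
      F = f_stat, p = p,
      interaction_p = interaction_p,
      degenerate_perfect = perfect,
      dffits = NULL, max_influence = NA_real_,
      data = tibble(x = x, y = y, cohort = cohorts)
    ),
    class = "pair_fit"
  )

  if (reduced_perfect) {
    # every residual is zero: DFFITS = 0 by convention
    fit$dffits <- rep(0, n)
    fit$max_influence <- 0
  } else if (df_full <= 1 || perfect) {
    warn(sprintf(
      "pair %s:%s: influence diagnostics skipped (deletion fit undefined)",
      microbe, immune
    ), class = "omescreen_diagnostics_skipped")
  } else {
    h <- hatvalues(full)
    d <- rstudent(full) * sqrt(h / (1 - h))
    d[!is.finite(d) | residuals(full) == 0] <- 0
    fit$dffits <- unname(d)
    fit$max_influence <- max(abs(d))
  }
  fit
}

#' @export
print.pair_fit <- function(x, ...) {
  cat(sprintf(
    "<pair_fit> %s ~ cohort * %s  (n = %d, %d cohorts, ref = %s)\n",
    x$microbe, x$immune, x$n, length(x$cohort_labels), x$reference
  ))
  cat(sprintf("  partial F = %.4g on (%d, %d) df, p = %.4g\n",
              x$F, x$df_reduced - x$df_full, x$df_full, x$p))
  if (!is.na(x$max_influence)) {
    cat(sprintf("  max |DFFITS| = %.4g\n", x$max_influence))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy pair_fit
#' @export
tidy.pair_fit <- function(x, ...) {
  ct <- x$coef_table
  tibble(
    term = rownames(ct),
    estimate = ct[, "Estimate"],
    std.error = ct[, "Std. Error"],
    statistic = ct[, "t value"],
    p.value = ct[, "Pr(>|t|)"]
  )
}

#' @method glance pair_fit
#' @export
glance.pair_fit <- function(x, ...) {
  tibble(
    microbe = x$microbe, immune = x$immune, n = x$n,
    F = x$F, p = x$p,
    df_num = x$df_reduced - x$df_full, df_den = x$df_full,
    rss_full = x$rss_full, rss_reduced = x$rss_reduced,
    max_influence = x$max_influence
  )
}

#' P-values of the cohort-by-readout interaction coefficients
#'
#' For each non-reference cohort, the two-sided t-test of the hypothesis that
#' its interaction coefficient is zero in the full model — i.e. that its
#' microbe~readout slope equals the reference cohort's. Residual degrees of
#' freedom are those of the full model.
#'
#' @param fit A non-degenerate [pair_fit].
#' @param cohort Optionally a single non-reference cohort to extract.
#' @return Named numeric vector (or a single value if `cohort` is given).
#' @export
interaction_pvalues <- function(fit, cohort = NULL) {
  stopifnot(inherits(fit, "pair_fit"))
  if (is.null(cohort)) return(fit$interaction_p)
  if (identical(cohort, fit$reference)) {
    os_contract_error(
      "the reference cohort has no interaction term; its slope is the baseline"
    )
  }
  if (!cohort %in% names(fit$interaction_p)) {
    os_contract_error(sprintf("unknown cohort '%s'", cohort))
  }
  fit$interaction_p[[cohort]]
}

#' Per-observation DFFITS influence
#'
#' DFFITS for observation `i` is the number of standard deviations by which
#' the `i`-th fitted value changes when the model is refitted without
#' observation `i`; computed from the full-model leverages and externally
#' studentized residuals via the standard closed form
#' `t_i * sqrt(h_ii / (1 - h_ii))`. Observations with a zero residual get
#' DFFITS 0 by convention. `max_influence` is the largest absolute DFFITS
#' and flags pairs whose fit is driven by a single influential sample.
#'
#' @param fit A [pair_fit].
#' @return A list with `dffits` (per-observation, in input order after
#'   pairwise deletion) and `max_influence`.
#' @export
pair_dffits <- function(fit) {
  stopifnot(inherits(fit, "pair_fit"))
  list(dffits = fit$dffits, max_influence = fit$max_influence)
}

#' Per-cohort fitted line segments
#'
#' Under treatment coding the reference cohort's line is
#' `(beta0, beta_x)`; each other cohort's intercept and slope add that
#' cohort's offset and interaction coefficients. Each segment spans only its
#' own cohort's observed readout range, so cohorts with different dynamic
#' ranges draw segments of different extents. Glyph coordinates
#' (`gx0/gy0` to `gx1/gy1`) map all segments jointly into the unit square
#' (shared min/max over segment endpoints), the normalization used by the
#' sparkline-sized microplots in the report.
#'
#' @param fit A non-degenerate [pair_fit].
#' @return A tibble with one row per cohort: `cohort`, `intercept`, `slope`,
#'   `x_min`, `x_max`, fitted endpoint values `y0`, `y1`, and glyph
#'   coordinates `gx0`, `gy0`, `gx1`, `gy1`.
#' @export
cohort_lines <- function(fit) {
  stopifnot(inherits(fit, "pair_fit"))
  beta <- fit$beta
  labels <- fit$cohort_labels
  lines <- purrr::map_dfr(labels, function(lab) {
    off_int <- if (lab == fit$reference) 0 else beta[[paste0("cohort", lab)]]
    off_slp <- if (lab == fit$reference) 0 else beta[[paste0("cohort", lab, ":x")]]
    xs <- fit$data$x[fit$data$cohort == lab]
    tibble(
      cohort = lab,
      intercept = beta[["(Intercept)"]] + off_int,
      slope = beta[["x"]] + off_slp,
      x_min = min(xs), x_max = max(xs)
    )
  })
  lines$y0 <- lines$intercept + lines$slope * lines$x_min
  lines$y1 <- lines$intercept + lines$slope * lines$x_max
  gx <- range(c(lines$x_min, lines$x_max))
  gy <- range(c(lines$y0, lines$y1))
  lines$gx0 <- unit_scale(lines$x_min, gx)
  lines$gx1 <- unit_scale(lines$x_max, gx)
  lines$gy0 <- unit_scale(lines$y0, gy)
  lines$gy1 <- unit_scale(lines$y1, gy)
  lines
}

# affine map onto [0, 1]; a degenerate range collapses to the midline
unit_scale <- function(v, rng) {
  if (diff(rng) == 0) return(rep(0.5, length(v)))
  (v - rng[1]) / diff(rng)
}

#' Detailed regression plot for one pair
#'
#' One point per sample, colored by cohort, sized by `|DFFITS|` when
#' influence diagnostics are available, with the fitted per-cohort line
#' segments overlaid. The closer the points to their cohort's line, the
#' better the model.
#'
#' @param object A [pair_fit].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pair_fit
#' @export
autoplot.pair_fit <- function(object, ...) {
  pts <- object$data
  lines <- cohort_lines(object)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$cohort))
  if (!is.null(object$dffits)) {
    pts$influence <- abs(object$dffits)
    p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                           colour = .data$cohort,
                                           size = .data$influence))
  }
  p +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_segment(
      data = lines,
      ggplot2::aes(x = .data$x_min, xend = .data$x_max,
                   y = .data$y0, yend = .data$y1, colour = .data$cohort),
      inherit.aes = FALSE, linewidth = 0.7
    ) +
    ggplot2::labs(
      x = object$immune, y = object$microbe,
      title = sprintf("%s ~ cohort × %s", object$microbe, object$immune),
      subtitle = sprintf("partial F p = %.3g", object$p)
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
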