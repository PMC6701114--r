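#' Fit every microbe-immune pair of a merged table
#'
#' Attempts one [fit_pair()] per (microbe, immune) combination — microbes in
#' the outer loop, immune readouts in the inner loop, both in manifest order
#' — so the number of attempted fits is `#microbes * #immune`. Pairs whose
#' fit is degenerate (constant response, singular design, or an exactly
#' perfect full fit) or under-sampled are recorded with a reason instead of
#' aborting the run. The result is deterministic for a given table and
#' configuration.
#'
#' @param table A validated (and, typically, prevalence-filtered and
#'   transformed) [merged_table].
#' @param config A [run_config()]; only `reference_cohort` matters here.
#' @return A `pair_screen` tibble with one row per attempted pair: `microbe`,
#'   `immune`, `n`, `F`, `p`, `max_influence`, list-columns `interaction_p`
#'   and `fit`, and `degenerate`/`reason` for excluded pairs.
#' @export
screen_pairs <- function(table, config) {
  stopifnot(inherits(table, "merged_table"), inherits(config, "run_config"))
  check_config_against_table(config, table)
  microbes <- ome_features(table, "microbe")
  immunes <- ome_features(table, "immune")
  if (length(microbes) == 0 || length(immunes) == 0) {
    os_config_error("screen needs at least one feature in each ome")
  }

  grid <- tidyr::expand_grid(microbe = microbes, immune = immunes)
  rows <- purrr::pmap(grid, function(microbe, immune) {
    fit <- NULL
    reason <- NA_character_
    withCallingHandlers(
      tryCatch(
        fit <- fit_pair(
          y = table$data[[microbe]], x = table$data[[immune]],
          cohorts = table$data$cohort,
          reference = config$reference_cohort,
          microbe = microbe, immune = immune
        ),
        omescreen_degenerate_error = function(e) reason <<- conditionMessage(e),
        omescreen_insufficient_error = function(e) reason <<- conditionMessage(e)
      ),
      omescreen_diagnostics_skipped = function(w) {
        invokeRestart("muffleWarning")
      }
    )
    if (!is.null(fit) && fit$degenerate_perfect) {
      reason <- sprintf("pair %s:%s: perfect full fit (rss_full = 0)",
                        microbe, immune)
      fit <- NULL
    }
    if (is.null(fit)) {
      return(tibble(
        microbe = microbe, immune = immune, n = NA_integer_,
        F = NA_real_, p = NA_real_, max_influence = NA_real_,
        interaction_p = list(NULL), fit = list(NULL),
        degenerate = TRUE, reason = reason
      ))
    }
    tibble(
      microbe = microbe, immune = immune, n = fit$n,
      F = fit$F, p = fit$p, max_influence = fit$max_influence,
      interaction_p = list(fit$interaction_p), fit = list(fit),
      degenerate = FALSE, reason = NA_character_
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pair_screen", class(out))
  attr(out, "reference") <- config$reference_cohort
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies the Benjamini-Hochberg step-up procedure
#' (via [stats::p.adjust()]): sort ascending, take `p_(i) * m / i`, enforce
#' monotonicity from the largest rank down, cap at 1, and return adjusted
#' values in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) os_contract_error("`p` must be numeric")
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    os_contract_error("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Filter and rank screened pairs into a top table
#'
#' Adjusted p-values are computed over all non-degenerate fits (the BH `m`
#' is the number of computed tests, not the attempted pair count). Rows are
#' retained when `p` (threshold type `"raw_p"`) or `pAdj` (`"fdr_p"`) is
#' strictly below the configured threshold, sorted by `p` ascending with
#' ties broken by (microbe, immune), and keyed `1..R`. Metric columns follow
#' `config$metric_columns`; per-cohort fitted-line geometry travels along in
#' the `lines` list-column.
#'
#' @param screen A `pair_screen` from [screen_pairs()].
#' @param config The [run_config()].
#' @return A `top_table` tibble. An empty result is an empty tibble, not an
#'   error.
#' @export
build_top_table <- function(screen, config) {
  stopifnot(inherits(screen, "pair_screen"), inherits(config, "run_config"))
  ok <- dplyr::filter(as_tibble(screen), !.data$degenerate)
  ok$pAdj <- bh_adjust(ok$p)
  kept <- switch(config$threshold_type,
    raw_p = dplyr::filter(ok, .data$p < config$threshold_value),
    fdr_p = dplyr::filter(ok, .data$pAdj < config$threshold_value)
  )
  kept <- dplyr::arrange(kept, .data$p, .data$microbe, .data$immune)
  kept$key <- seq_len(nrow(kept))
  kept$lines <- purrr::map(kept$fit, function(f) {
    if (is.null(f)) NULL else cohort_lines(f)
  })

  cols <- c("key", "microbe", "immune",
            intersect(c("F", "p", "pAdj", "interaction_p", "max_influence"),
                      config$metric_columns),
            "n", "lines", "fit")
  out <- kept[, cols]
  class(out) <- c("top_table", class(out))
  attr(out, "reference") <- attr(screen, "reference")
  attr(out, "m_tests") <- nrow(ok)
  attr(out, "config") <- config
  out
}

#' @export
print.top_table <- function(x, ...) {
  cat(sprintf("<top_table> %d relationship(s) (BH over %s tests)\n",
              nrow(x), attr(x, "m_tests") %||% "?"))
  shown <- x[, setdiff(names(x), c("lines", "fit", "interaction_p"))]
  print(as_tibble(shown), ...)
  invisible(x)
}

#' Summarize a top table as an analyte network
#'
#' Each distinct analyte becomes a node (tagged with its ome and its degree,
#' the number of incident edges) and each top-table row an edge between its
#' microbe and its immune readout. High-degree "hub" analytes are those
#' associated with many partners in the other ome.
#'
#' @param table A `top_table`.
#' @return A `network_summary`: list of tibbles `nodes` (`analyte`, `ome`,
#'   `degree`) and `edges` (`microbe`, `immune`, `key`).
#' @export
network_summary <- function(table) {
  stopifnot(inherits(table, "top_table"))
  edges <- tibble(microbe = table$microbe, immune = table$immune,
                  key = table$key)
  nodes <- dplyr::bind_rows(
    tibble(analyte = edges$microbe, ome = "microbe"),
    tibble(analyte = edges$immune, ome = "immune")
  )
  nodes <- dplyr::summarise(
    dplyr::group_by(nodes, .data$analyte, .data$ome),
    degree = dplyr::n(), .groups = "drop"
  )
  nodes <- dplyr::arrange(nodes, dplyr::desc(.data$degree), .data$analyte)
  structure(list(nodes = nodes, edges = edges), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("<network_summary> %d node(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes) > 0) print(head(x$nodes, 10))
  invisible(x)
}

#' Convert a network summary to an igraph graph
#' @param x A `network_summary`.
#' @return An [igraph::graph] with vertex attributes `ome` and `degree`.
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, "network_summary"))
  igraph::graph_from_data_frame(
    d = x$edges[, c("microbe", "immune")],
    directed = FALSE,
    vertices = as.data.frame(x$nodes)
  )
}

#' Plot the analyte network
#'
#' Node-link rendering of a [network_summary()] with a seeded deterministic
#' force-directed (Fruchterman-Reingold) layout; node color encodes the ome.
#'
#' @param x A `network_summary`.
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_network <- function(x, seed = 1L) {
  stopifnot(inherits(x, "network_summary"))
  lay <- network_layout(x, seed = seed)
  seg <- dplyr::left_join(x$edges, lay, by = c(microbe = "analyte"))
  seg <- dplyr::rename(seg, x0 = "x", y0 = "y")
  seg <- dplyr::left_join(seg, lay, by = c(immune = "analyte"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x, yend = .data$y),
      colour = "grey60"
    ) +
    ggplot2::geom_point(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$ome,
                   size = .data$degree)
    ) +
    ggplot2::geom_text(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$analyte),
      vjust = -1, size = 3
    ) +
    ggplot2::theme_void()
}

# deterministic seeded force-directed layout, shared by plot and report
network_layout <- function(x, seed = 1L) {
  if (nrow(x$nodes) == 0) {
    return(tibble(analyte = character(), ome = character(),
                  degree = integer(), x = numeric(), y = numeric()))
  }
  g <- as_igraph(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, niter = 500)
  out <- x$nodes
  out$x <- unit_scale(xy[, 1], range(xy[, 1]))
  out$y <- unit_scale(xy[, 2], range(xy[, 2]))
  out
}

# save/restore the global RNG state so seeded internals do not perturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
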