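#' Render a screen document as a self-contained HTML report
#'
#' A single static file with no external references: a node-link network of
#' the top table (seeded deterministic force-directed layout, node color by
#' ome), the top table itself with one inline microplot per row (the
#' glyph-normalized per-cohort fitted segments), and one detailed
#' regression plot per row — samples as points colored by cohort, point
#' radius proportional to `|DFFITS|` when influence diagnostics are
#' present, and the fitted line per cohort over that cohort's readout
#' range. All graphics are inline SVG; rendering the same document with the
#' same seed is byte-deterministic.
#'
#' @param doc A `screen_document`.
#' @param path Output HTML file path.
#' @param seed Layout seed; defaults to the document's configured seed.
#' @return `path`, invisibly.
#' @export
render_report <- function(doc, path, seed = doc$config$seed) {
  stopifnot(inherits(doc, "screen_document"))
  validate_document(doc)
  tt <- doc$top_table
  colors <- doc$config$cohortColors
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    "<title>Cross-ome screen report</title>",
    "<style>",
    "body{font-family:sans-serif;margin:2em;max-width:70em}",
    "table{border-collapse:collapse}",
    "td,th{border:1px solid #ccc;padding:4px 8px;font-size:13px}",
    "h1,h2{color:#333}",
    ".detail{display:inline-block;margin:6px;vertical-align:top}",
    "</style></head><body>",
    "<h1>Cross-ome interaction screen</h1>",
    sprintf(
      "<p>%d relationship%s at %s &lt; %s (reference cohort: %s).</p>",
      nrow(tt), if (nrow(tt) == 1) "" else "s",
      if (doc$config$thresholdType == "fdr_p") "FDR-adjusted p" else "raw p",
      fmt(doc$config$thresholdValue), esc(doc$config$referenceCohort)
    ),
    cohort_legend_html(colors)
  )
  if (nrow(tt) == 0) {
    html <- c(html, "<p><em>0 relationships surfaced; nothing to plot.</em></p>")
  } else {
    html <- c(
      html,
      "<h2>Analyte network</h2>",
      network_svg(network_summary(tt), seed = seed),
      "<h2>Top table</h2>",
      top_table_html(tt, colors),
      "<h2>Detailed regression plots</h2>",
      unlist(purrr::map(seq_len(nrow(tt)), function(i) {
        detail_svg(tt[i, ], doc$data[[as.character(tt$key[i])]], colors)
      }))
    )
  }
  html <- c(html, "</body></html>")
  writeLines(html, path, useBytes = TRUE)
  invisible(path)
}

esc <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

fmt <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) return("")
  formatC(signif(x, 3), format = "g", digits = 3)
}

cohort_legend_html <- function(colors) {
  items <- vapply(names(colors), function(lab) {
    sprintf(
      "<span style=\"color:%s\">&#9632;</span> %s", colors[[lab]], esc(lab)
    )
  }, character(1))
  paste0("<p>Cohorts: ", paste(items, collapse = " &nbsp; "), "</p>")
}

# sparkline-sized glyph of the per-cohort fitted segments; the glyph
# coordinates are already normalized into the unit square
microplot_svg <- function(lines, colors, w = 60, h = 36, pad = 3) {
  if (is.null(lines)) return("<svg width=\"60\" height=\"36\"></svg>")
  segs <- vapply(seq_len(nrow(lines)), function(j) {
    sprintf(
      "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"%s\" stroke-width=\"2\"/>",
      fmt(pad + lines$gx0[j] * (w - 2 * pad)),
      fmt(pad + (1 - lines$gy0[j]) * (h - 2 * pad)),
      fmt(pad + lines$gx1[j] * (w - 2 * pad)),
      fmt(pad + (1 - lines$gy1[j]) * (h - 2 * pad)),
      colors[[lines$cohort[j]]] %||% "#333333"
    )
  }, character(1))
  paste0(
    sprintf("<svg width=\"%d\" height=\"%d\">", w, h),
    paste(segs, collapse = ""), "</svg>"
  )
}

top_table_html <- function(tt, colors) {
  metric_cols <- intersect(c("F", "p", "pAdj", "max_influence"), names(tt))
  has_ip <- "interaction_p" %in% names(tt)
  ip_cohorts <- if (has_ip) {
    unique(unlist(purrr::map(tt$interaction_p, names)))
  } else character(0)
  headers <- c("key", "microbe", "immune", metric_cols,
               paste0("interaction_p ", ip_cohorts), "mPlot")
  head_row <- paste0(
    "<tr>", paste0("<th>", esc(gsub("max_influence", "maxInfluence", headers)),
                   "</th>", collapse = ""), "</tr>"
  )
  body <- vapply(seq_len(nrow(tt)), function(i) {
    cells <- c(
      as.character(tt$key[i]), esc(tt$microbe[i]), esc(tt$immune[i]),
      vapply(metric_cols, function(m) fmt(tt[[m]][i]), character(1))
    )
    if (has_ip) {
      ip <- tt$interaction_p[[i]]
      cells <- c(cells, vapply(ip_cohorts, function(ch) {
        if (!is.null(ip) && ch %in% names(ip)) fmt(ip[[ch]]) else ""
      }, character(1)))
    }
    cells <- c(cells, microplot_svg(
      if ("lines" %in% names(tt)) tt$lines[[i]] else NULL, colors
    ))
    paste0("<tr>", paste0("<td>", cells, "</td>", collapse = ""), "</tr>")
  }, character(1))
  paste0("<table>", head_row, paste(body, collapse = ""), "</table>")
}

detail_svg <- function(row, rec, colors, w = 320, h = 240, pad = 40) {
  xs <- rec$x; ys <- rec$y
  xr <- expand_range(range(xs)); yr <- expand_range(range(ys))
  px <- function(v) pad + unit_scale(v, xr) * (w - 2 * pad)
  py <- function(v) h - pad - unit_scale(v, yr) * (h - 2 * pad)
  radius <- if (!is.null(rec$influence) && max(rec$influence) > 0) {
    2 + 6 * rec$influence / max(rec$influence)
  } else {
    rep(3, length(xs))
  }
  pts <- vapply(seq_along(xs), function(j) {
    sprintf(
      "<circle cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"%s\" fill-opacity=\"0.7\"/>",
      fmt(px(xs[j])), fmt(py(ys[j])), fmt(radius[j]),
      colors[[rec$cohort[j]]] %||% "#333333"
    )
  }, character(1))
  lines <- row$lines[[1]]
  segs <- if (is.null(lines)) character(0) else {
    vapply(seq_len(nrow(lines)), function(j) {
      sprintf(
        "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"%s\" stroke-width=\"1.5\"/>",
        fmt(px(lines$x_min[j])), fmt(py(lines$y0[j])),
        fmt(px(lines$x_max[j])), fmt(py(lines$y1[j])),
        colors[[lines$cohort[j]]] %||% "#333333"
      )
    }, character(1))
  }
  x_lab <- if (!is.na(rec$xUnits %||% NA)) {
    sprintf("%s (%s)", row$immune, rec$xUnits)
  } else row$immune
  y_lab <- if (!is.na(rec$yUnits %||% NA)) {
    sprintf("%s (%s)", row$microbe, rec$yUnits)
  } else row$microbe
  paste0(
    "<div class=\"detail\">",
    sprintf("<div><b>key = %d</b></div>", row$key),
    sprintf("<svg width=\"%d\" height=\"%d\">", w, h),
    sprintf(
      "<rect x=\"%d\" y=\"%d\" width=\"%d\" height=\"%d\" fill=\"none\" stroke=\"#999\"/>",
      pad, pad, w - 2 * pad, h - 2 * pad
    ),
    paste(segs, collapse = ""), paste(pts, collapse = ""),
    sprintf(
      "<text x=\"%d\" y=\"%d\" text-anchor=\"middle\" font-size=\"11\">%s</text>",
      w %/% 2, h - 8, esc(x_lab)
    ),
    sprintf(
      "<text x=\"12\" y=\"%d\" text-anchor=\"middle\" font-size=\"11\" transform=\"rotate(-90 12 %d)\">%s</text>",
      h %/% 2, h %/% 2, esc(y_lab)
    ),
    "</svg></div>"
  )
}

expand_range <- function(r, frac = 0.05) {
  if (diff(r) == 0) return(r + c(-0.5, 0.5))
  r + c(-1, 1) * frac * diff(r)
}

network_svg <- function(ns, seed, w = 560, h = 360, pad = 45) {
  lay <- network_layout(ns, seed = seed)
  ome_fill <- c(microbe = "#2ca25f", immune = "#8856a7")
  px <- function(v) pad + v * (w - 2 * pad)
  py <- function(v) h - pad - v * (h - 2 * pad)
  pos <- setNames(seq_len(nrow(lay)), lay$analyte)
  edges <- vapply(seq_len(nrow(ns$edges)), function(i) {
    a <- lay[pos[[ns$edges$microbe[i]]], ]
    b <- lay[pos[[ns$edges$immune[i]]], ]
    sprintf(
      "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#bbb\"/>",
      fmt(px(a$x)), fmt(py(a$y)), fmt(px(b$x)), fmt(py(b$y))
    )
  }, character(1))
  nodes <- vapply(seq_len(nrow(lay)), function(i) {
    paste0(
      sprintf(
        "<circle cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"%s\"/>",
        fmt(px(lay$x[i])), fmt(py(lay$y[i])),
        fmt(4 + sqrt(lay$degree[i])), ome_fill[[lay$ome[i]]]
      ),
      sprintf(
        "<text x=\"%s\" y=\"%s\" font-size=\"10\" text-anchor=\"middle\">%s</text>",
        fmt(px(lay$x[i])), fmt(py(lay$y[i]) - 9), esc(lay$analyte[i])
      )
    )
  }, character(1))
  paste0(
    sprintf("<svg width=\"%d\" height=\"%d\">", w, h),
    paste(edges, collapse = ""), paste(nodes, collapse = ""), "</svg>"
  )
}
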