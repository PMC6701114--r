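#' Bundle a screen run into an exportable document
#'
#' The screen document is the hand-off format between the statistical run
#' and any downstream viewer: the run configuration (thresholds, reference
#' cohort, cohort display colors), the top table with its per-row metrics
#' and per-cohort fitted-line geometry, and — keyed by top-table row — the
#' sample-level arrays (post-transform readout `x`, abundance `y`, cohort
#' labels, and per-observation `|DFFITS|` when diagnostics ran) needed to
#' redraw every detailed regression plot. A machine-readable schema ships
#' with the package (`system.file("schema", "screen-document.schema.json",
#' package = "omescreen")`).
#'
#' @param table A `top_table` whose rows still carry their fits.
#' @param merged The [merged_table] the screen ran on (post transform), used
#'   for integrity checks and units.
#' @param config The [run_config()].
#' @return A list of class `screen_document` with elements `config`,
#'   `top_table`, and `data`.
#' @export
as_screen_document <- function(table, merged, config) {
  stopifnot(inherits(table, "top_table"), inherits(merged, "merged_table"),
            inherits(config, "run_config"))
  known <- merged$features$feature
  missing <- setdiff(unique(c(table$microbe, table$immune)), known)
  if (length(missing) > 0) {
    os_integrity_error(sprintf(
      "top-table analyte(s) absent from the merged table: %s",
      paste(missing, collapse = ", ")
    ))
  }
  labels <- sort(unique(merged$data$cohort))
  doc_config <- list(
    referenceCohort = config$reference_cohort,
    thresholdType = config$threshold_type,
    thresholdValue = config$threshold_value,
    minNonzero = config$min_nonzero,
    immuneTransform = config$immune_transform,
    metricColumns = config$metric_columns,
    seed = config$seed,
    cohortColors = cohort_colors(labels)
  )
  units <- setNames(merged$features$units, merged$features$feature)
  data <- setNames(
    purrr::map(seq_len(nrow(table)), function(i) {
      fit <- table$fit[[i]]
      if (is.null(fit)) {
        os_integrity_error(sprintf(
          "top-table row %d has no retained fit; cannot collect sample-level data",
          i
        ))
      }
      rec <- list(
        x = fit$data$x, y = fit$data$y, cohort = fit$data$cohort,
        xUnits = units[[fit$immune]] %||% NA_character_,
        yUnits = units[[fit$microbe]] %||% NA_character_
      )
      if (!is.null(fit$dffits)) rec$influence <- abs(fit$dffits)
      rec
    }),
    as.character(table$key)
  )
  new_screen_document(doc_config, table, data)
}

new_screen_document <- function(config, top_table, data) {
  doc <- structure(
    list(config = config, top_table = top_table, data = data),
    class = "screen_document"
  )
  validate_document(doc)
}

#' Fixed qualitative palette assigned to sorted cohort labels
#' @param labels Cohort labels.
#' @return Named character vector of hex colors.
#' @export
cohort_colors <- function(labels) {
  palette <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a",
               "#66a61e", "#e6ab02", "#a6761d", "#666666")
  setNames(rep_len(palette, length(labels)), labels)
}

#' Structural validation of a screen document
#'
#' Checks the contracts the schema file states: required config fields, one
#' data record per top-table key, and equal array lengths within each
#' record.
#'
#' @param doc A `screen_document`.
#' @return The document, invisibly; aborts with a validation error otherwise.
#' @export
validate_document <- function(doc) {
  stopifnot(inherits(doc, "screen_document"))
  required <- c("referenceCohort", "thresholdType", "thresholdValue",
                "minNonzero", "immuneTransform", "metricColumns", "seed",
                "cohortColors")
  absent <- setdiff(required, names(doc$config))
  if (length(absent) > 0) {
    os_validation_error(sprintf(
      "document config lacks field(s): %s", paste(absent, collapse = ", ")
    ))
  }
  tt <- doc$top_table
  keys <- as.character(tt$key)
  if (anyDuplicated(keys)) os_validation_error("duplicate top-table keys")
  if (!setequal(keys, names(doc$data))) {
    os_validation_error("top-table keys and data records are not 1:1")
  }
  for (k in names(doc$data)) {
    rec <- doc$data[[k]]
    lens <- c(length(rec$x), length(rec$y), length(rec$cohort))
    if (!is.null(rec$influence)) lens <- c(lens, length(rec$influence))
    if (length(unique(lens)) != 1) {
      os_validation_error(sprintf(
        "data record '%s' has unequal array lengths", k
      ))
    }
  }
  invisible(doc)
}

#' @export
print.screen_document <- function(x, ...) {
  cat(sprintf(
    "<screen_document> %d relationship(s), reference cohort %s, %s < %g\n",
    nrow(x$top_table), x$config$referenceCohort,
    if (x$config$thresholdType == "fdr_p") "FDR p" else "raw p",
    x$config$thresholdValue
  ))
  invisible(x)
}

# ---------------------------------------------------------------------------
# canonical serialization: fixed key order, fixed number formatting, so that
# serialize -> parse -> serialize is byte-identical

#' Serialize a screen document to canonical JSON
#'
#' Keys are emitted in a fixed canonical order and numbers in a fixed
#' round-trip-exact format, so serializing, parsing, and serializing again
#' yields identical bytes.
#'
#' @param doc A `screen_document`.
#' @return A single JSON string (UTF-8, no trailing newline).
#' @export
document_json <- function(doc) {
  validate_document(doc)
  tt <- doc$top_table
  rows <- purrr::map(seq_len(nrow(tt)), function(i) {
    row <- list(key = tt$key[i], microbe = tt$microbe[i], immune = tt$immune[i])
    for (m in c("F", "p", "pAdj", "max_influence")) {
      if (m %in% names(tt)) {
        row[[if (m == "max_influence") "maxInfluence" else m]] <- tt[[m]][i]
      }
    }
    if ("interaction_p" %in% names(tt)) {
      ip <- tt$interaction_p[[i]]
      row$interaction_p <- if (is.null(ip)) NULL else as.list(ip)
    }
    if ("n" %in% names(tt)) row$n <- tt$n[i]
    ln <- tt$lines[[i]]
    if (!is.null(ln)) {
      row$cohortLines <- purrr::map(seq_len(nrow(ln)), function(j) {
        list(
          cohort = ln$cohort[j], intercept = ln$intercept[j],
          slope = ln$slope[j], xMin = ln$x_min[j], xMax = ln$x_max[j],
          gx0 = ln$gx0[j], gy0 = ln$gy0[j], gx1 = ln$gx1[j], gy1 = ln$gy1[j]
        )
      })
    }
    row
  })
  data <- purrr::map(doc$data[as.character(tt$key)], function(rec) {
    out <- list(x = as.list(rec$x), y = as.list(rec$y),
                cohort = as.list(rec$cohort))
    if (!is.null(rec$influence)) out$influence <- as.list(rec$influence)
    out$xUnits <- rec$xUnits
    out$yUnits <- rec$yUnits
    out
  })
  cfg <- doc$config
  body <- list(
    config = list(
      referenceCohort = cfg$referenceCohort,
      thresholdType = cfg$thresholdType,
      thresholdValue = cfg$thresholdValue,
      minNonzero = cfg$minNonzero,
      immuneTransform = cfg$immuneTransform,
      metricColumns = as.list(cfg$metricColumns),
      seed = cfg$seed,
      cohortColors = as.list(cfg$cohortColors)
    ),
    topTable = rows,
    data = data
  )
  json_emit(body)
}

# minimal canonical JSON emitter; parsing is jsonlite's job
json_emit <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    if (length(x) == 0) {
      # empty containers: named shells are objects, bare ones arrays
      return(if (is.null(names(x))) "[]" else "{}")
    }
    if (!is.null(names(x))) {
      parts <- vapply(seq_along(x), function(i) {
        paste0(json_string(names(x)[i]), ":", json_emit(x[[i]]))
      }, character(1))
      return(paste0("{", paste(parts, collapse = ","), "}"))
    }
    parts <- vapply(x, json_emit, character(1))
    return(paste0("[", paste(parts, collapse = ","), "]"))
  }
  if (length(x) != 1) {
    return(json_emit(as.list(x)))
  }
  if (is.character(x)) return(if (is.na(x)) "null" else json_string(x))
  if (is.logical(x)) {
    return(if (is.na(x)) "null" else if (x) "true" else "false")
  }
  if (is.numeric(x)) return(json_number(x))
  os_contract_error(sprintf("cannot serialize object of class %s", class(x)[1]))
}

json_string <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  paste0("\"", s, "\"")
}

json_number <- function(x) {
  if (is.na(x) || !is.finite(x)) return("null")
  if (x == floor(x) && abs(x) < 2^31) return(sprintf("%d", as.integer(x)))
  sprintf("%.17g", x)
}

#' Parse a screen document from JSON
#'
#' @param json A JSON string produced by [document_json()] (or a compatible
#'   document).
#' @return A `screen_document`.
#' @export
parse_document <- function(json) {
  lst <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  cfg <- lst$config
  cfg$metricColumns <- as.character(unlist(cfg$metricColumns))
  cfg$cohortColors <- unlist(cfg$cohortColors)
  null_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  tt <- purrr::map_dfr(lst$topTable, function(row) {
    out <- tibble(
      key = as.integer(row$key), microbe = row$microbe, immune = row$immune
    )
    if (!is.null(row$F)) out$F <- as.numeric(row$F)
    if (!is.null(row$p)) out$p <- as.numeric(row$p)
    if (!is.null(row$pAdj)) out$pAdj <- as.numeric(row$pAdj)
    if (!is.null(row$interaction_p)) {
      out$interaction_p <- list(unlist(row$interaction_p))
    }
    if ("maxInfluence" %in% names(row)) {
      out$max_influence <- null_na(row$maxInfluence)
    }
    if (!is.null(row$n)) out$n <- as.integer(row$n)
    if (!is.null(row$cohortLines)) {
      out$lines <- list(purrr::map_dfr(row$cohortLines, function(ln) {
        tibble(
          cohort = ln$cohort, intercept = as.numeric(ln$intercept),
          slope = as.numeric(ln$slope), x_min = as.numeric(ln$xMin),
          x_max = as.numeric(ln$xMax),
          gx0 = as.numeric(ln$gx0), gy0 = as.numeric(ln$gy0),
          gx1 = as.numeric(ln$gx1), gy1 = as.numeric(ln$gy1)
        )
      }))
    }
    out
  })
  if (nrow(tt) == 0) {
    tt <- tibble(key = integer(), microbe = character(), immune = character(),
                 lines = list())
  }
  class(tt) <- c("top_table", class(tt))
  data <- purrr::map(lst$data, function(rec) {
    out <- list(
      x = as.numeric(unlist(rec$x)), y = as.numeric(unlist(rec$y)),
      cohort = as.character(unlist(rec$cohort))
    )
    if (!is.null(rec$influence)) out$influence <- as.numeric(unlist(rec$influence))
    out$xUnits <- if (is.null(rec$xUnits)) NA_character_ else rec$xUnits
    out$yUnits <- if (is.null(rec$yUnits)) NA_character_ else rec$yUnits
    out
  })
  new_screen_document(cfg, tt, data)
}

#' Read/write a screen document
#' @param doc A `screen_document`.
#' @param path File path.
#' @return `write_screen_document` returns `path` invisibly;
#'   `read_screen_document` returns the parsed `screen_document`.
#' @export
write_screen_document <- function(doc, path) {
  writeLines(document_json(doc), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_screen_document
#' @export
read_screen_document <- function(path) {
  parse_document(paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                       collapse = "\n"))
}

#' Write the top table to CSV
#'
#' One row per relationship; list-columns are flattened (one
#' `interaction_p.<cohort>` column per non-reference cohort) and fitted-line
#' geometry is omitted. Numbers are written at full (round-trip)
#' precision.
#'
#' @param table A `top_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_top_table_csv <- function(table, path) {
  stopifnot(inherits(table, "top_table"))
  flat <- as_tibble(table)[, setdiff(names(table), c("lines", "fit"))]
  if ("interaction_p" %in% names(flat)) {
    cohorts <- unique(unlist(purrr::map(flat$interaction_p, names)))
    for (ch in cohorts) {
      flat[[paste0("interaction_p.", ch)]] <-
        purrr::map_dbl(flat$interaction_p, function(v) {
          if (!is.null(v) && ch %in% names(v)) v[[ch]] else NA_real_
        })
    }
    flat$interaction_p <- NULL
  }
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}
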