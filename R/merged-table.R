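#' Construct a merged two-ome sample table
#'
#' A merged table is the single input of the pairwise screen: one row per
#' sample, a cohort label per sample, and one column per analyte from either
#' ome. Microbial features are relative abundances in `[0, 1]`; immune
#' features are continuous readouts (cytokine concentrations, percent of a
#' parent cell population, ...). Feature-to-ome assignment lives in a
#' manifest tibble carried alongside the values.
#'
#' @param data A data frame with columns `sample_id`, `cohort`, then one
#'   numeric column per feature. Missing values are allowed and are dropped
#'   pairwise at fit time.
#' @param features A data frame with columns `feature`, `ome` (one of
#'   `"microbe"`, `"immune"`), and optionally `units` and
#'   `transform_applied`.
#' @return An object of class `merged_table`: a list with tibbles `data` and
#'   `features`.
#' @examples
#' tbl <- merged_table(
#'   data.frame(
#'     sample_id = c("s1", "s2", "s3", "s4"),
#'     cohort = c("A", "A", "B", "B"),
#'     mb1 = c(0, 0.2, 0.5, 0.1),
#'     il6 = c(10, 20, 15, 30)
#'   ),
#'   data.frame(feature = c("mb1", "il6"), ome = c("microbe", "immune"))
#' )
#' n_samples(tbl)
#' @export
merged_table <- function(data, features) {
  data <- as_tibble(data)
  features <- as_tibble(features)
  if (!"units" %in% names(features)) features$units <- NA_character_
  if (!"transform_applied" %in% names(features)) {
    features$transform_applied <- "none"
  }
  features <- features[, c("feature", "ome", "units", "transform_applied")]
  validate_merged_table(structure(
    list(data = data, features = features),
    class = "merged_table"
  ))
}

validate_merged_table <- function(x) {
  data <- x$data
  features <- x$features

  if (!"cohort" %in% names(data)) {
    os_input_error("merged table has no `cohort` column")
  }
  if (!"sample_id" %in% names(data)) {
    os_input_error("merged table has no `sample_id` column")
  }
  dup <- data$sample_id[duplicated(data$sample_id)]
  if (length(dup) > 0) {
    os_input_error(sprintf(
      "duplicated sample id(s): %s", paste(unique(dup), collapse = ", ")
    ))
  }
  if (length(unique(data$cohort)) < 2) {
    os_validation_error("fewer than 2 distinct cohort labels present")
  }

  bad_ome <- setdiff(unique(features$ome), c("microbe", "immune"))
  if (length(bad_ome) > 0) {
    os_validation_error(sprintf(
      "unknown ome label(s) in manifest: %s", paste(bad_ome, collapse = ", ")
    ))
  }
  if (anyDuplicated(features$feature)) {
    os_validation_error("feature names must be unique in the manifest")
  }
  value_cols <- setdiff(names(data), c("sample_id", "cohort"))
  missing_meta <- setdiff(value_cols, features$feature)
  if (length(missing_meta) > 0) {
    os_input_error(sprintf(
      "column(s) not in the feature manifest: %s",
      paste(missing_meta, collapse = ", ")
    ))
  }
  missing_col <- setdiff(features$feature, value_cols)
  if (length(missing_col) > 0) {
    os_input_error(sprintf(
      "manifest feature(s) absent from the table: %s",
      paste(missing_col, collapse = ", ")
    ))
  }
  # keep feature columns in manifest order; pair enumeration depends on it
  x$data <- data[, c("sample_id", "cohort", features$feature)]

  for (f in features$feature[features$ome == "microbe"]) {
    v <- x$data[[f]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad) > 0) {
      os_validation_error(sprintf(
        "microbe feature '%s' has value %g outside [0, 1] for sample '%s'",
        f, v[bad[1]], x$data$sample_id[bad[1]]
      ))
    }
  }
  x
}

#' Read a merged table and its feature manifest from CSV
#'
#' The merged table is a comma-separated file with a header row; the first
#' column is the sample identifier, the second the cohort label, and the
#' remaining columns are features. The manifest is a CSV with columns
#' `feature,ome` and optionally `units`.
#'
#' @param path Path to the merged table CSV.
#' @param manifest Path to the manifest CSV, or a data frame with the same
#'   columns.
#' @return A [merged_table].
#' @export
read_merged_table <- function(path, manifest) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 3) {
    os_input_error("merged table needs sample id, cohort, and >= 1 feature column")
  }
  names(raw)[1:2] <- c("sample_id", "cohort")
  raw$sample_id <- as.character(raw$sample_id)
  raw$cohort <- as.character(raw$cohort)
  if (is.character(manifest) && length(manifest) == 1) {
    manifest <- readr::read_csv(manifest, show_col_types = FALSE, progress = FALSE)
  }
  if (!all(c("feature", "ome") %in% names(manifest))) {
    os_input_error("manifest must have columns `feature` and `ome`")
  }
  merged_table(raw, manifest)
}

#' @export
print.merged_table <- function(x, ...) {
  n_mb <- sum(x$features$ome == "microbe")
  n_ir <- sum(x$features$ome == "immune")
  cat(sprintf(
    "<merged_table> %d samples, %d cohorts (%s), %d microbes, %d immune readouts\n",
    nrow(x$data), length(unique(x$data$cohort)),
    paste(sort(unique(x$data$cohort)), collapse = ", "), n_mb, n_ir
  ))
  invisible(x)
}

#' @rdname merged_table
#' @param x A `merged_table`.
#' @export
n_samples <- function(x) nrow(x$data)

#' Feature names of one ome
#' @param x A [merged_table].
#' @param ome `"microbe"` or `"immune"`.
#' @return Character vector of feature names, in manifest order.
#' @export
ome_features <- function(x, ome = c("microbe", "immune")) {
  ome <- match.arg(ome)
  x$features$feature[x$features$ome == ome]
}

#' Retain microbial features observed in enough samples
#'
#' A microbial feature is kept when it has a strictly positive relative
#' abundance in at least `min_nonzero` samples ("non-zero in at least k
#' samples"); the boundary is inclusive. Immune features are never filtered.
#'
#' @param table A [merged_table].
#' @param min_nonzero Non-negative integer; maximum is the sample count.
#' @return The filtered [merged_table]; sample rows are unchanged.
#' @export
prevalence_filter <- function(table, min_nonzero) {
  stopifnot(inherits(table, "merged_table"))
  if (length(min_nonzero) != 1 || is.na(min_nonzero) || min_nonzero < 0) {
    os_config_error("`min_nonzero` must be a single non-negative integer")
  }
  if (min_nonzero > n_samples(table)) {
    os_config_error(sprintf(
      "`min_nonzero` (%d) exceeds the sample count (%d)",
      min_nonzero, n_samples(table)
    ))
  }
  keep <- vapply(seq_len(nrow(table$features)), function(i) {
    meta <- table$features[i, ]
    if (meta$ome != "microbe") return(TRUE)
    v <- table$data[[meta$feature]]
    sum(!is.na(v) & v > 0) >= min_nonzero
  }, logical(1))
  features <- table$features[keep, ]
  structure(
    list(
      data = table$data[, c("sample_id", "cohort", features$feature)],
      features = features
    ),
    class = "merged_table"
  )
}

#' Transform all features of one ome
#'
#' Applies an elementwise transform (currently `sqrt`, used to compress the
#' dynamic range of cytokine readouts and dampen very high readings) to every
#' feature of the given ome, and records it in the manifest.
#'
#' @param table A [merged_table].
#' @param ome Which ome to transform.
#' @param transform `"none"` or `"sqrt"`.
#' @return The transformed [merged_table].
#' @export
apply_transform <- function(table, ome = c("immune", "microbe"),
                            transform = c("none", "sqrt")) {
  stopifnot(inherits(table, "merged_table"))
  ome <- match.arg(ome)
  transform <- match.arg(transform)
  if (transform == "none") return(table)
  for (f in ome_features(table, ome)) {
    v <- table$data[[f]]
    bad <- which(!is.na(v) & v < 0)
    if (length(bad) > 0) {
      os_validation_error(sprintf(
        "cannot sqrt-transform feature '%s': negative value %g for sample '%s'",
        f, v[bad[1]], table$data$sample_id[bad[1]]
      ))
    }
    table$data[[f]] <- sqrt(v)
  }
  table$features$transform_applied[table$features$ome == ome] <- transform
  table
}
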