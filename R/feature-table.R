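#' Construct a sample-by-ion feature table
#'
#' The central container of the pipeline: a numeric abundance matrix
#' (samples in rows, ions in columns, NA marking missing peaks) with
#' per-ion metadata (retention time, m/z, internal-standard flag) and
#' per-sample metadata (injection order, QC flag). Ion names follow the
#' primary-id convention `X<rt>_<mz>`.
#'
#' @param abundances Numeric matrix, samples x ions, NA = missing.
#'   Raw tables are non-negative; centered/scaled tables produced by
#'   the pipeline may hold negative values, so sign is not validated.
#' @param ion_meta data.frame with columns `ion`, `retention_time`,
#'   `mz`, `is_internal_standard`; one row per column of `abundances`.
#' @param sample_meta data.frame with columns `sample`,
#'   `injection_order`, `is_qc`; one row per row of `abundances`.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(abundances, ion_meta, sample_meta) {
  abundances <- as.matrix(abundances)
  stopifnot(
    nrow(ion_meta) == ncol(abundances),
    nrow(sample_meta) == nrow(abundances),
    all(c("ion", "retention_time", "mz", "is_internal_standard") %in%
          names(ion_meta)),
    all(c("sample", "injection_order", "is_qc") %in% names(sample_meta))
  )
  if (anyDuplicated(ion_meta$ion)) stop("ion names must be unique")
  if (any(ion_meta$retention_time < 0)) stop("retention times must be >= 0")
  if (any(ion_meta$mz <= 0)) stop("m/z must be positive")
  if (any(!is.finite(abundances) & !is.na(abundances))) {
    stop("abundances must be finite or NA")
  }
  is_cols <- which(ion_meta$is_internal_standard)
  if (length(is_cols) && anyNA(abundances[, is_cols])) {
    stop("internal standard channels must have no missing values")
  }
  colnames(abundances) <- ion_meta$ion
  rownames(abundances) <- sample_meta$sample
  rownames(ion_meta) <- NULL
  rownames(sample_meta) <- NULL
  structure(
    list(abundances = abundances, ion_meta = ion_meta,
         sample_meta = sample_meta),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "feature_table: %d samples (%d QC) x %d ions (%d internal standards), %.1f%% missing\n",
    nrow(x$abundances), sum(x$sample_meta$is_qc), ncol(x$abundances),
    sum(x$ion_meta$is_internal_standard),
    100 * mean(is.na(x$abundances))
  ))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$abundances)

# retain a subset of ion columns, preserving metadata alignment
subset_ions <- function(table, keep) {
  feature_table(
    table$abundances[, keep, drop = FALSE],
    table$ion_meta[keep, , drop = FALSE],
    table$sample_meta
  )
}

#' Write / read a feature table as CSV
#'
#' The abundance CSV holds samples in rows and ions in columns; ion
#' metadata and sample metadata travel in sidecar CSVs
#' `<stem>_ions.csv` and `<stem>_samples.csv`.
#'
#' @param table A [feature_table()].
#' @param path Path of the abundance CSV; sidecars are derived from it.
#' @export
write_feature_csv <- function(table, path) {
  stem <- sub("\\.csv$", "", path)
  df <- data.frame(sample = table$sample_meta$sample,
                   table$abundances, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(table$ion_meta, paste0(stem, "_ions.csv"), row.names = FALSE)
  utils::write.csv(table$sample_meta, paste0(stem, "_samples.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  stem <- sub("\\.csv$", "", path)
  df <- utils::read.csv(path, check.names = FALSE)
  ab <- as.matrix(df[, -1, drop = FALSE])
  feature_table(
    ab,
    utils::read.csv(paste0(stem, "_ions.csv")),
    utils::read.csv(paste0(stem, "_samples.csv"))
  )
}
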