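#' Relative mass defect of an ion
#'
#' RMD = (mz - floor(mz)) / mz * 1e6, in ppm. Lipid ions cluster in a
#' characteristic RMD band (roughly 350-950 ppm), which is used to strip
#' non-lipid ions from an untargeted feature table before statistics.
#'
#' @param mz m/z in Th, > 0 (vectorized).
#' @return RMD in ppm.
#' @examples
#' relative_mass_defect(564.3289)  # 582.9 ppm
#' @export
relative_mass_defect <- function(mz) {
  if (any(mz <= 0)) stop("m/z must be positive")
  (mz - floor(mz)) / mz * 1e6
}

#' Relative-mass-defect filter
#'
#' Retains ions whose RMD lies in the closed interval `[low, high]`
#' (ions strictly below `low` or strictly above `high` are excluded).
#' Internal-standard channels are never dropped here; they are separated
#' from the analyte matrix later in the pipeline.
#'
#' @param table A [feature_table()].
#' @param low,high RMD band in ppm (defaults 350 and 950).
#' @return List with `table` (filtered) and `excluded` (ion names).
#' @export
rmd_filter <- function(table, low = 350, high = 950) {
  if (low >= high) stop("rmd filter requires low < high")
  rmd <- relative_mass_defect(table$ion_meta$mz)
  keep <- (rmd >= low & rmd <= high) | table$ion_meta$is_internal_standard
  list(table = subset_ions(table, keep),
       excluded = table$ion_meta$ion[!keep])
}

#' Missingness filter
#'
#' Drops ions whose fraction of missing values is strictly greater than
#' `max_missing` (default 0.20; an ion missing in 26/126 samples is
#' excluded, one missing in 25/126 is retained).
#'
#' @param table A [feature_table()].
#' @param max_missing Maximum tolerated missing proportion.
#' @return List with `table` and `excluded` ion names.
#' @export
missingness_filter <- function(table, max_missing = 0.20) {
  frac <- colMeans(is.na(table$abundances))
  keep <- frac <= max_missing
  list(table = subset_ions(table, keep),
       excluded = table$ion_meta$ion[!keep])
}

#' Mean imputation of missing abundances
#'
#' Each missing cell is replaced by the mean of that ion's observed
#' values; observed cells are unchanged.
#'
#' @param table A [feature_table()]; every ion must have at least one
#'   observed value.
#' @return The imputed [feature_table()].
#' @export
mean_impute <- function(table) {
  ab <- table$abundances
  n_obs <- colSums(!is.na(ab))
  if (any(n_obs == 0L)) {
    stop("all-missing ion(s): ",
         paste(table$ion_meta$ion[n_obs == 0L], collapse = ", "))
  }
  mu <- colMeans(ab, na.rm = TRUE)
  idx <- which(is.na(ab), arr.ind = TRUE)
  if (nrow(idx)) ab[idx] <- mu[idx[, 2]]
  table$abundances <- ab
  table
}

#' Internal-standard normalization
#'
#' Divides every analyte abundance by the named internal standard's
#' abundance in the same sample (removing shared injection-order drift),
#' then removes all internal-standard channels from the analyte matrix.
#'
#' @param table A [feature_table()].
#' @param is_name Ion name of the normalizing standard
#'   (default `"PC(8:0/8:0)"`).
#' @return Normalized [feature_table()] without IS channels.
#' @export
is_normalize <- function(table, is_name = "PC(8:0/8:0)") {
  j <- match(is_name, table$ion_meta$ion)
  if (is.na(j)) stop("internal standard not found: ", is_name)
  is_sig <- table$abundances[, j]
  bad <- which(is.na(is_sig) | is_sig <= 0)
  if (length(bad)) {
    stop("internal standard missing or nonpositive in sample(s): ",
         paste(table$sample_meta$sample[bad], collapse = ", "))
  }
  table$abundances <- table$abundances / is_sig
  subset_ions(table, !table$ion_meta$is_internal_standard)
}

#' Pareto scaling
#'
#' Centers each ion at its mean and divides by the square root of its
#' standard deviation — the metabolomics compromise between unit
#' variance and no scaling (the variance of a Pareto-scaled column
#' equals the standard deviation of the original column).
#'
#' @param table A [feature_table()] with no missing values.
#' @return Scaled [feature_table()].
#' @export
pareto_scale <- function(table) {
  ab <- table$abundances
  if (anyNA(ab)) stop("pareto_scale requires a complete matrix; impute first")
  s <- apply(ab, 2, stats::sd)
  zero <- s == 0
  if (any(zero)) {
    stop("zero-variance ion(s): ",
         paste(table$ion_meta$ion[zero], collapse = ", "))
  }
  table$abundances <- scale(ab, center = TRUE, scale = sqrt(s))
  attr(table$abundances, "scaled:center") <- NULL
  attr(table$abundances, "scaled:scale") <- NULL
  table
}

#' Per-ion coefficient of variation over QC injections
#'
#' @param table A [feature_table()] with at least 2 QC-flagged samples.
#' @return Named numeric vector, CV in percent (sd/mean * 100) per ion.
#' @export
qc_cv <- function(table) {
  qc <- table$sample_meta$is_qc
  if (sum(qc) < 2L) stop("need at least 2 QC samples")
  m <- table$abundances[qc, , drop = FALSE]
  100 * apply(m, 2, stats::sd, na.rm = TRUE) /
    colMeans(m, na.rm = TRUE)
}

#' Full preprocessing pipeline with accounting report
#'
#' Runs, in the pipeline's canonical order: RMD filter, missingness
#' filter, internal-standard split, mean imputation, IS normalization,
#' and (optionally) Pareto scaling, and returns the processed analyte
#' table together with a `processing_report` whose counts satisfy
#' `n_input_ions = n_rmd_excluded + n_missing_excluded + n_is_split +
#' n_retained`.
#'
#' @param table Raw aligned [feature_table()].
#' @param is_name Normalizing internal standard.
#' @param rmd_low,rmd_high RMD retention band (ppm).
#' @param max_missing Missingness cut (strict >).
#' @param pareto Apply Pareto scaling after normalization (default TRUE).
#' @param drop_qc Drop QC rows from the returned analysis table
#'   (default TRUE; the QC CVs are computed first).
#' @return List with `table` (processed) and `report`
#'   (class `processing_report`).
#' @export
preprocess <- function(table, is_name = "PC(8:0/8:0)", rmd_low = 350,
                       rmd_high = 950, max_missing = 0.20, pareto = TRUE,
                       drop_qc = TRUE) {
  n_input <- ncol(table$abundances)
  st1 <- rmd_filter(table, rmd_low, rmd_high)
  st2 <- missingness_filter(st1$table, max_missing)
  n_is <- sum(st2$table$ion_meta$is_internal_standard)
  imputed <- mean_impute(st2$table)
  normalized <- is_normalize(imputed, is_name)
  cv <- if (sum(normalized$sample_meta$is_qc) >= 2L) qc_cv(normalized) else NULL
  if (drop_qc) {
    keep <- !normalized$sample_meta$is_qc
    normalized <- feature_table(
      normalized$abundances[keep, , drop = FALSE],
      normalized$ion_meta,
      normalized$sample_meta[keep, , drop = FALSE]
    )
  }
  out <- if (pareto) pareto_scale(normalized) else normalized
  report <- structure(
    list(
      n_input_ions = n_input,
      n_rmd_excluded = length(st1$excluded),
      n_missing_excluded = length(st2$excluded),
      n_is_split = n_is,
      n_retained = ncol(out$abundances),
      qc_cv_per_ion = cv
    ),
    class = "processing_report"
  )
  stopifnot(report$n_input_ions == report$n_rmd_excluded +
              report$n_missing_excluded + report$n_is_split +
              report$n_retained)
  list(table = out, report = report)
}

#' @export
print.processing_report <- function(x, ...) {
  cat(sprintf(
    paste0("processing_report: %d input ions -> %d RMD-excluded, ",
           "%d missingness-excluded, %d IS split, %d retained\n"),
    x$n_input_ions, x$n_rmd_excluded, x$n_missing_excluded,
    x$n_is_split, x$n_retained
  ))
  if (!is.null(x$qc_cv_per_ion)) {
    cat(sprintf("  median QC CV: %.2f%%\n",
                stats::median(x$qc_cv_per_ion, na.rm = TRUE)))
  }
  invisible(x)
}

#' Write a processing report as JSON
#'
#' @param report A `processing_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
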