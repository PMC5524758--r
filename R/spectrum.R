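#' Construct a negative-mode MS/MS spectrum
#'
#' @param precursor_mz Precursor m/z (Th).
#' @param peaks data.frame or 2-column matrix of fragment `mz`,
#'   `intensity`; stored sorted by m/z.
#' @param retention_time Retention time (min), optional.
#' @param title Optional label (e.g. the generating lipid name).
#' @return Object of class `msms_spectrum`.
#' @export
msms_spectrum <- function(precursor_mz, peaks, retention_time = NA_real_,
                          title = "") {
  peaks <- as.data.frame(peaks)
  names(peaks)[1:2] <- c("mz", "intensity")
  if (any(peaks$intensity < 0)) stop("intensities must be >= 0")
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(
    list(precursor_mz = precursor_mz, peaks = peaks, polarity = "negative",
         retention_time = retention_time, title = title),
    class = "msms_spectrum"
  )
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat(sprintf("msms_spectrum '%s': precursor %.4f (negative), %d peaks\n",
              x$title, x$precursor_mz, nrow(x$peaks)))
  invisible(x)
}

#' Write spectra to an MGF file (negative mode)
#'
#' @param spectra A single `msms_spectrum` or a list of them.
#' @param path Output file.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "msms_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$title), con)
    writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
    writeLines("CHARGE=1-", con)
    if (!is.na(sp$retention_time)) {
      writeLines(sprintf("RTINSECONDS=%.2f", sp$retention_time * 60), con)
    }
    writeLines(sprintf("%.6f %.4f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read spectra from an MGF file
#'
#' @param path MGF file with BEGIN IONS/END IONS blocks.
#' @return List of `msms_spectrum` objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) stop("malformed MGF: ", path)
  lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[is_kv], "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, "", 1L))
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
    pk <- do.call(rbind, lapply(strsplit(trimws(block[!is_kv]), "[ \t]+"),
                                function(x) as.numeric(x[1:2])))
    rt <- if ("RTINSECONDS" %in% keys) {
      as.numeric(vals[keys == "RTINSECONDS"][1]) / 60
    } else NA_real_
    msms_spectrum(
      precursor_mz = as.numeric(strsplit(vals[keys == "PEPMASS"][1], " ")[[1]][1]),
      peaks = data.frame(mz = pk[, 1], intensity = pk[, 2]),
      retention_time = rt,
      title = if ("TITLE" %in% keys) vals[keys == "TITLE"][1] else ""
    )
  })
}

#' Read one spectrum from a simple CSV peak list
#'
#' Expects columns `mz`, `intensity`; the precursor is passed separately.
#'
#' @param path CSV file.
#' @inheritParams msms_spectrum
#' @export
read_spectrum_csv <- function(path, precursor_mz, retention_time = NA_real_) {
  df <- utils::read.csv(path)
  if (!all(c("mz", "intensity") %in% names(df))) {
    stop("spectrum CSV needs columns mz, intensity")
  }
  msms_spectrum(precursor_mz, df[, c("mz", "intensity")], retention_time)
}
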