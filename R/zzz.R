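#' @useDynLib LipidLens, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.onLoad <- function(libname, pkgname) {
  # every diagnostic constant must reproduce its reference value from
  # first principles; a mismatch aborts package load
  validate_diagnostics()
}
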