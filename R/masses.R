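#' Monoisotopic element masses
#'
#' IUPAC/CODATA monoisotopic masses (Da) for the elements occurring in
#' glycerophospholipids, plus the proton and electron masses used in
#' negative-mode adduct arithmetic. All diagnostic m/z values in the
#' annotation rules are derived from this table at load time; none is
#' hard coded.
#'
#' @return Named numeric vector with elements C, H, N, O, P, S and the
#'   entries `proton` and `electron`.
#' @export
element_masses <- function() {
  c(
    C = 12.0,
    H = 1.00782503207,
    N = 14.0030740048,
    O = 15.9949146196,
    P = 30.97376163,
    S = 31.97207100,
    proton = 1.007276466879,
    electron = 0.00054857990907
  )
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula Either a string such as `"C2H4O2"` or a named numeric
#'   vector of element counts, e.g. `c(C = 2, H = 4, O = 2)`.
#' @return Monoisotopic mass in Da. An empty formula has mass 0.
#' @examples
#' monoisotopic_mass("C2H4O2")  # methyl formate, 60.0211
#' monoisotopic_mass("H2O")     # 18.0106
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (length(counts) == 0L) return(0)
  if (any(counts < 0)) stop("element counts must be nonnegative")
  em <- element_masses()
  unknown <- setdiff(names(counts), setdiff(names(em), c("proton", "electron")))
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  }
  sum(em[names(counts)] * counts)
}

# "C2H4O2" -> c(C = 2, H = 4, O = 2); single-letter elements only (CHNOPS)
parse_formula <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- trimws(s)
  if (!nzchar(s)) return(numeric(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  parts <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(nchar(parts)) != nchar(s)) stop("cannot parse formula: ", s)
  el <- sub("[0-9]*$", "", parts)
  n <- as.numeric(ifelse(grepl("[0-9]", parts), sub("^[A-Za-z]+", "", parts), "1"))
  tapply(n, el, sum)[unique(el)]
}

#' Carboxylate anion m/z of a fatty acyl chain
#'
#' The fatty acid CnH(2n-2d)O2 loses a proton to give the carboxylate
#' anion observed in negative-mode MS/MS of glycerophospholipids; e.g.
#' 18:2 gives 279.233 and 20:4 gives 303.233.
#'
#' @param carbons Chain length (>= 2).
#' @param double_bonds Number of double bonds, `0 <= d <= carbons/2`.
#' @return m/z (Th) of the carboxylate anion.
#' @export
fa_anion_mz <- function(carbons, double_bonds) {
  if (any(carbons < 2) || any(double_bonds < 0) ||
      any(double_bonds > carbons / 2)) {
    stop("invalid fatty acyl chain ", carbons, ":", double_bonds)
  }
  em <- element_masses()
  neutral <- carbons * em["C"] + (2 * carbons - 2 * double_bonds) * em["H"] +
    2 * em["O"]
  unname(neutral - em["proton"])
}

#' Negative-mode adduct m/z from a neutral monoisotopic mass
#'
#' @param neutral_mass Neutral monoisotopic mass M (Da), > 0.
#' @param adduct `"[M-H]-"` (deprotonation) or `"[M+HCOO]-"` (formate).
#' @return Ion m/z: `M - 1.007276` or `M + 44.998201`.
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (any(neutral_mass <= 0)) stop("neutral mass must be positive")
  em <- element_masses()
  shift <- switch(adduct,
    "[M-H]-" = -em[["proton"]],
    "[M+HCOO]-" = em[["C"]] + em[["H"]] + 2 * em[["O"]] + em[["electron"]],
    stop("unknown adduct: ", adduct)
  )
  neutral_mass + shift
}

#' Head-group diagnostic rules for negative-mode glycerophospholipids
#'
#' The four class rules used to call the head group from an MS/MS
#' spectrum, each computed from element masses:
#' \itemize{
#'   \item PC (and LPC): neutral loss of methyl formate C2H4O2, 60.0211 Da,
#'     from the formate (or demethylation of the [M-H]- surrogate) precursor;
#'   \item PE (and LPE): ethanolamine phosphate fragment anion at 140.0118;
#'   \item PI: inositol phosphate minus water fragment anion at 241.0119;
#'   \item PS (and LPS): neutral loss of serine minus water, 87.0320 Da.
#' }
#'
#' @return data.frame with columns `class` ("PC","PE","PI","PS"),
#'   `kind` ("loss" or "fragment") and `mz` (Da for losses, Th for
#'   fragment anions).
#' @export
headgroup_diagnostics <- function() {
  em <- element_masses()
  pc_loss <- monoisotopic_mass("C2H4O2")
  pe_frag <- monoisotopic_mass("C2H8NO4P") - em[["proton"]]
  pi_frag <- monoisotopic_mass("C6H13O9P") - monoisotopic_mass("H2O") -
    em[["proton"]]
  ps_loss <- monoisotopic_mass("C3H7NO3") - monoisotopic_mass("H2O")
  data.frame(
    class = c("PC", "PE", "PI", "PS"),
    kind = c("loss", "fragment", "fragment", "loss"),
    mz = c(pc_loss, pe_frag, pi_frag, ps_loss),
    stringsAsFactors = FALSE
  )
}

# ether-PC diagnostic chains with their literature m/z; the theory-derived
# value (demethylated ether-LPC anion) must agree within 5 mDa at load
.ether_reference <- data.frame(
  chain = c("O-16:0", "O-16:1", "O-18:0", "O-18:1"),
  carbons = c(16L, 16L, 18L, 18L),
  double_bonds = c(0L, 1L, 0L, 1L),
  mz = c(466.3303, 464.3147, 494.3616, 492.3460),
  stringsAsFactors = FALSE
)

#' Diagnostic fragment m/z for ether-linked PC chains
#'
#' The O-alkyl chain of an ether PC is confirmed by the demethylated
#' ether-LPC fragment anion: glycerophosphocholine + CcH(2c-2d) alkyl
#' minus a methyl radical, carrying one electron. Only the four chains
#' with reported reference values are supported; the computed values are
#' asserted against the references at package load.
#'
#' @param chain One of `"O-16:0"`, `"O-16:1"`, `"O-18:0"`, `"O-18:1"`.
#' @return Fragment m/z (Th).
#' @export
ether_fragment_mz <- function(chain) {
  i <- match(chain, .ether_reference$chain)
  if (is.na(i)) stop("unsupported ether chain: ", chain)
  .ether_theoretical(.ether_reference$carbons[i], .ether_reference$double_bonds[i])
}

.ether_theoretical <- function(carbons, double_bonds) {
  em <- element_masses()
  gpc <- monoisotopic_mass("C8H20NO6P")
  alkyl <- carbons * em[["C"]] + (2 * carbons - 2 * double_bonds) * em[["H"]]
  ch3 <- em[["C"]] + 3 * em[["H"]]
  gpc + alkyl - ch3 + em[["electron"]]
}

# Load-time self check: every diagnostic constant recomputed from element
# masses must agree with its printed reference value. A failure aborts.
validate_diagnostics <- function() {
  hd <- headgroup_diagnostics()
  ref <- c(PC = 60.02, PE = 140.01, PI = 241.01, PS = 87.03)
  bad <- abs(hd$mz - ref[hd$class]) >= 0.005
  if (any(bad)) {
    stop("head-group diagnostic(s) disagree with reference: ",
         paste(hd$class[bad], collapse = ", "))
  }
  fa_ref <- rbind(
    c(16, 0, 255.233), c(17, 0, 269.248), c(18, 0, 283.264),
    c(18, 1, 281.248), c(18, 2, 279.233), c(18, 3, 277.217),
    c(20, 1, 309.279), c(20, 2, 307.264), c(20, 3, 305.248),
    c(20, 4, 303.233), c(20, 5, 301.217), c(22, 5, 329.248),
    c(22, 6, 327.233)
  )
  fa_err <- abs(fa_anion_mz(fa_ref[, 1], fa_ref[, 2]) - fa_ref[, 3])
  # printed values are truncated at 3 dp, so allow one unit in the last place
  if (any(fa_err >= 0.001)) stop("fatty acyl diagnostic mass check failed")
  eth_err <- abs(vapply(.ether_reference$chain, ether_fragment_mz, 0) -
                   .ether_reference$mz)
  if (any(eth_err >= 0.005)) stop("ether diagnostic mass check failed")
  invisible(TRUE)
}
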