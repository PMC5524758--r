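#' Parse a shorthand glycerophospholipid name
#'
#' Supported classes: diacyl PC, PE, PI, PS (two chains, optionally one
#' O-alkyl ether chain for PC), and the lysophospholipids LPC, LPE, LPS
#' (one chain). Chains are written `c:d` (`O-c:d` for ethers) and joined
#' with `_` because the sn-position is never assigned, e.g.
#' `"PC(O-16:1_18:2)"`, `"LPE(18:2)"`.
#'
#' @param name Shorthand string.
#' @return List with `class`, and `chains` — a data.frame with columns
#'   `linkage` ("acyl"/"ether"), `carbons`, `double_bonds`.
#' @export
parse_lipid_name <- function(name) {
  m <- regmatches(name, regexec("^(L?P[CEIS])\\(([^)]+)\\)$", name))[[1]]
  if (length(m) == 0L) stop("cannot parse lipid name: ", name)
  class <- m[2]
  if (!class %in% c("PC", "PE", "PI", "PS", "LPC", "LPE", "LPS")) {
    stop("unsupported lipid class: ", class)
  }
  parts <- strsplit(m[3], "_", fixed = TRUE)[[1]]
  chains <- lapply(parts, function(p) {
    cm <- regmatches(p, regexec("^(O-)?([0-9]+):([0-9]+)$", p))[[1]]
    if (length(cm) == 0L) stop("cannot parse chain '", p, "' in ", name)
    data.frame(
      linkage = if (nzchar(cm[2])) "ether" else "acyl",
      carbons = as.integer(cm[3]),
      double_bonds = as.integer(cm[4]),
      stringsAsFactors = FALSE
    )
  })
  chains <- do.call(rbind, chains)
  n_expected <- if (startsWith(class, "L")) 1L else 2L
  if (nrow(chains) != n_expected) {
    stop(class, " requires ", n_expected, " chain(s), got ", nrow(chains))
  }
  if (any(chains$linkage == "ether") && class != "PC") {
    stop("ether chains are only supported for PC")
  }
  if (sum(chains$linkage == "ether") > 1L) stop("at most one ether chain")
  list(class = class, chains = chains)
}

# glycerophospho-head-group residue masses (neutral, with both hydroxyls free)
.backbone_formula <- c(
  PC = "C8H20NO6P", PE = "C5H14NO6P", PS = "C6H14NO8P", PI = "C9H19O11P"
)

#' Neutral monoisotopic mass of a parsed or shorthand lipid
#'
#' Built as glycerophospho-backbone + acyl residues (fatty acid minus
#' water per esterification) + at most one O-alkyl residue.
#'
#' @param lipid Shorthand string or result of [parse_lipid_name()].
#' @return Neutral monoisotopic mass (Da).
#' @export
lipid_neutral_mass <- function(lipid) {
  if (is.character(lipid)) lipid <- parse_lipid_name(lipid)
  em <- element_masses()
  base_class <- sub("^L", "", lipid$class)
  mass <- monoisotopic_mass(.backbone_formula[[base_class]])
  h2o <- monoisotopic_mass("H2O")
  for (i in seq_len(nrow(lipid$chains))) {
    ch <- lipid$chains[i, ]
    hyd <- 2 * ch$carbons - 2 * ch$double_bonds
    if (ch$linkage == "acyl") {
      mass <- mass + ch$carbons * em[["C"]] + hyd * em[["H"]] + 2 * em[["O"]] - h2o
    } else {
      mass <- mass + ch$carbons * em[["C"]] + hyd * em[["H"]]
    }
  }
  mass
}

#' Theoretical precursor m/z for a lipid under a negative-mode adduct
#'
#' @inheritParams lipid_neutral_mass
#' @param adduct `"[M-H]-"` or `"[M+HCOO]-"`.
#' @export
lipid_precursor_mz <- function(lipid, adduct) {
  adduct_mz(lipid_neutral_mass(lipid), adduct)
}

# canonical shorthand: ether chain first, then acyls by (carbons, db)
canonical_lipid_name <- function(class, chains) {
  ord <- order(chains$linkage != "ether", chains$carbons, chains$double_bonds)
  chains <- chains[ord, , drop = FALSE]
  lab <- paste0(ifelse(chains$linkage == "ether", "O-", ""),
                chains$carbons, ":", chains$double_bonds)
  paste0(class, "(", paste(lab, collapse = "_"), ")")
}

#' Primary id of a feature from retention time and m/z
#'
#' Features are keyed "X<rt>_<mz>" with rt printed to 2 decimals and m/z
#' to 4, e.g. `primary_id(1.17, 564.3289)` is `"X1.17_564.3289"`.
#'
#' @param retention_time Retention time in minutes, >= 0.
#' @param mz m/z in Th.
#' @export
primary_id <- function(retention_time, mz) {
  if (any(retention_time < 0)) stop("retention time must be >= 0")
  sprintf("X%.2f_%.4f", retention_time, mz)
}
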