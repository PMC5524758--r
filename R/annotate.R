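#' Rule-based annotation of a negative-mode phospholipid MS/MS spectrum
#'
#' Applies the head-group rules (PC: methyl formate loss 60.0211 Da;
#' PE: ethanolamine phosphate fragment 140.0118; PI: inositol
#' phosphate - H2O fragment 241.0119; PS: serine loss 87.0320), collects
#' all fatty acyl carboxylate and ether-PC diagnostic matches, enumerates
#' the chain combinations whose theoretical precursor under either
#' negative-mode adduct matches the observed precursor within 0.05 Da,
#' and returns the candidate with the smallest absolute precursor mass
#' error. Lysophospholipid classes (LPC/LPE/LPS) are assigned when a
#' single chain explains the precursor. If no rule fires, or no chain
#' combination fits, the head group is `"unknown"`.
#'
#' @param spectrum An [msms_spectrum()] (negative polarity).
#' @param tolerance Fragment match tolerance in Da (default 0.01).
#' @param precursor_tolerance Precursor mass-error bound in Da
#'   (default 0.05, the acceptance bound for identified lipids).
#' @return A `lipid_annotation`: list with `head_group`, `chains`
#'   (data.frame linkage/carbons/double_bonds, NULL if unknown),
#'   `adduct`, `theoretical_mz`, `mass_error` (observed - theoretical),
#'   and `name`.
#' @export
annotate <- function(spectrum, tolerance = 0.01, precursor_tolerance = 0.05) {
  if (!inherits(spectrum, "msms_spectrum")) stop("need an msms_spectrum")
  if (!identical(spectrum$polarity, "negative")) {
    stop("only negative-mode spectra are supported")
  }
  if (is.null(spectrum$precursor_mz) || is.na(spectrum$precursor_mz)) {
    stop("spectrum has no precursor m/z")
  }
  prec <- spectrum$precursor_mz
  pk <- spectrum$peaks$mz

  unknown <- structure(
    list(head_group = "unknown", chains = NULL, adduct = NA_character_,
         theoretical_mz = NA_real_, mass_error = NA_real_, name = "unknown"),
    class = "lipid_annotation"
  )

  hd <- headgroup_diagnostics()
  fired <- character(0)
  for (i in seq_len(nrow(hd))) {
    hit <- if (hd$kind[i] == "loss") {
      any(abs((prec - pk) - hd$mz[i]) <= tolerance)
    } else {
      any(abs(pk - hd$mz[i]) <= tolerance)
    }
    if (hit) fired <- c(fired, hd$class[i])
  }
  if (length(fired) == 0L) return(unknown)

  acyls <- .match_acyl_chains(pk, tolerance)
  ethers <- .match_ether_chains(pk, tolerance)

  cands <- .enumerate_candidates(fired, acyls, ethers, prec, precursor_tolerance)
  if (nrow(cands) == 0L) return(unknown)
  cands <- cands[order(abs(cands$err), cands$name, cands$adduct), , drop = FALSE]
  best <- cands[1L, ]
  parsed <- parse_lipid_name(best$name)
  structure(
    list(head_group = parsed$class, chains = parsed$chains,
         adduct = best$adduct, theoretical_mz = best$theo,
         mass_error = best$err, name = best$name),
    class = "lipid_annotation"
  )
}

#' @export
print.lipid_annotation <- function(x, ...) {
  if (x$head_group == "unknown") {
    cat("lipid_annotation: unknown\n")
  } else {
    cat(sprintf("lipid_annotation: %s %s theoretical %.4f (mass error %+.4f)\n",
                x$name, x$adduct, x$theoretical_mz, x$mass_error))
  }
  invisible(x)
}

# all (carbons, double_bonds) acyl chains whose carboxylate matches a peak
.match_acyl_chains <- function(peak_mz, tolerance,
                               carbon_range = c(4L, 30L), max_db = 8L) {
  out <- list()
  for (c_ in seq(carbon_range[1], carbon_range[2])) {
    for (d_ in 0:min(max_db, c_ %/% 2)) {
      if (any(abs(peak_mz - fa_anion_mz(c_, d_)) <= tolerance)) {
        out[[length(out) + 1L]] <- c(c_, d_)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(carbons = integer(0), double_bonds = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(carbons = m[, 1], double_bonds = m[, 2])
}

.match_ether_chains <- function(peak_mz, tolerance) {
  ref <- .ether_reference
  hit <- vapply(ref$chain, function(ch) {
    any(abs(peak_mz - ether_fragment_mz(ch)) <= tolerance)
  }, logical(1))
  ref[hit, , drop = FALSE]
}

.enumerate_candidates <- function(classes, acyls, ethers, prec, prec_tol) {
  rows <- list()
  add <- function(class, chains) {
    name <- canonical_lipid_name(class, chains)
    neutral <- lipid_neutral_mass(list(class = class, chains = chains))
    for (ad in c("[M-H]-", "[M+HCOO]-")) {
      theo <- adduct_mz(neutral, ad)
      err <- prec - theo
      if (abs(err) <= prec_tol) {
        rows[[length(rows) + 1L]] <<- data.frame(
          name = name, adduct = ad, theo = theo, err = err,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  na <- nrow(acyls)
  for (cl in classes) {
    # lysophospholipid: a single acyl chain (no LPI in the supported set)
    if (cl %in% c("PC", "PE", "PS") && na > 0L) {
      for (i in seq_len(na)) {
        add(paste0("L", cl), data.frame(
          linkage = "acyl", carbons = acyls$carbons[i],
          double_bonds = acyls$double_bonds[i], stringsAsFactors = FALSE
        ))
      }
    }
    # diacyl: unordered pairs of matched acyls, repeats allowed
    if (na > 0L) {
      for (i in seq_len(na)) {
        for (j in i:na) {
          add(cl, data.frame(
            linkage = c("acyl", "acyl"),
            carbons = acyls$carbons[c(i, j)],
            double_bonds = acyls$double_bonds[c(i, j)],
            stringsAsFactors = FALSE
          ))
        }
      }
    }
    # ether PC: one matched ether chain + one matched acyl
    if (cl == "PC" && nrow(ethers) > 0L && na > 0L) {
      for (i in seq_len(nrow(ethers))) {
        for (j in seq_len(na)) {
          add("PC", data.frame(
            linkage = c("ether", "acyl"),
            carbons = c(ethers$carbons[i], acyls$carbons[j]),
            double_bonds = c(ethers$double_bonds[i], acyls$double_bonds[j]),
            stringsAsFactors = FALSE
          ))
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(name = character(0), adduct = character(0),
                      theo = numeric(0), err = numeric(0)))
  }
  unique(do.call(rbind, rows))
}

#' Annotate a batch of spectra and tabulate the results
#'
#' @param spectra List of [msms_spectrum()] objects.
#' @inheritParams annotate
#' @return data.frame with one row per spectrum: `primary_id` (from the
#'   spectrum retention time and precursor where available), `name`,
#'   `adduct`, `theoretical_mz`, `mass_error`.
#' @export
annotate_spectra <- function(spectra, tolerance = 0.01,
                             precursor_tolerance = 0.05) {
  rows <- lapply(spectra, function(sp) {
    an <- annotate(sp, tolerance, precursor_tolerance)
    data.frame(
      primary_id = if (!is.na(sp$retention_time)) {
        primary_id(sp$retention_time, sp$precursor_mz)
      } else NA_character_,
      name = an$name,
      adduct = if (is.na(an$adduct)) NA_character_ else an$adduct,
      theoretical_mz = an$theoretical_mz,
      mass_error = an$mass_error,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
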