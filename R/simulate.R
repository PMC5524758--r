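#' Cohort specification for the synthetic-data generator
#'
#' Defaults reproduce the study population the pipeline targets: 126
#' males aged 48-65 (mean 56.9, sd 4.7 before truncation), with smoking
#' recorded as ever / never / unknown in proportions 25.40 / 57.14 /
#' 17.46 percent.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param age_mean,age_sd Normal age parameters (years).
#' @param age_range Truncation interval (years).
#' @param smoking_probs Named proportions for (ever, never, unknown);
#'   must sum to 1.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 126, age_mean = 56.9, age_sd = 4.7,
                        age_range = c(48, 65),
                        smoking_probs = c(ever = 0.2540, never = 0.5714,
                                          unknown = 0.1746)) {
  if (n_subjects < 3) stop("need at least 3 subjects")
  if (abs(sum(smoking_probs) - 1) > 1e-9) {
    stop("smoking_probs must sum to 1")
  }
  if (any(smoking_probs < 0)) stop("smoking_probs must be nonnegative")
  if (age_range[1] >= age_range[2]) stop("invalid age_range")
  structure(list(n_subjects = n_subjects, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 smoking_probs = smoking_probs),
            class = "cohort_spec")
}

#' Generate a synthetic cohort (covariates only)
#'
#' Ages are drawn from a truncated normal (inverse-CDF method, so the
#' draw is exact and deterministic under a seed); smoking is sampled
#' from the specified category proportions.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return data.frame with columns `subject`, `age`, `smoking` (factor
#'   with reference level "never").
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects
  lo <- stats::pnorm(spec$age_range[1], spec$age_mean, spec$age_sd)
  hi <- stats::pnorm(spec$age_range[2], spec$age_mean, spec$age_sd)
  age <- stats::qnorm(stats::runif(n, lo, hi), spec$age_mean, spec$age_sd)
  smoking <- factor(
    sample(names(spec$smoking_probs), n, replace = TRUE,
           prob = spec$smoking_probs),
    levels = c("never", "ever", "unknown")
  )
  data.frame(subject = sprintf("S%03d", seq_len(n)), age = age,
             smoking = smoking, stringsAsFactors = FALSE)
}

#' Feature panel specification
#'
#' Defaults emulate the aligned untargeted panel the pipeline was built
#' for: 4,802 ions of which 10 are internal standards; the in-band RMD
#' fraction defaults to 2881/4802 so that, with 1,126 ions assigned
#' >20% missingness, the canonical accounting 4,802 -> 1,126 excluded +
#' 10 IS + 1,745 retained holds exactly on the default table.
#'
#' @param n_ions Total ions in the aligned table.
#' @param n_internal_standards Number of IS channels (< n_ions).
#' @param rmd_in_range_fraction Fraction of analyte ions generated
#'   inside the RMD band [350, 950] ppm.
#' @param missing_fraction_high Fraction of ions assigned >20%
#'   missingness (placed only among in-band analytes; counts are exact).
#' @param drift_magnitude Log-scale injection-order slope shared by all
#'   channels including the IS (0 = no drift).
#' @param abundance_log_sd Total per-ion log-scale biological +
#'   technical sd of analyte channels across subjects (0.5 ~ 50% CV,
#'   typical of untargeted peak areas).
#' @param n_factors Number of latent co-regulation factors shared
#'   across analyte ions (lipid classes and pathways make untargeted
#'   features strongly correlated; without this structure the lipidome
#'   kernel degenerates towards the identity and whole-lipidome
#'   variance is unidentifiable).
#' @param factor_share Fraction of each analyte ion's subject-level
#'   log-variance carried by the shared factors (loadings are random,
#'   so realized per-ion communality varies around this).
#' @param is_log_sd Log-normal noise sd of the spiked internal-standard
#'   channels (default 0.05, ~5% CV: a standard is only usable as a
#'   normalizer because its biological variance is nil).
#' @param n_qc Number of pooled-QC injections interleaved in the run.
#' @param qc_log_sd Log-normal noise sd of QC injections (default 0.03,
#'   i.e. ~3% CV, matching a well-behaved instrument).
#' @return List of class `feature_panel_spec`.
#' @export
feature_panel_spec <- function(n_ions = 4802, n_internal_standards = 10,
                               rmd_in_range_fraction = 2881 / 4802,
                               missing_fraction_high = 1126 / 4802,
                               drift_magnitude = 0.3,
                               abundance_log_sd = 0.5,
                               n_factors = 20, factor_share = 0.7,
                               is_log_sd = 0.05,
                               n_qc = 13, qc_log_sd = 0.03) {
  if (n_internal_standards >= n_ions) stop("n_internal_standards < n_ions required")
  if (rmd_in_range_fraction < 0 || rmd_in_range_fraction > 1) {
    stop("rmd_in_range_fraction must be in [0, 1]")
  }
  if (missing_fraction_high < 0 || missing_fraction_high > 1) {
    stop("missing_fraction_high must be in [0, 1]")
  }
  if (factor_share < 0 || factor_share >= 1) {
    stop("factor_share must be in [0, 1)")
  }
  structure(list(n_ions = n_ions,
                 n_internal_standards = n_internal_standards,
                 rmd_in_range_fraction = rmd_in_range_fraction,
                 missing_fraction_high = missing_fraction_high,
                 drift_magnitude = drift_magnitude,
                 abundance_log_sd = abundance_log_sd,
                 n_factors = n_factors, factor_share = factor_share,
                 is_log_sd = is_log_sd,
                 n_qc = n_qc, qc_log_sd = qc_log_sd),
            class = "feature_panel_spec")
}

# m/z with a prescribed relative mass defect: frac = rmd*M/(1e6 - rmd)
.mz_with_rmd <- function(int_part, rmd_ppm) {
  int_part + rmd_ppm * int_part / (1e6 - rmd_ppm)
}

#' Generate a synthetic aligned feature table
#'
#' Abundances are log-normal per ion with a multiplicative
#' injection-order drift shared between analytes and the internal
#' standards (so IS normalization is exactly corrective). Missingness is
#' MCAR with exact per-ion counts; ions flagged high-missingness exceed
#' the 20% cut by construction and all lie inside the RMD band so they
#' reach the missingness filter. QC injections are interleaved every
#' 10th position. The first internal standard is the normalization
#' channel "PC(8:0/8:0)"; analyte ions are named `X<rt>_<mz>`.
#'
#' @param spec A [feature_panel_spec()].
#' @param cohort A cohort data.frame from [generate_cohort()].
#' @param seed Optional integer seed.
#' @return A [feature_table()].
#' @export
generate_feature_table <- function(spec = feature_panel_spec(),
                                   cohort = generate_cohort(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(cohort) == 0L) stop("cohort must be nonempty")
  n_sub <- nrow(cohort)
  n_qc <- spec$n_qc
  n_samp <- n_sub + n_qc
  n_is <- spec$n_internal_standards
  n_analyte <- spec$n_ions - n_is
  # the in-band fraction is read against the full panel (IS channels are
  # in-band by construction), so the default reproduces the canonical
  # accounting: in-band analytes = round(f * n_ions) - n_is
  n_in <- round(spec$rmd_in_range_fraction * spec$n_ions) - n_is
  n_in <- max(0L, min(n_analyte, n_in))
  n_out <- n_analyte - n_in

  in_band <- c(rep(TRUE, n_in), rep(FALSE, n_out))
  int_part <- integer(n_analyte)
  rmd <- numeric(n_analyte)
  int_part[in_band] <- sample(150:1000, n_in, replace = TRUE)
  rmd[in_band] <- stats::runif(n_in, 360, 940)
  if (n_out > 0) {
    low_side <- stats::runif(n_out) < 0.5
    rmd[!in_band] <- ifelse(low_side, stats::runif(n_out, 30, 320),
                            stats::runif(n_out, 1000, 1300))
    int_part[!in_band] <- ifelse(low_side,
                                 sample(150:1000, n_out, replace = TRUE),
                                 sample(150:600, n_out, replace = TRUE))
  }
  mz <- .mz_with_rmd(int_part, rmd)
  rt <- stats::runif(n_analyte, 0.5, 15)
  ion <- primary_id(rt, mz)
  while (anyDuplicated(ion)) {
    dup <- duplicated(ion)
    rt[dup] <- stats::runif(sum(dup), 0.5, 15)
    ion <- primary_id(rt, mz)
  }

  is_mass <- adduct_mz(lipid_neutral_mass("PC(8:0_8:0)"), "[M+HCOO]-")
  is_meta <- data.frame(
    ion = c("PC(8:0/8:0)", sprintf("IS_%02d", seq_len(n_is)[-1])),
    retention_time = stats::runif(n_is, 0.5, 15),
    mz = c(is_mass, .mz_with_rmd(sample(150:1000, n_is - 1, replace = TRUE),
                                 stats::runif(n_is - 1, 360, 940))),
    is_internal_standard = TRUE, stringsAsFactors = FALSE
  )
  ion_meta <- rbind(
    is_meta,
    data.frame(ion = ion, retention_time = rt, mz = mz,
               is_internal_standard = FALSE, stringsAsFactors = FALSE)
  )

  # injection schedule: QC after every 10th study sample, QC first
  order_all <- seq_len(n_samp)
  qc_pos <- unique(round(seq(1, n_samp, length.out = n_qc)))
  while (length(qc_pos) < n_qc) {
    qc_pos <- union(qc_pos, sample(setdiff(order_all, qc_pos), 1))
  }
  is_qc <- order_all %in% qc_pos
  sample_meta <- data.frame(
    sample = character(n_samp), injection_order = order_all,
    is_qc = is_qc, stringsAsFactors = FALSE
  )
  sample_meta$sample[!is_qc] <- cohort$subject
  sample_meta$sample[is_qc] <- sprintf("QC%02d", seq_len(sum(is_qc)))

  log_base <- stats::rnorm(spec$n_ions, log(1e5), 1)
  drift <- exp(spec$drift_magnitude *
                 (order_all - (n_samp + 1) / 2) / n_samp)
  # subject-level co-regulation: latent factors load on analyte ions
  # only (IS channels are spiked standards, QC rows are one pooled
  # sample, so neither carries biological variation)
  idio_sd <- spec$abundance_log_sd * sqrt(1 - spec$factor_share)
  noise_sd <- outer(ifelse(is_qc, spec$qc_log_sd, idio_sd),
                    rep(1, spec$n_ions))
  noise_sd[, seq_len(n_is)] <- pmin(noise_sd[, seq_len(n_is)], spec$is_log_sd)
  logab <- matrix(log_base, n_samp, spec$n_ions, byrow = TRUE) +
    matrix(stats::rnorm(n_samp * spec$n_ions), n_samp) * noise_sd
  if (spec$n_factors > 0 && spec$factor_share > 0) {
    k <- spec$n_factors
    # factor strengths decay harmonically: a few dominant lipid-class
    # axes plus progressively weaker ones, as in real untargeted data
    w <- (1 / seq_len(k)) / sum(1 / seq_len(k))
    loadings <- matrix(stats::rnorm(k * n_analyte), k, n_analyte) *
      (spec$abundance_log_sd * sqrt(spec$factor_share * w))
    fac <- matrix(0, n_samp, k)
    fac[!is_qc, ] <- matrix(stats::rnorm(n_sub * k), n_sub, k)
    logab[, (n_is + 1L):spec$n_ions] <-
      logab[, (n_is + 1L):spec$n_ions] + fac %*% loadings
  }
  ab <- exp(logab) * drift

  # exact MCAR missingness, subject rows only, never in IS channels
  n_high <- round(spec$missing_fraction_high * spec$n_ions)
  in_band_cols <- n_is + which(in_band)
  if (n_high > length(in_band_cols)) {
    stop("not enough in-band analyte ions for requested high-missingness count")
  }
  high_cols <- sample(in_band_cols, n_high)
  low_cols <- setdiff((n_is + 1L):spec$n_ions, high_cols)
  subj_rows <- which(!is_qc)
  cut <- floor(0.20 * n_samp)
  for (j in high_cols) {
    k <- sample((cut + 1L):min(floor(0.45 * n_samp), length(subj_rows)), 1L)
    ab[sample(subj_rows, k), j] <- NA
  }
  for (j in low_cols) {
    k <- round(stats::runif(1, 0, 0.6) * cut)
    if (k > 0) ab[sample(subj_rows, k), j] <- NA
  }

  feature_table(ab, ion_meta, sample_meta)
}

#' Trait generation specification
#'
#' @param variance_fraction Target fraction of trait variance carried by
#'   the lipidome term u = X alpha, in [0, 1).
#' @param n_causal_lipids Number of lipids with nonzero effects
#'   (NULL = all lipids, the dense whole-lipidome regime).
#' @param effect_size Relative magnitude of causal effects before the
#'   variance-targeting rescale.
#' @param covariate_effects List with `age` (slope per year) and
#'   `smoking` (named offsets for ever/unknown relative to never).
#' @param sigma_e Residual standard deviation.
#' @return List of class `trait_gen_spec`.
#' @export
trait_gen_spec <- function(variance_fraction = 0.5, n_causal_lipids = 50,
                           effect_size = 1,
                           covariate_effects = list(
                             age = 0.05,
                             smoking = c(ever = 0.5, unknown = 0.2)
                           ),
                           sigma_e = 1) {
  if (variance_fraction < 0 || variance_fraction >= 1) {
    stop("variance_fraction must be in [0, 1)")
  }
  structure(list(variance_fraction = variance_fraction,
                 n_causal_lipids = n_causal_lipids,
                 effect_size = effect_size,
                 covariate_effects = covariate_effects,
                 sigma_e = sigma_e),
            class = "trait_gen_spec")
}

#' Generate a trait under the additive lipidome variance model
#'
#' y = b0 + age*b1 + smoking offsets + u + e with u = X alpha, where X
#' is the column-standardized abundance matrix of the subject rows.
#' alpha is rescaled so the sample variance of u equals
#' `f/(1-f) * sigma_e^2` exactly, making the targeted variance fraction
#' hold up to the Monte-Carlo fluctuation of var(e).
#'
#' @param spec A [trait_gen_spec()].
#' @param features A [feature_table()] whose non-QC rows align with
#'   `cohort` (any processing state; columns are standardized
#'   internally, IS channels are ignored).
#' @param cohort Cohort data.frame.
#' @param seed Optional integer seed.
#' @return List of class `trait_sim`: `value` (named trait vector),
#'   and `truth` with `alpha`, `causal_ions`, `u`, `epsilon`, and
#'   `realized_fraction` = var(u)/(var(u)+var(e)).
#' @export
generate_traits <- function(spec = trait_gen_spec(), features, cohort,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keep_rows <- !features$sample_meta$is_qc
  keep_cols <- !features$ion_meta$is_internal_standard
  X <- features$abundances[keep_rows, keep_cols, drop = FALSE]
  if (nrow(X) != nrow(cohort)) {
    stop("feature table subject rows do not match cohort")
  }
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  s <- apply(X, 2, stats::sd)
  ok <- s > 0
  X <- scale(X[, ok, drop = FALSE])
  m <- ncol(X)
  n <- nrow(X)
  n_causal <- if (is.null(spec$n_causal_lipids)) m else spec$n_causal_lipids
  if (n_causal > m) stop("n_causal_lipids exceeds available lipids")

  alpha <- numeric(m)
  names(alpha) <- colnames(X)
  u <- numeric(n)
  if (spec$variance_fraction > 0 && n_causal > 0) {
    causal <- sample(m, n_causal)
    alpha[causal] <- spec$effect_size *
      sample(c(-1, 1), n_causal, replace = TRUE)
    u0 <- drop(X %*% alpha)
    target_var <- spec$variance_fraction / (1 - spec$variance_fraction) *
      spec$sigma_e^2
    c_ <- sqrt(target_var / stats::var(u0))
    alpha <- alpha * c_
    u <- u0 * c_
  }
  eps <- stats::rnorm(n, 0, spec$sigma_e)
  ce <- spec$covariate_effects
  smoke_off <- c(never = 0, ce$smoking)[as.character(cohort$smoking)]
  y <- 10 + ce$age * cohort$age + smoke_off + u + eps
  names(y) <- cohort$subject
  structure(
    list(value = y,
         truth = list(alpha = alpha,
                      causal_ions = names(alpha)[alpha != 0],
                      u = u, epsilon = eps,
                      realized_fraction =
                        stats::var(u) / (stats::var(u) + stats::var(eps)))),
    class = "trait_sim"
  )
}

#' Generate a synthetic negative-mode MS/MS spectrum for a lipid
#'
#' The inverse of [annotate()]: emits the theoretical precursor, the
#' head-group diagnostic (as a loss peak for PC/PS classes, as the
#' fragment ion for PE/PI), one carboxylate anion per acyl chain, the
#' ether diagnostic ion for an O- chain, and `noise_peaks` random peaks
#' kept at least 25 mDa away from every diagnostic m/z (including the
#' whole carboxylate grid) so the diagnostic match set is unchanged.
#'
#' @param lipid_name Shorthand name parseable by [parse_lipid_name()].
#' @param adduct `"[M-H]-"` or `"[M+HCOO]-"`.
#' @param noise_peaks Number of non-diagnostic peaks to add.
#' @param seed Optional integer seed.
#' @param retention_time Optional rt (min) stored on the spectrum.
#' @return An [msms_spectrum()] titled with the canonical lipid name.
#' @export
generate_msms_spectrum <- function(lipid_name, adduct, noise_peaks = 0,
                                   seed = NULL, retention_time = NA_real_) {
  if (!is.null(seed)) set.seed(seed)
  lipid <- parse_lipid_name(lipid_name)
  prec <- lipid_precursor_mz(lipid, adduct)
  hd <- headgroup_diagnostics()
  base_class <- sub("^L", "", lipid$class)
  rule <- hd[hd$class == base_class, ]
  head_mz <- if (rule$kind == "loss") prec - rule$mz else rule$mz
  chain_mz <- vapply(seq_len(nrow(lipid$chains)), function(i) {
    ch <- lipid$chains[i, ]
    if (ch$linkage == "acyl") {
      fa_anion_mz(ch$carbons, ch$double_bonds)
    } else {
      ether_fragment_mz(sprintf("O-%d:%d", ch$carbons, ch$double_bonds))
    }
  }, 0)
  mzs <- c(prec, head_mz, chain_mz)
  ints <- c(100, 40, rep(60, length(chain_mz)))

  if (noise_peaks > 0) {
    protected <- c(mzs, prec - hd$mz[hd$kind == "loss"],
                   hd$mz[hd$kind == "fragment"],
                   vapply(.ether_reference$chain, ether_fragment_mz, 0),
                   unlist(lapply(4:30, function(c_) {
                     vapply(0:min(8, c_ %/% 2),
                            function(d_) fa_anion_mz(c_, d_), 0)
                   })))
    noise <- numeric(0)
    while (length(noise) < noise_peaks) {
      cand <- stats::runif(noise_peaks, 80, prec - 5)
      ok <- vapply(cand, function(x) all(abs(x - protected) > 0.025),
                   logical(1))
      noise <- c(noise, cand[ok])
    }
    noise <- noise[seq_len(noise_peaks)]
    mzs <- c(mzs, noise)
    ints <- c(ints, stats::runif(noise_peaks, 1, 10))
  }
  msms_spectrum(prec, data.frame(mz = mzs, intensity = ints),
                retention_time = retention_time,
                title = canonical_lipid_name(lipid$class, lipid$chains))
}
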