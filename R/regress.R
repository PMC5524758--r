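#' Declared trait transformations
#'
#' The pipeline's transformation scheme: natural log for leptin, total
#' adiponectin, C-peptide, IL-6, TNF-alpha and IP-10; identity for BMI,
#' WC and MCP-1.
#'
#' @return Named character vector mapping trait name to "log" or
#'   "identity".
#' @export
trait_transforms <- function() {
  c(BMI = "identity", WC = "identity", leptin = "log",
    adiponectin = "log", c_peptide = "log", IL6 = "log",
    TNFa = "log", IP10 = "log", MCP1 = "identity")
}

#' Apply declared transformations to trait columns
#'
#' Log-transformed traits with zeros present get a natural log with
#' offset equal to the smallest positive observed value of that trait
#' (recorded in the `"offsets"` attribute); negative values error.
#'
#' @param traits data.frame of trait columns (covariates untouched).
#' @param transforms Named scheme as from [trait_transforms()]; only
#'   names present in `traits` are used.
#' @return The transformed data.frame, with attributes `"transforms"`
#'   and `"offsets"`.
#' @export
transform_traits <- function(traits, transforms = trait_transforms()) {
  transforms <- transforms[names(transforms) %in% names(traits)]
  offsets <- stats::setNames(numeric(length(transforms)), names(transforms))
  for (nm in names(transforms)) {
    if (transforms[[nm]] == "log") {
      x <- traits[[nm]]
      if (any(x < 0, na.rm = TRUE)) {
        stop("negative values in log-transformed trait ", nm)
      }
      off <- if (any(x == 0, na.rm = TRUE)) min(x[x > 0], na.rm = TRUE) else 0
      offsets[nm] <- off
      traits[[nm]] <- log(x + off)
    }
  }
  attr(traits, "transforms") <- transforms
  attr(traits, "offsets") <- offsets
  traits
}

# design matrix for the covariate adjustment: intercept + age + smoking
# dummies (reference = never)
covariate_design <- function(covariates) {
  smoking <- covariates$smoking
  if (!is.factor(smoking)) {
    smoking <- factor(smoking, levels = c("never", "ever", "unknown"))
  }
  smoking <- droplevels(smoking)
  X <- cbind(`(Intercept)` = 1, age = covariates$age)
  if (nlevels(smoking) > 1L) {
    mm <- stats::model.matrix(~smoking)[, -1, drop = FALSE]
    X <- cbind(X, mm)
  }
  X
}

#' Single-lipid regression (one trait, one lipid)
#'
#' Ordinary least squares of trait = intercept + age + smoking + lipid,
#' reporting the lipid effect, its two-sided t-test p-value, and the
#' residual degrees of freedom. A rank-deficient fit (e.g. a constant
#' lipid) returns a flagged record with NA effect and p.
#'
#' @param trait Transformed response vector (no missing values).
#' @param covariates data.frame with `age` and `smoking`.
#' @param lipid Lipid abundance vector (typically Pareto scaled).
#' @param ion Optional ion id stored on the record.
#' @return One-row data.frame: `ion`, `effect`, `se`, `p`, `df`,
#'   `flagged`.
#' @export
fit_single_lipid <- function(trait, covariates, lipid, ion = NA_character_) {
  if (anyNA(trait) || anyNA(lipid)) stop("missing values in trait or lipid")
  X <- cbind(covariate_design(covariates), lipid = lipid)
  n <- nrow(X)
  p <- ncol(X)
  if (n < p + 2) stop("too few observations for the model")
  qr_ <- qr(X)
  if (qr_$rank < p) {
    return(data.frame(ion = ion, effect = NA_real_, se = NA_real_,
                      p = NA_real_, df = n - qr_$rank, flagged = TRUE,
                      stringsAsFactors = FALSE))
  }
  coef_ <- qr.coef(qr_, trait)
  res <- trait - drop(X %*% coef_)
  df <- n - p
  sigma2 <- sum(res^2) / df
  XtXinv_jj <- chol2inv(qr.R(qr_))[p, p]
  se <- sqrt(sigma2 * XtXinv_jj)
  tval <- coef_[p] / se
  data.frame(ion = ion, effect = unname(coef_[p]), se = se,
             p = 2 * stats::pt(-abs(tval), df), df = df, flagged = FALSE,
             stringsAsFactors = FALSE)
}

# Frisch-Waugh residualization: regress each column of M on X0, return
# residuals; used to vectorize thousands of single-lipid fits
.residualize <- function(M, qr0) {
  M - qr.fitted(qr0, M)
}

#' All single-lipid regressions for a set of traits
#'
#' For every trait and every ion, fits the age- and smoking-adjusted
#' single-lipid model and adjusts p-values within trait by
#' Benjamini-Hochberg and Bonferroni over the ions. Computation uses
#' Frisch-Waugh residualization (equivalent to the full OLS fit, tested
#' against [fit_single_lipid()]), so thousands of lipids are fit in one
#' pass.
#'
#' @param traits data.frame of (already transformed) trait columns.
#' @param covariates data.frame with `age` and `smoking`, same rows.
#' @param table Processed [feature_table()] (no missing values).
#' @return List with `records` (data.frame: trait, ion, effect, se, p,
#'   bh_fdr, bonferroni, df, flagged) and `effects` (ions x traits
#'   matrix of lipid effects for the biplot).
#' @export
run_all_regressions <- function(traits, covariates, table) {
  L <- table$abundances
  if (anyNA(L)) stop("feature table has missing values; preprocess first")
  X0 <- covariate_design(covariates)
  stopifnot(nrow(X0) == nrow(L))
  qr0 <- qr(X0)
  n <- nrow(L)
  p_full <- ncol(X0) + 1L
  df <- n - p_full

  Lr <- .residualize(L, qr0)
  ss_l <- colSums(Lr^2)
  flagged <- ss_l <= 1e-12 * n

  records <- vector("list", length(names(traits)))
  effects <- matrix(NA_real_, ncol(L), ncol(traits),
                    dimnames = list(colnames(L), names(traits)))
  for (k in seq_along(names(traits))) {
    tr <- names(traits)[k]
    y <- traits[[tr]]
    yr <- .residualize(y, qr0)
    beta <- colSums(Lr * yr) / ss_l
    res_ss <- pmax(sum(yr^2) - beta^2 * ss_l, 0)
    sigma2 <- res_ss / df
    se <- sqrt(sigma2 / ss_l)
    tval <- beta / se
    pval <- 2 * stats::pt(-abs(tval), df)
    beta[flagged] <- NA
    se[flagged] <- NA
    pval[flagged] <- NA
    effects[, k] <- beta
    records[[k]] <- data.frame(
      trait = tr, ion = colnames(L), effect = beta, se = se, p = pval,
      bh_fdr = bh_fdr(pval), bonferroni = bonferroni_adjust(pval),
      df = df, flagged = flagged, stringsAsFactors = FALSE,
      row.names = NULL
    )
  }
  list(records = do.call(rbind, records), effects = effects)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard BH step-up with monotonicity enforcement; NAs are carried
#' through and do not count toward the number of tests.
#'
#' @param pvalues Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  .check_p(pvalues)
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  m <- length(p)
  out <- rep(NA_real_, length(pvalues))
  if (m > 0L) {
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))[order(o)]
    out[ok] <- adj
  }
  out
}

#' Bonferroni adjusted p-values
#'
#' @inheritParams bh_fdr
#' @export
bonferroni_adjust <- function(pvalues) {
  .check_p(pvalues)
  m <- sum(!is.na(pvalues))
  pmin(1, pvalues * m)
}

.check_p <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  invisible(TRUE)
}

#' Significant-lipid overlaps across traits
#'
#' Computes, for a subset of traits, the per-trait significant ion sets
#' at `alpha` under the chosen p-value column, and the count of every
#' exclusive Venn region (2^k regions for k traits).
#'
#' @param records The `records` data.frame from [run_all_regressions()].
#' @param traits Character vector of trait names to intersect.
#' @param threshold `"raw"`, `"bh_fdr"` or `"bonferroni"`.
#' @param alpha Significance cut (default 0.05).
#' @return List of class `overlap_result`: `sets` (named list of ion
#'   vectors), `regions` (data.frame with one row per exclusive region:
#'   membership pattern and count), and `n_common` (all-way
#'   intersection size).
#' @export
venn_overlaps <- function(records, traits, threshold = c("bh_fdr", "raw",
                                                         "bonferroni"),
                          alpha = 0.05) {
  threshold <- match.arg(threshold)
  missing_tr <- setdiff(traits, unique(records$trait))
  if (length(missing_tr)) {
    stop("unknown trait(s): ", paste(missing_tr, collapse = ", "))
  }
  col <- c(raw = "p", bh_fdr = "bh_fdr", bonferroni = "bonferroni")[threshold]
  sets <- lapply(traits, function(tr) {
    r <- records[records$trait == tr, ]
    r$ion[!is.na(r[[col]]) & r[[col]] < alpha]
  })
  names(sets) <- traits
  universe <- unique(unlist(sets))
  k <- length(traits)
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(patterns) <- traits
  counts <- apply(patterns, 1, function(pat) {
    if (length(universe) == 0L) return(0L)
    sum(apply(member, 1, function(row) all(row == pat)))
  })
  regions <- cbind(patterns, count = as.integer(counts))
  structure(
    list(sets = sets, regions = regions,
         n_common = if (length(universe)) {
           sum(apply(member, 1, all))
         } else 0L),
    class = "overlap_result"
  )
}

#' Cohort summary by BMI category
#'
#' Splits subjects into lean (BMI < 25), overweight (25 <= BMI < 30) and
#' obese (BMI >= 30), reports the median [range] of each parameter per
#' group, the Kruskal-Wallis test across groups, Dunn's pairwise
#' rank-sum z-tests with BH adjustment, and a compact letter display
#' (groups sharing a letter are not significantly different).
#'
#' @param traits data.frame of per-subject parameters including `BMI`.
#' @param parameters Columns to summarize (default: all numeric columns).
#' @param alpha Significance level for the letter display.
#' @return data.frame of class `cohort_summary` with one row per
#'   parameter x group plus per-parameter KW statistics; also carries a
#'   `"pairwise"` attribute with the Dunn z, raw and BH-adjusted p.
#' @export
cohort_summary <- function(traits, parameters = NULL, alpha = 0.05) {
  if (!"BMI" %in% names(traits)) stop("BMI column required")
  group <- cut(traits$BMI, c(-Inf, 25, 30, Inf), right = FALSE,
               labels = c("lean", "overweight", "obese"))
  if (is.null(parameters)) {
    parameters <- names(traits)[vapply(traits, is.numeric, TRUE)]
  }
  small <- table(group) < 2
  if (any(small)) {
    warning("group(s) with <2 members excluded from pairwise tests: ",
            paste(names(small)[small], collapse = ", "))
  }
  rows <- list()
  pairwise <- list()
  for (par in parameters) {
    x <- traits[[par]]
    kw <- stats::kruskal.test(x, group)
    dunn <- dunn_test(x, group, exclude_small = TRUE)
    letters <- compact_letters(dunn, levels(group), alpha)
    for (g in levels(group)) {
      xi <- x[group == g]
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = par, group = g, n = length(xi),
        median = stats::median(xi), min = min(xi), max = max(xi),
        kw_statistic = unname(kw$statistic), kw_p = kw$p.value,
        letter = letters[[g]], stringsAsFactors = FALSE
      )
    }
    dunn$parameter <- par
    pairwise[[par]] <- dunn
  }
  out <- do.call(rbind, rows)
  attr(out, "pairwise") <- do.call(rbind, pairwise)
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Dunn's pairwise rank-sum z-tests
#'
#' Post-hoc comparisons after Kruskal-Wallis: for groups i, j the
#' statistic is the difference in mean ranks divided by
#' sqrt((N(N+1)/12 - tie correction) * (1/ni + 1/nj)); two-sided normal
#' p-values, BH adjusted across the pairs.
#'
#' @param x Numeric vector.
#' @param group Grouping factor.
#' @param exclude_small Drop groups with fewer than 2 members.
#' @return data.frame with `group1`, `group2`, `z`, `p`, `bh_fdr`.
#' @export
dunn_test <- function(x, group, exclude_small = TRUE) {
  group <- droplevels(as.factor(group))
  if (exclude_small) {
    keep <- group %in% names(which(table(group) >= 2))
    x <- x[keep]
    group <- droplevels(group[keep])
  }
  N <- length(x)
  r <- rank(x)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, group, mean)
  n_g <- tapply(r, group, length)
  g <- levels(group)
  pairs <- utils::combn(g, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / n_g[[pr[1]]] + 1 / n_g[[pr[2]]]))
    (mean_rank[[pr[1]]] - mean_rank[[pr[2]]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             bh_fdr = bh_fdr(p), stringsAsFactors = FALSE, row.names = NULL)
}

# compact letter display by insert-and-absorb: groups not significantly
# different (BH-adjusted p >= alpha) may share a letter
compact_letters <- function(pairwise, groups, alpha = 0.05) {
  sig <- function(a, b) {
    hit <- (pairwise$group1 == a & pairwise$group2 == b) |
      (pairwise$group1 == b & pairwise$group2 == a)
    any(hit) && any(pairwise$bh_fdr[hit] < alpha, na.rm = TRUE)
  }
  blocks <- list()
  for (g in groups) {
    placed <- FALSE
    for (i in seq_along(blocks)) {
      if (!any(vapply(blocks[[i]], function(h) sig(g, h), TRUE))) {
        blocks[[i]] <- c(blocks[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) blocks[[length(blocks) + 1L]] <- g
  }
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(blocks)) {
    for (g in blocks[[i]]) out[g] <- paste0(out[g], LETTERS[i])
  }
  out
}

#' Cross-reference an untargeted phospholipid against targeted FAME data
#'
#' Fits log(PL abundance) = log(% FA isomer) + BMI by OLS and reports
#' the log-log effect with its p-value, plus the companion Spearman
#' correlation between the two measures.
#'
#' @param pl_abundance Positive lipid abundance vector.
#' @param fa_percent Positive %-of-total-FA vector, same subjects.
#' @param bmi BMI covariate vector.
#' @return List: `effect`, `se`, `p`, `spearman_rho`, `spearman_p`, `n`.
#' @export
fame_crossref <- function(pl_abundance, fa_percent, bmi) {
  if (length(pl_abundance) != length(fa_percent) ||
      length(pl_abundance) != length(bmi)) {
    stop("inputs must have equal length")
  }
  if (any(pl_abundance <= 0) || any(fa_percent <= 0)) {
    stop("pl_abundance and fa_percent must be strictly positive for logs")
  }
  fit <- stats::lm(log(pl_abundance) ~ log(fa_percent) + bmi)
  sm <- summary(fit)$coefficients
  ct <- suppressWarnings(
    stats::cor.test(pl_abundance, fa_percent, method = "spearman")
  )
  list(effect = sm["log(fa_percent)", "Estimate"],
       se = sm["log(fa_percent)", "Std. Error"],
       p = sm["log(fa_percent)", "Pr(>|t|)"],
       spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
       n = length(bmi))
}

#' Manhattan plot table for one trait
#'
#' Emits the plot-ready table (retention time, -log10 p, significance
#' flag) restricted to the informative retention window for display;
#' no records are dropped from the underlying results.
#'
#' @param records `records` from [run_all_regressions()].
#' @param table The [feature_table()] supplying retention times.
#' @param trait Trait name.
#' @param rt_window Display window in minutes (default c(0.5, 11.5)).
#' @param alpha BH-FDR significance cut for the flag.
#' @return data.frame: `ion`, `retention_time`, `neg_log10_p`,
#'   `significant`.
#' @export
manhattan_table <- function(records, table, trait,
                            rt_window = c(0.5, 11.5), alpha = 0.05) {
  r <- records[records$trait == trait, ]
  rt <- table$ion_meta$retention_time[match(r$ion, table$ion_meta$ion)]
  keep <- rt >= rt_window[1] & rt <= rt_window[2] & !is.na(r$p)
  data.frame(ion = r$ion[keep], retention_time = rt[keep],
             neg_log10_p = -log10(r$p[keep]),
             significant = r$bh_fdr[keep] < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}
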