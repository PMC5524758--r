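test_that("single-lipid OLS matches the normal-equations oracle to 1e-10", {
  set.seed(31)
  n <- 8
  cov <- data.frame(
    age = c(50, 52, 55, 57, 60, 61, 63, 64),
    smoking = factor(c("never", "ever", "never", "unknown", "ever",
                       "never", "never", "unknown"),
                     levels = c("never", "ever", "unknown"))
  )
  lipid <- c(-1.2, 0.4, 0.8, -0.3, 1.5, -0.7, 0.2, 0.9)
  y <- 3 + 0.1 * cov$age + 0.5 * lipid + c(0.1, -0.2, 0.05, 0.3, -0.1,
                                           0.2, -0.3, 0.1)
  rec <- fit_single_lipid(y, cov, lipid)
  X <- cbind(1, cov$age, model.matrix(~smoking, cov)[, -1], lipid)
  oracle <- ols_oracle(y, X)
  expect_equal(rec$effect, unname(oracle$beta[5]), tolerance = 1e-10)
  expect_equal(rec$p, unname(oracle$p[5]), tolerance = 1e-10)
  expect_identical(rec$df, oracle$df)
  # constant lipid -> flagged record, not an error
  flg <- fit_single_lipid(y, cov, rep(1, n))
  expect_true(flg$flagged)
  expect_true(is.na(flg$p))
})

test_that("a lipid equal to the covariate-adjusted residual is a perfect hit", {
  set.seed(32)
  panel <- small_panel(seed = 33, n_subjects = 50, n_ions = 40)
  y <- rnorm(50)
  X0 <- LipidLens:::covariate_design(panel$cohort)
  resid <- lm.fit(X0, y)$residuals
  rec <- fit_single_lipid(y, panel$cohort, resid / sqrt(sd(resid)))
  expect_gt(rec$effect, 0)
  expect_lt(rec$p, 1e-20)
})

test_that("vectorized regressions agree with per-lipid fits and have the right shape", {
  panel <- small_panel(seed = 34, n_subjects = 40, n_ions = 60)
  set.seed(35)
  traits <- data.frame(BMI = rnorm(40), WC = rnorm(40))
  out <- run_all_regressions(traits, panel$cohort, panel$processed)
  m <- ncol(panel$processed$abundances)
  expect_identical(dim(out$effects), c(m, 2L))
  expect_identical(nrow(out$records), 2L * m)
  for (j in c(1L, m %/% 2L, m)) {
    rec <- fit_single_lipid(traits$WC, panel$cohort,
                            panel$processed$abundances[, j])
    row <- out$records[out$records$trait == "WC", ][j, ]
    expect_equal(row$effect, rec$effect, tolerance = 1e-10)
    expect_equal(row$p, rec$p, tolerance = 1e-10)
  }
})

test_that("null lipids give approximately uniform p-values", {
  panel <- small_panel(seed = 36, n_subjects = 126, n_ions = 250,
                       n_factors = 0)
  set.seed(37)
  y <- rnorm(126)
  out <- run_all_regressions(data.frame(y = y), panel$cohort,
                             panel$processed)
  p <- out$records$p
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 1e-3)
})

test_that("BH step-up matches examples and the reference implementation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(38)
  for (i in 1:50) {
    m <- sample(1:200, 1)
    p <- round(runif(m), sample(c(1, 3, 6), 1))  # induce ties
    expect_equal(bh_fdr(p), p.adjust(p, "BH"))
    expect_equal(bonferroni_adjust(p), p.adjust(p, "bonferroni"))
  }
  # order invariance
  p <- runif(40)
  o <- sample(40)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))
  # bonferroni dominates raw; BH never exceeds bonferroni
  expect_true(all(bonferroni_adjust(p) >= p))
  expect_true(all(bh_fdr(p) <= bonferroni_adjust(p) + 1e-12))
})

test_that("power configuration: the causal lipids have the smallest p-values", {
  cohort <- generate_cohort(cohort_spec(n_subjects = 126), seed = 40)
  spec <- feature_panel_spec(n_ions = 400, n_internal_standards = 2,
                             rmd_in_range_fraction = 1,
                             missing_fraction_high = 0,
                             n_factors = 0, n_qc = 3)
  features <- generate_feature_table(spec, cohort, seed = 41)
  proc <- preprocess(features)$table
  ts <- generate_traits(trait_gen_spec(variance_fraction = 0.9,
                                       n_causal_lipids = 5),
                        proc, cohort, seed = 42)
  out <- run_all_regressions(data.frame(y = ts$value), cohort, proc)
  top5 <- out$records$ion[order(out$records$p)][1:5]
  expect_setequal(top5, ts$truth$causal_ions)
  # permuted trait: nothing survives BH-FDR
  set.seed(43)
  hits <- vapply(1:10, function(i) {
    yp <- sample(ts$value)
    r <- run_all_regressions(data.frame(y = yp), cohort, proc)
    sum(r$records$bh_fdr < 0.05, na.rm = TRUE)
  }, 0)
  expect_gte(mean(hits == 0), 0.9)
})

test_that("Venn overlaps match brute-force region enumeration", {
  mk <- function(sets) {
    rows <- do.call(rbind, lapply(names(sets), function(tr) {
      if (length(sets[[tr]]) == 0) {
        return(data.frame(trait = tr, ion = "none", p = 1, bh_fdr = 1,
                          bonferroni = 1))
      }
      data.frame(trait = tr, ion = sets[[tr]], p = 0.01, bh_fdr = 0.01,
                 bonferroni = 0.01)
    }))
    rows
  }
  dis <- venn_overlaps(mk(list(A = c("x", "y"), B = c("z", "w"))),
                       c("A", "B"))
  expect_identical(dis$n_common, 0L)
  idn <- venn_overlaps(mk(list(A = c("x", "y"), B = c("x", "y"))),
                       c("A", "B"))
  expect_identical(idn$n_common, 2L)
  set.seed(44)
  ions <- paste0("ion", 1:30)
  sets <- list(A = sample(ions, 12), B = sample(ions, 8),
               C = sample(ions, 15))
  ov <- venn_overlaps(mk(sets), c("A", "B", "C"))
  # brute force every exclusive region
  for (r in seq_len(nrow(ov$regions))) {
    pat <- unlist(ov$regions[r, c("A", "B", "C")])
    cnt <- sum(vapply(ions, function(i) {
      all((i %in% sets$A) == pat[1], (i %in% sets$B) == pat[2],
          (i %in% sets$C) == pat[3])
    }, TRUE) & (ions %in% unlist(sets)))
    expect_identical(ov$regions$count[r], as.integer(cnt))
  }
  # inclusion-exclusion: regions sum to the union size
  expect_identical(sum(ov$regions$count), length(unique(unlist(sets))))
  expect_error(venn_overlaps(mk(sets), c("A", "Q")), "unknown trait")
})

test_that("cohort summary: Kruskal-Wallis, Dunn and letters behave", {
  set.seed(45)
  # null: three groups from one distribution
  bmi <- c(runif(20, 20, 24), runif(20, 26, 29), runif(20, 31, 40))
  null_tr <- data.frame(BMI = bmi, marker = rnorm(60))
  cs <- cohort_summary(null_tr, parameters = "marker")
  expect_gt(cs$kw_p[1], 0.2)
  # strong separation: distinct letters everywhere
  shift_tr <- data.frame(BMI = bmi,
                         marker = c(rnorm(20, 0, 0.1), rnorm(20, 5, 0.1),
                                    rnorm(20, 10, 0.1)))
  cs2 <- cohort_summary(shift_tr, parameters = "marker")
  expect_identical(sort(unique(cs2$letter)), c("A", "B", "C"))
  expect_lt(cs2$kw_p[1], 1e-6)
  # KW statistic against the rank-sum formula on a small dataset
  x <- c(1.1, 2.3, 0.7, 4.5, 3.3, 5.1, 2.2, 6.6, 7.0)
  g <- factor(rep(c("a", "b", "c"), each = 3))
  r <- rank(x)
  H <- 12 / (9 * 10) * sum(tapply(r, g, sum)^2 / 3) - 3 * 10
  expect_equal(unname(kruskal.test(x, g)$statistic), H)
  # Dunn z against the mean-rank formula (no ties)
  d <- dunn_test(x, g)
  se <- sqrt((9 * 10 / 12) * (2 / 3))
  z_ab <- (mean(r[g == "a"]) - mean(r[g == "b"])) / se
  expect_equal(d$z[d$group1 == "a" & d$group2 == "b"], z_ab)
})

test_that("trait transforms follow the declared scheme with zero offsets", {
  tr <- data.frame(BMI = c(25, 30), leptin = c(2, 8), IL6 = c(0, 3.5))
  out <- transform_traits(tr)
  expect_identical(out$BMI, tr$BMI)
  expect_equal(out$leptin, log(tr$leptin))
  expect_equal(out$IL6, log(tr$IL6 + 3.5))  # offset = min positive value
  expect_equal(unname(attr(out, "offsets")["IL6"]), 3.5)
  expect_error(transform_traits(data.frame(leptin = c(-1, 2))), "negative")
})

test_that("smoking dummies reproduce a saturated group-means fit when age is inert", {
  cov <- data.frame(
    age = rep(55, 9),  # constant age cannot carry signal
    smoking = factor(rep(c("never", "ever", "unknown"), each = 3),
                     levels = c("never", "ever", "unknown"))
  )
  y <- c(1, 1.2, 0.8, 4, 4.1, 3.9, -2, -2.2, -1.8)
  X <- LipidLens:::covariate_design(cov)
  fit <- lm.fit(cbind(X[, colnames(X) != "age"]), y)
  expect_equal(unname(tapply(fit$fitted.values, cov$smoking, mean)),
               unname(tapply(y, cov$smoking, mean)))
  expect_lt(max(abs(fit$fitted.values -
                      ave(y, cov$smoking))), 1e-10)
})

test_that("FAME cross-reference recovers proportionality and Spearman oracle", {
  set.seed(46)
  fa <- runif(30, 1, 10)
  pl <- 3 * fa * exp(rnorm(30, 0, 0.01))
  bmi <- runif(30, 20, 35)
  fit <- fame_crossref(pl, fa, bmi)
  expect_equal(fit$effect, 1, tolerance = 0.02)
  expect_lt(fit$p, 1e-10)
  # Spearman rho by the rank formula on a 5-point example (no ties)
  a <- c(3.1, 1.2, 5.4, 2.2, 4.4)
  b <- c(2.0, 1.1, 4.9, 3.3, 4.1)
  d2 <- sum((rank(a) - rank(b))^2)
  rho <- 1 - 6 * d2 / (5 * 24)
  got <- fame_crossref(a, b, runif(5, 20, 30))
  expect_equal(got$spearman_rho, rho)
  expect_error(fame_crossref(c(-1, 2), c(1, 2), c(25, 26)), "positive")
})

test_that("manhattan table restricts display window without dropping records", {
  panel <- small_panel(seed = 47, n_subjects = 30, n_ions = 50)
  set.seed(48)
  out <- run_all_regressions(data.frame(BMI = rnorm(30)), panel$cohort,
                             panel$processed)
  mt <- manhattan_table(out$records, panel$processed, "BMI")
  rts <- panel$processed$ion_meta$retention_time
  expect_identical(nrow(mt), sum(rts >= 0.5 & rts <= 11.5))
  expect_true(all(mt$neg_log10_p >= 0))
})
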