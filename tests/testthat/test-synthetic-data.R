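test_that("cohort generation respects the specification", {
  co <- generate_cohort(cohort_spec(n_subjects = 126), seed = 1)
  expect_identical(nrow(co), 126L)
  expect_true(all(co$age >= 48 & co$age <= 65))
  expect_identical(co, generate_cohort(cohort_spec(n_subjects = 126),
                                       seed = 1))
  # large-n smoking proportions within +-0.02 of the target mix
  big <- generate_cohort(cohort_spec(n_subjects = 10000), seed = 2)
  p <- prop.table(table(big$smoking))
  expect_lt(abs(p[["ever"]] - 0.2540), 0.02)
  expect_lt(abs(p[["never"]] - 0.5714), 0.02)
  expect_lt(abs(p[["unknown"]] - 0.1746), 0.02)
  expect_error(cohort_spec(smoking_probs = c(0.5, 0.6, 0.1)), "sum to 1")
  expect_error(cohort_spec(n_subjects = 2), "at least 3")
})

test_that("feature tables have the configured structure", {
  panel <- small_panel(seed = 9, n_subjects = 40, n_ions = 200, n_is = 4)
  ft <- panel$features
  expect_identical(ncol(ft$abundances), 200L)
  expect_identical(sum(ft$ion_meta$is_internal_standard), 4L)
  expect_true(all(ft$ion_meta$mz > 100 & ft$ion_meta$mz < 1500))
  expect_true(all(grepl("^X[0-9.]+_[0-9.]+$",
                        ft$ion_meta$ion[!ft$ion_meta$is_internal_standard])))
  # configured high-missingness count is exact
  spec <- feature_panel_spec(n_ions = 200, n_internal_standards = 4,
                             rmd_in_range_fraction = 0.8,
                             missing_fraction_high = 0.15, n_qc = 4)
  cohort <- generate_cohort(cohort_spec(n_subjects = 40), seed = 3)
  ft2 <- generate_feature_table(spec, cohort, seed = 4)
  n_high <- sum(colMeans(is.na(ft2$abundances)) > 0.20)
  expect_identical(n_high, 30L)
  # bit-reproducible under the same seed
  ft3 <- generate_feature_table(spec, cohort, seed = 4)
  expect_identical(ft2$abundances, ft3$abundances)
})

test_that("injection-order drift is shared with IS and removed by normalization", {
  cohort <- generate_cohort(cohort_spec(n_subjects = 50), seed = 5)
  drifty <- feature_panel_spec(n_ions = 80, n_internal_standards = 2,
                               rmd_in_range_fraction = 1,
                               missing_fraction_high = 0,
                               drift_magnitude = 2, n_factors = 0, n_qc = 3)
  ft <- generate_feature_table(drifty, cohort, seed = 6)
  ord <- ft$sample_meta$injection_order
  is_col <- which(ft$ion_meta$is_internal_standard)[1]
  expect_gt(cor(log(ft$abundances[, is_col]), ord), 0.9)
  norm <- is_normalize(mean_impute(ft))
  cors <- cor(log(norm$abundances), ord)
  expect_lt(median(abs(cors)), 0.2)
  # no drift injected -> IS correlation is pure noise
  calm <- feature_panel_spec(n_ions = 80, n_internal_standards = 2,
                             rmd_in_range_fraction = 1,
                             missing_fraction_high = 0,
                             drift_magnitude = 0, n_factors = 0, n_qc = 3)
  ft0 <- generate_feature_table(calm, cohort, seed = 7)
  is0 <- which(ft0$ion_meta$is_internal_standard)[1]
  expect_lt(abs(cor(log(ft0$abundances[, is0]),
                    ft0$sample_meta$injection_order)), 0.35)
})

test_that("trait generation hits the targeted variance fraction", {
  panel <- small_panel(seed = 21, n_subjects = 126)
  # null: no lipid effect at all
  null <- generate_traits(trait_gen_spec(variance_fraction = 0),
                          panel$processed, panel$cohort, seed = 1)
  expect_true(all(null$truth$alpha == 0))
  expect_identical(null$truth$realized_fraction, 0)
  # realized fraction within +-0.05 of 0.64 across seeds
  fr <- vapply(1:6, function(i) {
    generate_traits(trait_gen_spec(variance_fraction = 0.64,
                                   n_causal_lipids = NULL),
                    panel$processed, panel$cohort,
                    seed = i)$truth$realized_fraction
  }, 0)
  expect_true(all(abs(fr - 0.64) < 0.05))
  # causal lipids carry the largest |alpha| by construction
  ts <- generate_traits(trait_gen_spec(variance_fraction = 0.5,
                                       n_causal_lipids = 5,
                                       effect_size = 1.0),
                        panel$processed, panel$cohort, seed = 2)
  top5 <- names(sort(abs(ts$truth$alpha), decreasing = TRUE))[1:5]
  expect_setequal(top5, ts$truth$causal_ions)
  expect_error(trait_gen_spec(variance_fraction = 1), "in \\[0, 1\\)")
  # deterministic under seed
  ts2 <- generate_traits(trait_gen_spec(variance_fraction = 0.5,
                                        n_causal_lipids = 5),
                         panel$processed, panel$cohort, seed = 2)
  expect_identical(ts$value, ts2$value)
})

test_that("spectrum generation is deterministic and annotation round-trips it", {
  a <- generate_msms_spectrum("PC(16:0_18:2)", "[M+HCOO]-",
                              noise_peaks = 20, seed = 12)
  b <- generate_msms_spectrum("PC(16:0_18:2)", "[M+HCOO]-",
                              noise_peaks = 20, seed = 12)
  expect_identical(a$peaks, b$peaks)
  expect_identical(annotate(a)$name, "PC(16:0_18:2)")
  expect_error(generate_msms_spectrum("QQ(1:0)", "[M-H]-"), "parse")
})
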