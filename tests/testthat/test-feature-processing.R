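test_that("relative mass defect matches hand arithmetic", {
  expect_equal(relative_mass_defect(564.3289), 582.9, tolerance = 0.1)
  # 0.2331 / 255.2331 * 1e6, frozen from hand arithmetic
  expect_equal(relative_mass_defect(255.2331), 913.28, tolerance = 0.1)
  expect_identical(relative_mass_defect(500.0000), 0)
  expect_error(relative_mass_defect(0), "positive")
})

test_that("RMD filter keeps the closed band and never drops IS channels", {
  tb <- tiny_table()
  # place one analyte exactly on the lower bound, one below, one above
  tb$ion_meta$mz <- c(554.31, 500 + 350e-6 * 500 / (1 - 350e-6),
                      600.12, 700.42, 800.9)
  tb$abundances[, 5] <- 1  # keep valid
  out <- rmd_filter(tb)
  rmds <- relative_mass_defect(tb$ion_meta$mz)
  expect_true(tb$ion_meta$ion[2] %in% out$table$ion_meta$ion)  # exactly 350
  expect_true(tb$ion_meta$ion[3] %in% out$excluded)            # ~200 ppm
  expect_true(tb$ion_meta$ion[5] %in% out$excluded)            # >950 ppm
  expect_true("PC(8:0/8:0)" %in% out$table$ion_meta$ion)       # IS retained
  expect_error(rmd_filter(tb, low = 900, high = 400), "low < high")
})

test_that("missingness filter uses a strict 20% cut", {
  n <- 126
  ab <- matrix(1, n, 3)
  ab[seq_len(26), 2] <- NA   # 26/126 = 20.6% -> excluded
  ab[seq_len(25), 3] <- NA   # 25/126 = 19.8% -> retained
  tb <- feature_table(
    ab,
    data.frame(ion = c("A", "B", "C"), retention_time = 1:3,
               mz = c(500.4, 600.4, 700.4),
               is_internal_standard = FALSE),
    data.frame(sample = paste0("S", 1:n), injection_order = 1:n,
               is_qc = FALSE)
  )
  out <- missingness_filter(tb)
  expect_identical(out$excluded, "B")
  expect_setequal(out$table$ion_meta$ion, c("A", "C"))
})

test_that("mean imputation fills with observed means and preserves them", {
  tb <- tiny_table()
  imp <- mean_impute(tb)
  expect_false(anyNA(imp$abundances))
  # ion 3 missing in sample 2: observed mean of the others
  obs <- tb$abundances[-2, 3]
  expect_equal(imp$abundances[2, 3], mean(obs))
  # property: post-imputation column means equal observed means
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(rexp(60), 10, 6)
    m[sample(60, 12)] <- NA
    m[1, ] <- 1  # ensure no all-NA column
    tb2 <- feature_table(
      m, data.frame(ion = paste0("I", 1:6), retention_time = 1:6,
                    mz = 100.5 + 1:6, is_internal_standard = FALSE),
      data.frame(sample = paste0("S", 1:10), injection_order = 1:10,
                 is_qc = FALSE)
    )
    expect_equal(colMeans(mean_impute(tb2)$abundances),
                 colMeans(m, na.rm = TRUE), ignore_attr = TRUE)
  }
  bad <- tb
  bad$abundances[, 4] <- NA
  bad$ion_meta$is_internal_standard[4] <- FALSE
  expect_error(mean_impute(bad), "all-missing")
})

test_that("IS normalization divides by the standard and is scale equivariant", {
  tb <- mean_impute(tiny_table())
  out <- is_normalize(tb)
  expect_false("PC(8:0/8:0)" %in% out$ion_meta$ion)
  # sample 1: IS = 2, analyte 2 = 10 -> 5
  expect_equal(out$abundances[1, "X1.00_500.2500"], 5)
  # multiplying a whole sample row by c leaves normalized values unchanged
  tb2 <- tb
  tb2$abundances[3, ] <- tb2$abundances[3, ] * 7.3
  expect_equal(is_normalize(tb2)$abundances, out$abundances)
  # zero IS errors and names the sample
  tb3 <- tb
  tb3$abundances[2, 1] <- 0
  expect_error(is_normalize(tb3), "S2")
})

test_that("Pareto scaling centers and divides by sqrt(sd)", {
  ab <- cbind(a = c(1, 2, 3), b = c(2, 4, 9))
  tb <- feature_table(
    ab, data.frame(ion = c("a", "b"), retention_time = 1:2,
                   mz = c(100.5, 200.5), is_internal_standard = FALSE),
    data.frame(sample = paste0("S", 1:3), injection_order = 1:3,
               is_qc = FALSE)
  )
  sc <- pareto_scale(tb)$abundances
  expect_equal(sc[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_lt(abs(mean(sc[, "b"])), 1e-12)
  # variance of a scaled column equals the sd of the original column
  expect_equal(var(sc[, "b"]), sd(ab[, "b"]))
  tb$abundances[, 2] <- 5
  expect_error(pareto_scale(tb), "zero-variance")
})

test_that("QC coefficient of variation is sd/mean in percent", {
  tb <- tiny_table()
  tb$abundances[5:6, 2] <- c(95, 105)
  tb$abundances <- rbind(tb$abundances, tb$abundances[5, ])
  tb$sample_meta <- rbind(tb$sample_meta,
                          data.frame(sample = "QC3", injection_order = 7,
                                     is_qc = TRUE))
  tb$abundances[7, 2] <- 100
  tb <- feature_table(tb$abundances, tb$ion_meta, tb$sample_meta)
  cv <- qc_cv(tb)
  expect_equal(unname(cv["X1.00_500.2500"]), 5.0)
  expect_equal(unname(cv["PC(8:0/8:0)"]), 0)
  one_qc <- tiny_table()
  one_qc$sample_meta$is_qc <- c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  expect_error(qc_cv(one_qc), "2 QC")
})

test_that("pipeline accounting identity holds and report serializes", {
  panel <- small_panel(seed = 5)
  res <- preprocess(panel$features)
  r <- res$report
  expect_identical(
    r$n_input_ions,
    r$n_rmd_excluded + r$n_missing_excluded + r$n_is_split + r$n_retained
  )
  expect_false(anyNA(res$table$abundances))
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(r, path)
  back <- jsonlite::read_json(path)
  expect_identical(back$n_retained, r$n_retained)
})

test_that("RMD and missingness filters commute only when no ion violates both", {
  tb <- tiny_table()
  tb <- feature_table(tb$abundances, tb$ion_meta, tb$sample_meta)
  # no ion violates both rules here: both orders retain the same set
  a <- missingness_filter(rmd_filter(tb)$table)$table
  b <- rmd_filter(missingness_filter(tb)$table)$table
  expect_setequal(a$ion_meta$ion, b$ion_meta$ion)
  # make one ion violate both: counts differ between orders
  tb2 <- tiny_table()
  tb2$ion_meta$mz[2] <- 500.05           # RMD 100 ppm, out of band
  tb2$abundances[1:2, 2] <- NA           # and 33% missing
  o1 <- rmd_filter(tb2)
  o2 <- missingness_filter(o1$table)
  expect_true("X1.00_500.2500" %in% o1$excluded)
  expect_false("X1.00_500.2500" %in% o2$excluded)
})

test_that("feature table CSV round trip preserves data and metadata", {
  tb <- tiny_table()
  path <- file.path(withr::local_tempdir(), "feat.csv")
  write_feature_csv(tb, path)
  back <- read_feature_csv(path)
  expect_equal(back$abundances, tb$abundances, ignore_attr = TRUE)
  expect_identical(back$ion_meta$ion, tb$ion_meta$ion)
  expect_identical(back$sample_meta$is_qc, tb$sample_meta$is_qc)
})
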