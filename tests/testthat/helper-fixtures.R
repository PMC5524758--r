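# shared fixtures, all built in code

# tiny handmade feature table: 6 samples (1 QC pair), 5 ions (1 IS)
tiny_table <- function() {
  ab <- rbind(
    c(2.0, 10, 20, 5, 8),
    c(2.0, 12, NA, 6, 9),
    c(4.0, 20, 44, 11, 15),
    c(4.0, 22, 40, NA, 17),
    c(2.0, 11, 21, 5, 8),
    c(2.0, 10, 22, 5, 8)
  )
  feature_table(
    ab,
    data.frame(
      ion = c("PC(8:0/8:0)", "X1.00_500.2500", "X2.00_600.3600",
              "X3.00_700.4200", "X4.00_800.4800"),
      retention_time = 1:5 * 1.0,
      mz = c(554.31, 500.25, 600.36, 700.42, 800.48),
      is_internal_standard = c(TRUE, FALSE, FALSE, FALSE, FALSE)
    ),
    data.frame(
      sample = c("S1", "S2", "S3", "S4", "QC1", "QC2"),
      injection_order = 1:6,
      is_qc = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
    )
  )
}

# small synthetic panel shared by several test files (cheap to build)
small_panel <- function(seed = 42, n_subjects = 60, n_ions = 300,
                        n_is = 3, n_factors = 5, factor_share = 0.5) {
  cohort <- generate_cohort(cohort_spec(n_subjects = n_subjects),
                            seed = seed)
  spec <- feature_panel_spec(
    n_ions = n_ions, n_internal_standards = n_is,
    rmd_in_range_fraction = 0.8, missing_fraction_high = 0.1,
    n_factors = n_factors, factor_share = factor_share, n_qc = 4
  )
  features <- generate_feature_table(spec, cohort, seed = seed + 1)
  list(cohort = cohort, features = features,
       processed = preprocess(features)$table)
}

# closed-form OLS oracle via normal equations (independent of the
# package's QR/FWL paths)
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  list(beta = drop(beta), se = se,
       p = 2 * pt(-abs(tval), df), df = df)
}

# grid of lipid names exercised by annotation round-trip tests
annotation_grid <- function() {
  chains <- c("16:0", "17:0", "18:0", "18:1", "18:2", "18:3",
              "20:4", "20:5", "22:6")
  pairs <- list(c("16:0", "18:2"), c("18:0", "18:2"), c("18:1", "18:2"),
                c("18:0", "20:4"), c("16:0", "22:6"), c("18:2", "18:2"))
  names <- character(0)
  for (h in c("PC", "PE", "PI", "PS")) {
    for (p in pairs) {
      names <- c(names, sprintf("%s(%s_%s)", h, p[1], p[2]))
    }
  }
  for (h in c("LPC", "LPE", "LPS")) {
    names <- c(names, sprintf("%s(%s)", h, chains))
  }
  for (e in c("O-16:0", "O-16:1", "O-18:0", "O-18:1")) {
    names <- c(names, sprintf("PC(%s_18:2)", e), sprintf("PC(%s_20:4)", e))
  }
  names
}
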