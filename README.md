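# LipidLens

Untargeted plasma lipidomics for population studies: feature-table
preprocessing, single-lipid trait regressions with false-discovery
control, cross-product PCA and SVD effect biplots, a Bayesian
whole-lipidome variance partition, and a rule-based negative-mode
MS/MS annotation engine for glycerophospholipids — plus a synthetic-data
module that makes the entire pipeline testable without cohort data.

## Who it is for

Researchers relating an untargeted LC-MS lipidomics panel (thousands of
ions keyed `X<rt>_<mz>`) to obesity-related traits — BMI, waist
circumference, adipokines (leptin, adiponectin), inflammatory cytokines
(IL-6, TNF-α, IP-10, MCP-1) and glycemic markers (C-peptide) — in
cohorts of modest size, where p ≫ n.

## The models at its core

For subject *i* and lipid *j* (Pareto-scaled abundance *l_ij*), with
age *a_i* and smoking category *s_i*:

* **Single-lipid OLS**, one regression per lipid, BH-FDR and Bonferroni
  within trait:
  *y_i = β₀ + a_i β₁ + s_i β₂ + l_ij β₃ + ε_i*
* **Cross-product PCA**: eigen-decomposition of the n×n sample
  cross-product XX′; traits regressed on scores, scores regressed on
  lipids.
* **SVD biplot** of the lipids × traits matrix of β₃ estimates
  (points = UD, arrows = V, radius rule for influential lipids).
* **Kernel variance partition** (RKHS/GBLUP-style), fit by a compiled
  Gibbs sampler in the kernel eigenbasis:
  *y = Wβ + u + ε*, *u ~ N(0, σ²_g G)*, *G = XX′/m*,
  reporting the posterior of the lipidomic variance fraction
  var(u)/(var(u) + σ²_ε).
* **Annotation rules** from exact monoisotopic masses: head-group
  diagnostics (PC: −60.0211 Da; PE: 140.0118; PI: 241.0119; PS:
  −87.0320), fatty acyl carboxylate anions (e.g. 18:2 → 279.233), and
  ether-PC chain fragments (O-16:0 → 466.3303).

## Worked example

```r
library(LipidLens)

cohort   <- generate_cohort(seed = 1)                    # n = 126, ages 48-65
features <- generate_feature_table(seed = 2)             # 4802 ions, 10 IS
res      <- preprocess(features)
print(res$report)
#> processing_report: 4802 input ions -> 1921 RMD-excluded,
#>   1126 missingness-excluded, 10 IS split, 1745 retained
#>   median QC CV: 4.10%

ts <- generate_traits(trait_gen_spec(variance_fraction = 0.64,
                                     n_causal_lipids = NULL),
                      res$table, cohort, seed = 3)
rr <- run_all_regressions(data.frame(BMI = ts$value), cohort, res$table)
sum(rr$records$bh_fdr < 0.05, na.rm = TRUE)
#> [1] 18

fit <- gibbs_fit(ts$value, cohort, build_kernel(res$table),
                 chain = list(n_iter = 20000, burn_in = 5000, thin = 5),
                 seed = 4)
print(fit)
#> posterior_summary: fraction 0.643 [0.431, 0.804], 3000 kept draws (ESS 1049)
round(ts$truth$realized_fraction, 3)
#> [1] 0.654

sp <- generate_msms_spectrum("PC(O-16:1_18:2)", "[M+HCOO]-",
                             noise_peaks = 20, seed = 5)
annotate(sp)
#> lipid_annotation: PC(O-16:1_18:2) [M+HCOO]- theoretical 786.5654
#>   (mass error +0.0000)
```

Reading the numbers: the preprocessing report accounts for every input
ion (filters, IS split, retained analytes); 18 of 1,745 lipids pass
BH-FDR for the simulated BMI-like trait; the Gibbs posterior mean of
the lipidomic variance fraction (0.643, 95% CI [0.43, 0.80]) recovers
the realized truth (0.654); and the annotation engine round-trips an
ether-linked phosphatidylcholine spectrum, noise peaks and all, with
zero precursor mass error.

## Command line

A thin CLI over the same functions ships in `inst/scripts/lipidlens.R`
with subcommands `simulate`, `preprocess`, `regress`, `pca`, `varpart`,
`annotate` (see the header of that file for flags).

## More

The methods vignette
(`vignettes/untargeted-lipidomics-methods.Rmd`) documents the models
and their assumptions, every tunable parameter with its default and
rationale, what the synthetic-data generator does and does not emulate,
numerical conventions, and known limitations (including why very small
variance fractions are prior-limited at n = 126).
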