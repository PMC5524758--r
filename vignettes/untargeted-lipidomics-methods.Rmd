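---
title: "Untargeted plasma lipidomics with LipidLens: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untargeted plasma lipidomics with LipidLens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LipidLens)
```

## What this package models

LipidLens analyzes untargeted negative-mode LC-MS lipidomics feature
tables — thousands of ions keyed by retention time and m/z — against
anthropometric and serum traits (BMI, waist circumference, adipokines,
cytokines, C-peptide) in a modest cohort (around 126 subjects). Four
statistical layers sit on a common preprocessing pipeline:

1. **Single-lipid regressions.** For each Pareto-scaled lipid $l_{ij}$,
   OLS of the (possibly log-transformed) trait on age, smoking category
   and the lipid: $y_i = \beta_0 + a_i\beta_1 + s_i\beta_2 +
   l_{ij}\beta_3 + \varepsilon_i$; the lipid effect $\beta_3$ is tested
   two-sided with BH-FDR and Bonferroni control within trait.
2. **Cross-product PCA.** Because $p \gg n$, PCA is computed on the
   $n\times n$ sample cross-product $XX'$; trait-on-score and
   score-on-lipid regressions identify trait-associated components and
   the lipids driving them.
3. **SVD effect biplot.** The lipids-by-traits matrix of $\beta_3$
   estimates is decomposed by SVD; lipid points ($UD$) and trait arrows
   ($V$) in the first two vectors summarize which lipids push which
   traits, with a radius rule flagging influential lipids.
4. **Whole-lipidome variance partition.** A Bayesian kernel model
   $y = W\beta + u + \varepsilon$, $u \sim N(0, \sigma_g^2 G)$, with
   $G = XX'/m$ built from standardized lipid abundances, estimates the
   fraction of inter-individual trait variance attributable to the
   lipidome — the lipidomic analogue of heritability — by Gibbs
   sampling.

A fifth component, the **annotation engine**, implements the
negative-mode fragmentation rules for glycerophospholipids (head-group
diagnostics, fatty acyl carboxylate anions, ether-chain fragments) on
exact monoisotopic mass arithmetic.

## Preprocessing: order and conventions

The pipeline order is: relative-mass-defect filter, then missingness
filter, then internal-standard split, then mean imputation, then IS
normalization, then Pareto scaling. The report's accounting identity
`input = rmd_excluded + missing_excluded + is_split + retained` is
asserted on every run.

* **RMD filter.** RMD = fractional mass / m/z in ppm; ions outside the
  closed band [350, 950] ppm are dropped (lipids cluster inside it).
  The fractional part is taken relative to `floor(mz)`: every lipid ion
  in range has a defect well below the next integer, so floor and round
  agree in-domain and floor is total and monotone. The band is treated
  as *retained-closed* because the exclusion rule is strict
  ("below 350, above 950").
* **Missingness.** Strictly more than 20% missing excludes an ion
  (26/126 is out, 25/126 stays). Imputation uses the mean of observed
  values only — the only well-defined choice.
* **Order of imputation and normalization.** The narrative order of the
  source workflow (impute, then normalize) is adopted; the alternative
  order changes only imputed cells and is not exposed as an option.
* **IS normalization** divides each sample's analyte row by that
  sample's spiked-standard signal, which removes any multiplicative
  injection-order drift shared between analytes and the standard, and
  is scale-equivariant per sample by construction.
* **Pareto scaling** divides centered columns by the square root of
  their standard deviation; the variance of a scaled column equals the
  original column's sd, a property the tests check numerically.

## The Gibbs sampler

The variance model is sampled in the eigenbasis of $G$: with
$G = E\Lambda E'$ and $\delta = E'u$, the random-effect conditional
factorizes into independent normals, so one rotation up front buys
$O(n)$ per iteration; the inner loop is compiled (Rcpp) and uses R's
RNG, so runs are bit-reproducible under `set.seed()`. Priors are
scaled-inverse-$\chi^2$ on both variances with df 5 and scale chosen so
each prior mode equals half the sample variance of the trait (the
default heuristic of the standard Bayesian whole-genome-regression
software this model family comes from). The default chain is 200,000
iterations, 50,000 burn-in, thinning 5; tests and examples use much
shorter chains.

The reported **variance fraction** is computed per kept draw as
$\mathrm{var}(u)/(\mathrm{var}(u) + \sigma_\varepsilon^2)$ from the
*realized* random effect rather than from $\sigma_g^2$ alone, making it
invariant to the kernel's overall scaling (the kernel is nonetheless
normalized to mean diagonal 1). A naive full-covariance Gibbs sampler
(`gibbs_fit_naive()`, pure R, $O(n^3)$ per iteration) is kept as an
independent oracle; the two agree within Monte-Carlo error on small
problems, and the eigenbasis sampler was additionally validated against
a two-dimensional numerical integration of the exact posterior.

## What the synthetic data emulates — and what it does not

`generate_cohort()` reproduces the target population: n = 126, ages
truncated-normal 56.9 ± 4.7 on [48, 65], smoking ever/never/unknown at
25.40/57.14/17.46%. "Unknown" is kept as its own category so all
subjects stay in the model (the adjustment uses two dummies with
"never" as reference).

`generate_feature_table()` emulates a 4,802-ion aligned panel with 10
internal standards. Choices a maintainer should know, each made once on
realism grounds:

* **Log-normal abundances** (log-sd 0.5, ~50% CV) — standard for MS
  peak areas; no distribution is dictated by the domain beyond
  positivity and right skew.
* **In-band RMD fraction** defaults to 2881/4802 so the default table
  reproduces the canonical accounting 4,802 → 1,126 high-missingness +
  10 IS + 1,745 retained; the post-RMD count is otherwise a free
  parameter.
* **Exact MCAR missingness**: high-missingness ions get exact per-ion
  missing counts above the 20% cut (and are placed inside the RMD band
  so they actually reach the missingness filter), which makes filter
  counts deterministic for tests.
* **Multiplicative injection-order drift shared with the IS**, so IS
  normalization is exactly corrective — a testable contract rather than
  a vague promise.
* **IS channels carry ~5% CV**, not the analytes' 50%: a spiked
  standard has no biological variance, and that is precisely why it can
  serve as a normalizer. (With analyte-level IS noise, normalization
  injects a dominant artificial common-mode component.)
* **Latent co-regulation factors.** Analyte ions load on 20 latent
  factors with harmonically decaying strengths carrying 70% of the
  subject-level log-variance. Untargeted panels are highly redundant —
  several adduct/isotope ions per compound, plus lipid-class
  co-regulation — and this matters statistically: with independent
  ions the kernel $G$ converges to the identity (a Marchenko–Pastur
  bulk at 1) and the whole-lipidome variance fraction becomes
  *unidentifiable* — the posterior reproduces the prior at every truth.
  The chosen structure yields a leading PCA spectrum of roughly
  14/9/6/4% of total variation, bracketing the one spectral value the
  target study reports (Pc4 = 5.9%).

`generate_traits()` draws $y = \beta_0 + a\beta_1 + s\beta_2 + X\alpha
+ \varepsilon$ with $\alpha$ rescaled so the realized
$\mathrm{var}(u)$ hits $f/(1-f)\,\sigma_\varepsilon^2$ exactly; the
targeted fraction is then realized up to the sampling fluctuation of
$\mathrm{var}(\varepsilon)$ (±0.05 at n = 126). Causal-effect
magnitudes are fixed at `effect_size` (random signs), so "the causal
lipids have the largest |α|" holds by construction.

What the generator does **not** emulate: raw chromatograms, isotope
envelopes, adduct multiplicity tied to specific compounds, retention
behavior by lipid class, missingness that depends on abundance (real
missingness is left-censored, not MCAR), or batch structure beyond a
single smooth drift. A green test therefore establishes algorithmic
correctness on a faithful statistical caricature, not instrument-level
realism.

## The annotation rules

Head groups: PC by neutral loss of methyl formate (60.0211 Da from the
formate adduct), PE by the ethanolamine phosphate anion (140.0118), PI
by inositol phosphate − H2O (241.0119), PS by neutral loss of serine −
H2O (87.0320). Chains: carboxylate anions CnH(2n−2d−1)O2⁻ (255.233 for
16:0, 279.233 for 18:2, …); ether chains by the demethylated ether-LPC
anion, whose theory-derived values reproduce the four reported
diagnostics (466.3303, 464.3147, 494.3616, 492.3460) to 4 decimals.
Deprotonation uses the proton mass 1.007276 (the electron stays with
the ion) — required for 3-decimal agreement with the printed chain
masses. Every constant is recomputed from element masses at package
load and validated against its reference value; a mismatch aborts.

`annotate()` fires all head rules within the fragment tolerance
(default 0.01 Da), inverts every peak against the acyl-chain grid,
enumerates chain combinations (including one-chain lysophospholipid
solutions and ether+acyl PCs) under both adducts, keeps candidates
whose theoretical precursor is within 0.05 Da, and returns the smallest
absolute precursor error (deterministic tie-break by name, then
adduct). If a spectrum satisfies two head rules, the precursor error
decides — documented behavior, since the rule ordering is otherwise
arbitrary. Spectra with no firing rule, or no viable chain combination,
return `"unknown"`; sphingomyelins need positive-mode confirmation and
are out of scope, so SM-like spectra fall into `"unknown"` by design.
sn-positions are never assigned; names join chains with `_`.

## Numerical choices

* OLS throughout is QR-based; the vectorized all-lipids path uses
  Frisch–Waugh residualization against the covariate design and is
  tested to 1e-10 against per-lipid fits and a normal-equations oracle.
  Residual sums of squares are clamped at zero against cancellation.
* BH-FDR is the standard step-up with monotonicity enforcement; NAs
  (flagged rank-deficient fits) pass through without counting toward m.
* PCA and biplot signs follow a fixed convention (largest-magnitude
  coordinate/loading positive) so runs are exactly reproducible.
* The biplot radius rule is applied to radii normalized by the largest
  lipid norm, because the absolute coordinate units of the original
  rule are not recoverable; both raw and normalized radii are returned.
* Kernel eigenvalues are floored at zero; a non-PSD kernel is an error.
* The truncated-normal age draw uses the inverse-CDF, so truncation is
  exact, not rejection-based.

## Known limitations

* **Null/low variance fractions are prior-limited.** With the df-5
  scaled-inverse-$\chi^2$ priors (mode at half the trait variance) and
  n = 126, the marginal likelihood for the lipidome fraction is nearly
  flat below ~0.4, and the prior's essentially-zero left tail keeps the
  posterior 95% interval floor near 0.15. Fractions of 0.1 or less are
  therefore systematically over-estimated and their credible intervals
  cannot cover the truth; recovery is reliable for mid-to-high
  fractions (ordering across 0.1/0.4/0.7 is always recovered). This is
  a property of the model-prior-sample-size combination, verified
  against exact numerical integration of the posterior — not a sampler
  defect.
* **Post-normalization drift correlations have a sampling floor.** The
  per-ion correlation with injection order after IS normalization is
  pure noise with sd ≈ $1/\sqrt{n}$; at n = 126 the *median absolute*
  correlation over ions concentrates near 0.060 (slightly lower after
  mean imputation) for any noise level, so thresholds below that cannot
  be met at this cohort size regardless of how well drift is removed.
* With G = I the variance split $\sigma_g^2$ vs $\sigma_\varepsilon^2$
  is not likelihood-identified (only the sum enters), so no
  REML-style benchmark exists in that degenerate corner.
* Annotation covers PC/PE/PI/PS/LPC/LPE/LPS with acyl chains C4–C30
  and the four reported ether chains; no isotope scoring, no spectral
  libraries, no positive mode.
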