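---
title: "Cross-platform proteomics concordance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform proteomics concordance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoconcord)
```

## The problem

Affinity proteomics panels measure thousands of proteins from tens of
microlitres of biofluid, but the two dominant chemistries — slow
off-rate modified aptamers read out as fluorescence (RFU), and paired
antibodies read out through a DNA reporter as NPX — do not always
agree, especially in cerebrospinal fluid. Before treating any single
reagent's readout as a biomarker candidate, one wants to know whether
it reproduces (a) across two runs of the same aptamer platform and
(b) across platforms with entirely different capture chemistry.
`proteoconcord` implements that audit as a pipeline: harmonization,
structural QC (PCA, coefficient of variation), a 12-category
reproducibility-and-reliability score, covariate-adjusted phenotype
association screens, and a bootstrap null for the overlap of top-ranked
association lists.

## Harmonization and pairing

Aptamer matrices arrive on the strictly positive linear RFU scale,
antibody matrices as log2 NPX. `log2_zscale()` takes both to a common
representation: log2 where needed, then per-reagent centering and
scaling to unit SD (n−1 denominator), applied to each dataset
independently. Constant reagent rows have no defined z-score and are
excluded with a warning rather than silently propagated. Because every
correlation downstream is Spearman (rank-based), the z-scaling is a
convenience for PCA and regression, not a prerequisite for the
correlation stages — monotone transforms leave all categories and
scores unchanged, and the test suite asserts exactly that.

Reagents are matched across panels by their *complete* UniProt
accession set (`pair_reagents()`): a two-accession complex annotation
only matches the identical two-accession set, never a subset. Several
aptamers per protein and several antibody assays per protein are all
retained (many-to-many pairing), so counts are reported both at
reagent-pair level and collapsed to unique accession sets
(`collapse_to_proteins()`), which is why pair counts and protein
counts legitimately differ in the summaries.

## The reproducibility and reliability score

For each aptamer, the intra-platform Spearman correlation between the
two aptamer runs and the best inter-platform correlation against the
antibody panel are each classified as GOOD (rho ≥ 0.5), MODERATE
(0.3 ≤ rho < 0.5) or POOR (rho < 0.3); negative coefficients are POOR
— the scheme does not treat inverted measurements as a separate
category. Both thresholds are inclusive toward the better class. The
two categories combine into scores 1–9 (intra category × best inter
category), and aptamers whose protein has no antibody assay at all
fall back to A–C from the intra category alone. When an aptamer has
two inter-platform records (one per aptamer run) or several antibody
matches, the record with the highest rho decides the column — the
score is deliberately optimistic about cross-platform evidence. The
"reproducible set" used by downstream stages is scores 1, 2, 3 and A:
everything with good intra-platform reproducibility, whether or not
the antibody panel can corroborate it.

A minimum of 10 overlapping complete observations per pair (`min_n`)
is required before a rho is reported at all; the study design this
emulates had ~264 overlapping individuals, so the floor only matters
for degenerate inputs.

## Coefficient of variation

CVs are computed on the raw, pre-harmonization matrices — variability
estimates on z-scores would be meaningless. The two scales need two
formulas: on the linear RFU scale, CV = σ/μ over calibrator
replicates; on the log2 NPX scale the readout is already logged, so
the CV of the implied linear quantity follows the log-normal identity
CV = sqrt(exp((ln 2 · σ_NPX)²) − 1). This is 0 at σ_NPX = 0,
monotone in σ_NPX, invariant under additive NPX shifts, and ≈
ln 2 · σ_NPX for small σ. The intra-assay CV takes each plate's
calibrator replicates separately and averages the per-plate CVs
(unweighted — no weighting scheme is implied by the design); the
inter-assay CV pools all calibrators across plates, so plate-to-plate
shifts inflate it relative to the intra-assay CV. `cv_summary()`
reports the 10/25/50/75/90 percentiles (linear interpolation), the
fraction of reagents under 20% CV, and a Mann-Whitney comparison
between two platforms after trimming CV outliers beyond 1.5 × IQR.

## PCA audit

`run_pca()` operates on samples of the z-scored matrix. Components
are deterministic up to sign, so the loading with the largest
magnitude on each component is made positive. `pcs_for_variance()`
reports the number of components to a cumulative target (default
95%), `top_loadings()` the strongest |loading| reagents (ties broken
by reagent id), and `pc_phenotype_screen()` runs either per-variable
Pearson correlations (UNADJUSTED) or one joint linear model per PC
over all phenotypes (JOINT) — the joint model is what isolates
independent contributors when clinical variables are mutually
correlated. Outlier samples are removed by the 1.5 × IQR rule on PC1
and PC2 scores by default (`iqr_outlier_samples()`); which components
the rule scans is configurable because reasonable analysts differ
here, and an infinite fold is treated as "no exclusions".

## Association screens and the overlap null

For continuous traits, each (z-scored) protein is the outcome of a
linear model on the trait plus covariates — sex, age and CSF total
protein, plus assay technique when the trait is a CSF core biomarker
(Aβ42, p-tau); a covariate identical to the tested trait is dropped
automatically. Sex is screened with the logistic orientation (sex as
outcome, protein as predictor). Total tau is never screened; it is
nearly collinear with p-tau. Significance is flagged at the Bonferroni
threshold α divided by the number of reagents tested, and rankings
break p-value ties by |effect| then reagent id so top-K sets are
reproducible. The per-phenotype linear screen shares one QR
decomposition across all reagents; its output is verified against
`stats::lm` in the tests.

To ask whether the top-K lists of several screens share more
identifiers than chance allows, `bootstrap_overlap_null()` draws m
multisets of k identifiers with replacement from a universe of N,
reduces each to its unique elements, intersects, and repeats B times.
The null mean has the closed form N·(1 − (1 − 1/N)^k)^m, a useful
cross-check the tests enforce. Empirical p-values use the add-one
convention (x + 1)/(B + 1), so "greater than everything simulated" is
reported as 1/(B + 1), never zero. `enrichment_stats()` compares hit
rates between two reagent sets with an odds ratio (log-normal 95% CI)
and a Pearson chi-square without continuity correction, applying the
Haldane–Anscombe +0.5 only when a cell is zero, and flagging it.

For the LASSO variance-explained reports (`lasso_performance()`), the
penalty is tuned by 5-fold cross-validation repeated 5 times over the
data-derived glmnet lambda path (selection by RMSE for continuous,
rank-based AUC for binary phenotypes) on a stratified 80/20 split;
the held-out 20% yields the reported R² or AUC/sensitivity/
specificity. Everything is deterministic under the seed.

## What the synthetic generator emulates

The generator (`sim_config()`, `simulate_study()`) exists so every
stage can be validated against known ground truth:

- **Latent proteome with planted effects.** Each protein's level is a
  standardized combination of planted phenotype effects (β per SD)
  plus noise, so both platforms inherit the same biology — the basis
  for the expectation that reliable reagents produce more consistent
  top-K overlaps.
- **Bimodal reagent fidelity.** Each reagent reads its protein with
  log2 signal y = α·L + sqrt(1 − α²)·e; α is drawn from a two-class
  mixture (defaults: a third of reagents in 0.75–0.95, the rest in
  0–0.25). Two reagents sharing a protein then correlate at α₁·α₂
  (Pearson), and the population Spearman follows the bivariate-normal
  identity (6/π)·asin(r/2) (`expected_pair_correlation()`, verified
  against large-n simulation). Aptamer fidelity is shared between the
  two aptamer runs — it is a property of the physical reagent — while
  antibody fidelity is independent, so intra-reproducible aptamers
  need not replicate cross-platform, reproducing the empirically
  observed bimodal pattern and the 2/3-score phenomenon.
- **Plate structure.** Calibrator wells share one fixed latent vector
  across plates; each (reagent, plate) gets a shift with SD
  `tau_inter` and each calibrator replicate noise with SD
  `sigma_intra`, so with `tau_inter > sigma_intra` the inter-assay CV
  dominates the intra-assay CV by construction.
- **Cohort defaults.** 264 individuals, 230 MCI, 55.7% female, mean
  age ≈ 71 (per-diagnosis normals truncated above 40 years), MMSE per
  diagnosis clipped to [0, 30], core CSF biomarkers drawn per
  (diagnosis, technique) cell, plus CSF biochemistry, APOE-ε4 and
  storage duration. Fidelity defaults (f_good = 1/3) and the
  platform-overlap fraction (0.30) echo the observed intra-good
  fraction and reagent overlap of the study design this emulates.
  RFU export is `1000 · 2^y`; the baseline is arbitrary and only
  keeps values positive and realistically scaled.

What the generator does **not** emulate: vendor normalization
artifacts, limit-of-detection censoring, missing-not-at-random
dropout, proteoform-specific epitope effects, or the hypothesized
albumin–aptamer interference (no quantitative model of it exists to
copy, so none is guessed). Passing tests therefore demonstrate that
the statistical machinery is correct under the stated model, not that
any particular real-world panel is reliable.

## Numerical choices and degenerate inputs

- SD uses the n−1 denominator everywhere.
- Spearman is computed as the Pearson correlation of average ranks
  (exact under ties), vectorized over reagents for speed and verified
  against `stats::cor(method = "spearman")`.
- Percentiles and quartiles use linear interpolation (type 7).
- Constant reagent rows are excluded at harmonization, with the ids
  recorded on the result; constant phenotypes raise a rank-deficiency
  error naming the column; perfectly separated logistic fits are
  returned flagged non-converged with a missing p-value.
- Double z-scaling, non-positive RFU values, empty sample overlaps
  and duplicate (sample, reagent) rows are all hard errors.
- All stochastic functions accept a seed and restore the ambient RNG
  state afterwards (`with_seed()`); identical seeds give bit-identical
  output.

## Problem sizes used in validation

The packaged tests validate planted-class recovery at 300 samples ×
3,000 aptamers (recovery of the high-fidelity class ≥ 95%, the
low-fidelity class ≥ 95%), null calibration of the screen at 200 × 500
(Kolmogorov–Smirnov uniformity of p-values), and the bootstrap null at
B = 10,000 for universes of 7,289 and 2,428 identifiers, where the
simulated mean and SD agree with the closed-form expectation and run
in seconds. These sizes were chosen as the smallest at which the
binomial/Monte-Carlo error bars are comfortably inside the asserted
margins.

## Known limitations

- The scorer adjudicates reproducibility, not correctness: a reagent
  pair can agree well and both be wrong, and discordant pairs are not
  arbitrated.
- The attenuation model is linear-Gaussian; heavy-tailed readouts or
  saturation effects would attenuate rank correlations differently.
- Complete-case handling only; no imputation of missing phenotypes.
- The enrichment odds ratio requires explicit 2×2 counts from the
  caller, because more than one defensible table construction exists
  for "hits among reproducible vs complete sets"; the default pipeline
  construction is (hits in reproducible set, reproducible set size,
  hits in complete set, complete set size).
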