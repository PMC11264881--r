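---
title: "Methods: models, parameters and design choices in neometab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in neometab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neometab)
```

# Scope

`neometab` implements a complete metabolome-wide case-control analysis for
plate-based untargeted LC-MS data from neonatal dried blood spots, together
with a synthetic cohort generator that reproduces the data structure such a
study produces. This vignette is the package's own account of the methods:
what each stage assumes, which parameters matter and why their defaults are
what they are, what the generator does and does not emulate, and where the
design was genuinely open and a choice had to be made.

# The data model

A `feature_table` is a samples-by-features intensity matrix with explicit
missingness plus the run structure quality control needs: a plate (batch)
label, a 1-based injection order unique within plate, and a QC role per row
(`analytical`, `external_control`, `plate_pool`). Two semantics are fixed
throughout:

* A missing cell means *not detected*. A measured zero is a valid intensity
  distinct from missing — presence/absence is itself an analytical signal.
* Plates are opaque labels; nothing is inferred from their names.

Subject records carry the matched case-control design: outcome, pair id,
gestational age (weeks), age at sampling (days), season and year of birth,
family history of psychiatric disorders (0/1), a standardized polygenic
score, six genetic principal components, and for cases an age at diagnosis
(years). Cohort tables sometimes label age at sampling in years; the package
uses days (range 3–8), the scale on which neonatal DBS are actually drawn,
and treats the years label as a typographical artifact rather than guessing.

# QC-based drift correction (QC-RLSC)

Within-batch instrument drift is modeled as a smooth multiplicative function
of injection order. For each plate and feature, a LOESS curve (tricube
weights, span α = 2/3, local degree 1) is fitted to the plate's repeated QC
injections versus injection order, and every intensity is corrected as

    corrected = raw * reference / f(order)

**Span α = 2/3** is the fraction of QC points entering each local fit; it is
the classical QC-RLSC setting and is exposed (`span`). **Degree 1** is the
default reading of a "low-order" local fit: with the handful of QC points a
plate provides, local quadratics chase noise; degree 2 is available.
**The reference** is the study-wide per-feature QC median. Dividing by the
plate's own curve and multiplying back a common reference removes the
plate's overall level shift along with its drift — the form the QC-RLSC
literature uses. A plate-local reference would instead preserve cross-plate
offsets in the corrected data.

Numerical safeguards: evaluation is clamped to the observed QC order range
(no extrapolation, no sign flips); a feature with fewer than 4 QC points on
a plate, or whose fitted curve is not strictly positive, is passed through
uncorrected and logged; missing cells stay missing, so correction can never
change a presence/absence pattern. Correction is scale-equivariant by
construction. Whether the curve should be per-plate or global across the
run is not decidable from first principles; per-plate is the default because
pool QCs are plate-specific, and a global mode is provided.

A separate `correct_batch()` stage (per-feature log shift equalizing plate
medians of analytical samples to the grand median) remains available for
data corrected with a plate-local reference or normalized elsewhere.

# Missingness-stratified feature processing

Features are triaged on the presence fraction over analytical samples:
below 0.25 dropped, below 0.75 treated as a presence indicator, otherwise
continuous. The boundary semantics are strict (`< 0.25` drops, `< 0.75`
binarizes), so a fraction of exactly 0.25 is binary and exactly 0.75 is
continuous. The partition depends only on the missingness mask, never on
intensities, and is idempotent.

Continuous features are imputed (iterative regression-tree imputation
initialized at half the feature minimum, with half-minimum as the fallback —
a deliberately simple, documented stand-in for forest-based imputation),
batch-corrected, log-transformed (natural log; detection-limit-censored
log-normal intensities are closest to symmetric on this scale) and
standardized to mean 0, SD 1. Two choices here were genuinely open and are
recorded in the run manifest: standardization uses **all analytical
samples** (cases and controls pooled), and quartile coding for follow-up
analyses is computed on the **full analytical cohort**, ties going to the
lower bin at quartile boundaries. Both could defensibly be controls-only;
pooled versions are stabler at 1:1 matching and are what the manifest
declares.

# Association models

The scan fits one maximum-likelihood logistic regression per retained
feature: standardized log intensity for continuous features (so exp(β) is
the odds ratio per SD), the presence indicator for binary features. Model 1
adjusts for the matching factors — gestational age, age at sampling, season
of birth (three dummies, winter reference), birth year (integer). Model 2
adds family history, the polygenic score and six genetic PCs. Matching is
handled by *adjustment*, not conditional logistic regression: pair ids are
ignored in fitting, which mirrors how such cohorts are typically analyzed
and keeps binary features estimable when a pair is discordant on
missingness.

Inference is Wald (estimate, 95% CI, two-sided p); a likelihood-ratio
alternative was considered and rejected as the default because the scan
refits ~10³ models and the Wald form is the one reported alongside ORs.
Complete or quasi-complete separation (detected via non-convergence,
|β| > 15, or SE > 10) triggers a Firth-type penalized-likelihood refit
(Jeffreys-prior score correction), flagged in the output. Failed fits
contribute p = 1 and stay in the multiplicity family — conservative, and it
keeps the BH denominator stable. FDR control is Benjamini-Hochberg step-up
("FDR-adjusted" does not name a procedure; BH is the field default).

Small-sample behavior worth knowing: at ~200 analytical samples with the
model-1 covariate set, the null rejection rate of the Wald test sits near
4% rather than 5% (each ingredient is individually calibrated; the deficit
is the usual finite-sample Wald conservatism with ~8 parameters, slightly
amplified by batch correction). The calibration suite therefore checks the
per-scan count of nominal discoveries against its binomial band and the
empirical FDR against 0.07, rather than demanding exact pooled uniformity.

Diagnosis-age-stratified analysis fits the primary model separately for
early- and late-diagnosed cases, each against *all* controls (shared
controls, flagged in the output). The interaction p-value is a Wald test on
the feature-by-stratum product term in a stacked two-stratum model with the
controls entering both strata; sharing controls makes the test mildly
conservative, which the test suite verifies empirically. Single-marker
discrimination is summarized by the rank-based (Mann-Whitney) AUC with ties
counted one half.

# Enrichment and correlation structure

Class enrichment is a two-sided Fisher exact test (point-probability rule)
on the 2×2 table of class membership by significance over annotated
features; unannotated features are excluded. Partial Pearson correlations
"adjusted for all other features" are computed from the standardized
inverse correlation matrix — algebraically identical to per-pair residual
regressions at a fraction of the cost; p-values use the t transform with
df = n − p. When n ≤ p the exact inverse does not exist; a ridge-regularized
mode (λ added to the correlation diagonal, flagged in the result) is
provided, and neither mode is asserted to be what any particular study used.
Binary features participate as 0/1 numerics. Partial Spearman correlations
rank-transform the two variables *and* the covariates before residualizing —
ranking the covariates makes the adjustment insensitive to monotone
covariate transformations, and is what dedicated partial-correlation
packages do for the Spearman case. Dietary intakes are energy-adjusted by
dividing with non-alcoholic energy intake before testing.

# Spectral matching

Library screening uses plain cosine similarity over tolerance-paired peaks
with raw intensity weighting: candidate pairs within the fragment tolerance
are taken greedily by descending intensity product (ties to the smaller m/z
difference), one-to-one. Acceptance requires cosine > 0.7, at least 4
matched peaks, and parent mass difference < 0.05 Da, with a 0.05 Da fragment
tolerance — all exposed in `match_thresholds()`. Greedy pairing is
deterministic and, at the operating tolerance, indistinguishable from the
exhaustive optimal assignment (the test suite compares the two on random
small spectra; at artificially inflated tolerances the greedy score can
very occasionally fall below the optimum, and never exceeds it). No
precursor-shift "modified cosine" and no square-root intensity transform by
default (a toggle exists), since deployed search tools differ on both.

# Genetic and dietary determinant scans

The per-SNP scan is ordinary least squares of the metabolite on additive
0/1/2 dosage plus covariates, computed by residualizing outcome and dosages
on the covariates (Frisch-Waugh; exact, and one matrix operation for the
whole panel). Monomorphic SNPs are emitted flagged with NA estimates.
Calibration is summarized by λ_GC = median(χ²)/0.4549. The phenome-wide
scan is an L1-penalized regression solved by coordinate descent (glmnet)
with the penalty chosen by 10-fold cross-validation and the 1-SE rule;
reported are the nonzero coefficients ranked by magnitude and out-of-fold
R². Sex-stratified scans are a row filter.

# The synthetic cohort generator

The generator is the package's test bed and defines the conditions under
which every calibration claim is made. It emulates:

* **Design**: 1:1 matched male pairs (default 739), control covariates drawn
  within matching calipers (birth date ±14 d, gestational age ±4 d, age at
  sampling ±1 d); season from the birth date via the meteorological rule
  (Dec-Feb winter, and so on); family history Bernoulli with rates 0.300
  (cases) and 0.187 (controls); a polygenic score planted as a binormal
  shift δ = √2·Φ⁻¹(AUC) with default AUC 0.58; six unit-normal PCs; age at
  diagnosis truncated normal (mean 6, SD 2, ≥1 y).
* **Intensities**: log-normal features (base level U(log 10⁴, log 10⁶),
  biological log-SD U(0.35, 0.65)) over 19 plates with per-plate log offset
  (batch SD 0.10), smooth multiplicative drift
  g(order) = 1 + A·sin(π·order/orders-per-plate) (default amplitude 0.2; any
  smooth positive shape is pluggable — the half-sine matches the smoothness
  the LOESS correction assumes), and injection-level noise. The analytical
  CV is a free parameter with no published value; the default of 0.05
  log-units is a realistic pooled-QC repeatability for a well-behaved LC-MS
  feature and is exposed in the config.
* **Missingness**: per-feature left-censoring at the empirical intensity
  quantile matching a target detection fraction; default targets are drawn
  as a mixture calibrated to the emulated study's stratum mix (~8%
  detection-failure tail, the rest split 452:413 continuous:binary).
* **Planted effects**: continuous effects as an equal-variance Gaussian
  location shift of ln(OR) standard deviations in cases — which makes the
  logistic coefficient of the standardized feature exactly ln(OR), with no
  rejection sampling; binary effects on the presence odds via group-specific
  censoring quantiles solved to give the target presence OR at the target
  average presence.
* **QC rows**: per plate, evenly spaced external-control and plate-pool
  injections carrying the same drift and batch structure but only analytical
  noise (the external control gets a feature-specific level offset, being a
  different matrix).
* **Adult cohort**: Hardy-Weinberg 0/1/2 genotypes with MAF U(0.05, 0.5); a
  metabolite built additively from standardized causal dosages (each scaled
  to its stated variance fraction) plus an energy-adjusted dairy score whose
  coefficient is 2·sin(π·ρ/6), the bivariate-normal inverse of the target
  Spearman correlation; age, sex, BMI, non-alcoholic energy and six
  log-normal dietary intake groups.

Everything is deterministic given the config seed; one global seed is
expanded into per-stage seeds with a counter scheme so adding a stage never
reshuffles the randomness of another.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: chromatographic artifacts beyond smooth
drift (sudden level shifts, retention-time drift, co-elution), correlated
feature blocks from shared metabolic pathways or in-source fragments
(features are independent given the design), informative missingness beyond
intensity censoring, linkage disequilibrium between SNPs, registry-based
outcome misclassification, and any form of population stratification. Tests
on generator data demonstrate internal correctness and statistical
calibration under the stated model, not robustness to violations of it.

# Problem sizes and numerical conventions

The test and acceptance suites use study-sized cohorts where the claim is
about the study design (739 pairs for odds-ratio recovery; n = 3409/3714
for the adult scans) and smaller replicate counts elsewhere (50 all-null
scans of 800 features at 100 pairs for FDR calibration; 100 replicates for
coverage and GWAS power; 30–100 for LASSO recovery), sizes chosen to make
Monte-Carlo bands decisive while keeping a full run in minutes on one core.
Other conventions: Wald CIs use ±1.96 SE; quartile ties go to the lower
bin; BH q-values are computed jointly across continuous and binary
features; ridge partial correlation defaults to λ = 0.1; LOESS evaluation
is clamped to the QC order range; all tab-delimited output uses "." as the
decimal separator and empty cells for missing.

# Known limitations

* Unconditional logistic adjustment for matching factors is standard but
  not fully efficient for matched designs; conditional logistic regression
  is deliberately out of scope.
* The tree-based imputer is a simple stand-in: it restores plausible values
  for left-censored cells but does not propagate imputation uncertainty.
* The stacked shared-control interaction test is mildly conservative.
* Exact partial correlations over many hundreds of features at cohort-scale
  n sit close to the df = n − p degeneracy; the ridge mode trades a small,
  flagged bias for stability, and no claim is made about which a given
  study used.
* The spectral matcher implements screening thresholds, not full molecular
  networking; annotation of what a match *means* chemically is upstream of
  this package.
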