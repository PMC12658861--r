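---
title: "Methods: targeted quantification, multivariate statistics, and integrative pathway analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted quantification, multivariate statistics, and integrative pathway analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmstats)
```

This vignette documents the statistical models, the defaults and the
numerical choices behind `lcmstats`, in the spirit of a methods section: it
states what each procedure assumes, why each tunable matters, and what the
simulation-backed tests do and do not demonstrate about real data.

## Targeted peak analysis

A targeted experiment supplies, per compound, a precursor m/z and
optionally an expected retention time and a list of true fragment m/z
values. Detection (`detect_ms1()`) scans every MS1 spectrum for centroids
within the m/z tolerance and reports the most intense match; when an RT is
supplied the scan is restricted to RT ± `rt_tol`. The observed centroid
m/z — not the query — is reported as the estimated m/z, which is what makes
downstream ppm-delta identification meaningful.

Tunables and defaults:

* `mz_tol_ppm = 1000` — wide by high-resolution standards, appropriate for
  picking a known analyte out of a sparse targeted panel where the nearest
  interfering species is far away. Tolerance is computed relative to the
  *query* m/z for detection and XIC extraction; identification deltas
  (below) divide by the *reference* adduct m/z instead. Both conventions
  are deliberate and documented because they differ in the fifth decimal.
* `rt_tol = 5` s — half-width of the RT window used for MS2 association
  and abundance integration.
* `fragment_tol = 0.5` Da — fragment lists are often given as nominal
  (integer) masses, so an absolute Dalton window is the default; a ppm
  mode is available for accurate-mass fragment lists.

Within a scan, multiple matching centroids are **summed** in the XIC
(the alternative, taking the maximum, is not offered: summation makes the
trace monotone in the tolerance, an invariant the tests exploit). Among
candidate fragment centroids the most intense defines the estimated m/z,
with exact intensity ties resolved toward lower m/z for determinism.

Abundance is the sum of XIC intensities over RT ± `rt_window`; S/N is the
mean of those XIC points divided by their sample standard deviation
(n − 1). S/N can be computed in two modes — per run over in-window scan
points (what `analyze_targets()` reports) and per feature across samples
(what `peak_metrics()` reports) — because an acquisition-level and a
study-level notion of noise answer different QC questions. Neither mode is
claimed to reproduce any particular published instrument's values; raw
vendor data differ in scan rates and spike handling.

## The synthetic-run generator

`synthesize_run()` emulates a mixture injection: each target elutes as a
Gaussian of width `peak_width = 3` s (a typical UHPLC peak sigma) on the
MS1 grid, with an MS2 spectrum at the apex carrying the stated fragment
intensities, plus zero-truncated Gaussian baseline noise. It reproduces
the features the targeted module relies on — apex location, Gaussian area,
fragment ratios — and deliberately omits chromatographic tailing,
saturation, isotope envelopes, co-eluting interferents and mass-accuracy
drift. Tests passing on these runs therefore validate the bookkeeping and
the estimators, not robustness to pathological chromatography.

## Preprocessing

* **Pareto scaling**: per feature, (x − x̄)/√s with the sample standard
  deviation s. Dividing by √s rather than s tempers the dominance of
  high-variance metabolites while keeping more of the covariance
  structure than unit-variance scaling; the identity
  sd(scaled) = √sd(original) is asserted in the tests. Features with zero
  variance are centered only (with a warning) since the scale factor is
  undefined.
* **Rank-based inverse normal transform**: Φ⁻¹((r − c)/(n − 2c + 1)) with
  the Blom constant c = 3/8 (the GWAS convention); c is exposed because
  the literature also uses 0 and 1/2. Ties receive average ranks — RINT on
  tied data is implementation-defined, so the choice is documented rather
  than assumed.
* Internal-standard division and log transforms are exact, invertible
  operations; both preserve NA positions, as does every transform in the
  module.

## Quality control

Peak filtering combines three per-feature criteria: missing rate, zero
rate (computed among non-missing entries — a feature absent in half the
samples should not look zero-inflated on top of that), and across-sample
S/N. The conjunction is order-independent and idempotent. Sample filtering
computes 1 − correlation distances (Pearson, Spearman, or tie-corrected
Kendall τ-b), clusters by average linkage, and removes samples left as
singletons when the dendrogram is cut at the user's height. Average
linkage plus the singleton rule is this package's concrete choice for
"outlying sample"; other linkages would move the cut heights, which is
why the cut is a required, explicit parameter rather than a default.

## ANCOVA and PLS/PLS-DA

Per feature, `ancova()` fits y ~ trait + covariates by least squares and
reports the trait coefficient (for a two-level factor: the adjusted
between-group difference), its t statistic and p-value, with
Benjamini–Hochberg adjustment across features. Rank-deficient designs
(e.g. a covariate collinear with the trait) skip the feature with a
warning rather than silently dropping terms. `residualize()` provides
covariate-adjusted residuals (trait excluded) as PLS input, so covariate
adjustment and multivariate modelling compose without external tools.

`pls_fit()` implements NIPALS PLS on column-centered, unit-variance data;
a factor response switches to PLS-DA via one-hot dummy coding. Class
prediction takes the largest predicted dummy column, ties resolving to the
first class. Components stop early (with a warning) when the response or
predictor residual is numerically exhausted. VIP scores use the standard
definition VIP_j = √(p · Σ_a SS_a (w_ja)² / Σ_a SS_a) with unit-norm
weights, satisfying Σ VIP² = p exactly.

Cross-validation defaults to 7 folds (the convention of the R package
ecosystem this model family comes from), stratified by class in
discriminant mode, with a seeded shuffle so Q²Y is reproducible.
Q²Y = 1 − PRESS/TSS with TSS about the training-fold mean; RMSEE uses the
denominator n − A − 1. One property worth stating precisely: a noiseless
linear response gives Q²Y = 1 only when the retained components span the
signal direction — with correlated random predictors that requires A up to
the design's rank, and the test suite constructs an orthogonalized design
when it asserts the single-component case.

The dual filter intersects {pFDR < 0.05} with the top-k VIP features
(k = 10 by default), breaking VIP ties by feature id so selections are
deterministic. Score-plot ellipses are normal-theory chi-square ellipses;
Hotelling T² ellipses would be slightly wider at small n.

## Integrative pathway analysis

Pathways are signed, typed graphs over gene and compound nodes, loaded
from a one-file TSV dialect or from KEGG KGML XML (activation/expression
→ +1, inhibition/repression → −1, unsigned relations dropped and
counted). Three statistics are computed per pathway:

1. **ORA**: hypergeometric upper tail P(X ≥ k) with the universe
   restricted to features present in the summary tables, per mode (gene,
   compound) and jointly. The default significance rule flags
   |β| > 0.005 (an effect-size threshold appropriate for log-scale
   expression/abundance contrasts); an FDR-based rule (pFDR < 0.05 within
   each omic) is available because both conventions are in circulation
   and they can produce different counts.
2. **Perturbation (eSPIA-style)**: perturbation factors solve the linear
   system PF = ΔE + M·PF, where M divides each source node's signed
   influence by its out-degree; the statistic t_A = Σ(PF − ΔE) is the net
   accumulated perturbation. The null reassigns the observed nonzero ΔE
   multiset to uniformly random pathway nodes; the p-value is the
   median-centered two-sided bootstrap tail with add-one smoothing. A
   near-singular system (cyclic gain ≈ 1) is damped by a factor 0.99 with
   a warning. Because t_A = cᵀΔE for a fixed influence vector c, the
   bootstrap costs one dot product per draw. The *normalized* score
   divides t_A by the largest |t_A| attainable by pairing the biggest
   |ΔE| values with the most influential nodes — a documented convention
   that makes scores comparable across pathway sizes.
3. **Combination**: Fisher's method (χ²₄ upper tail, assuming
   independence) or a permutation-based strategy that estimates the joint
   null of (p_ORA, p_perturbation) by permuting the significance labels
   across the universe and taking the empirical tail of Fisher's
   statistic. The permutation p-values for the perturbation component
   reuse each pathway's precomputed influence vector and bootstrap null,
   which keeps the per-permutation statistic exact while avoiding a
   bootstrap-within-permutation blow-up. This strategy is an
   approximation to dependence-aware combination, not a reimplementation
   of any external method.

FDR and Bonferroni columns are reported over the tested pathway set, and
`m_tested` is reported explicitly so the divisor is never implicit.

## Identification by accurate mass

Monoisotopic masses come from an embedded table of most-abundant-isotope
masses (≥ 6 decimals). Adduct m/z is (m·M + shift)/|z|; [M+H]⁺ uses the
proton mass 1.007276 Da — not the hydrogen atom mass — and metal adducts
subtract one electron mass. Deltas divide by the reference adduct m/z.
Batch matching returns every record within tolerance sorted by delta
(ties by database id), and queries with no hit yield an explicit NA row:
absence from a database is a result, not an error. A practical note
encoded in the tests: deltas recomputed from values rounded to four
decimals can differ from full-precision deltas by ~0.1 ppm, so published
tables rounded at 4 dp are compared at that precision.

## Concentration calibration

For each scenario (form × weight × outlier rule) the standards are fitted
by weighted least squares (weights 1, 1/x, 1/x² — chosen against the
concentration–variance relationship of the assay), outliers are flagged,
all flagged levels are removed at once, and the model is refitted until
no flags remain, `max_iter = 5` passes elapse, or removal would drop
below 4 (linear) / 5 (quadratic) points. All-at-once removal is a
documented choice; worst-first removal would occasionally retain one more
level. R² for weighted fits is computed on the weighted scale (weighted
sums of squares about the weighted mean) so that 1/x² fits are not judged
by their absolute high-concentration residuals.

The outlier rules:

* **Cook's D** with the conventional 4/n cutoff.
* **CI**: a point is flagged when it falls outside its own 95% prediction
  interval computed *with the point deleted* (externally studentized
  residuals). The band from a fit that includes a gross outlier inflates
  its own residual variance and can mask the outlier entirely; the
  deleted version restores the intended behaviour at small n and is this
  package's documented divergence from a naive band check.
* **Bias**: back-calculated concentration deviating from nominal by more
  than 20%, using the current iteration's model. Note this rule is
  scale-aware by construction: an additive shift that is huge in
  intensity terms can still be under 20% of a high concentration.

A numerically exact fit (R² within 1e-10 of 1) reports no outliers under
any rule — residuals at machine precision otherwise produce arbitrary
flags. Scenarios are ranked by adjusted R² descending, ties broken by
fewer removed levels and then the simpler form. Inverse prediction solves
the linear or quadratic curve; for quadratics the real root inside the
fitted concentration range is returned, two in-range roots are an error
(the curve is not invertible there), and out-of-range responses carry an
extrapolation warning.

## The omics simulators

`simulate_feature_table()` generates log-scale Gaussian abundances for a
two-group design with age and ancestry covariates: defaults 30 samples
per group, 200 features of which 20 carry a group shift of δ = 1 residual
sd, covariate effects 0.01/unit age and 0.2 for ancestry, and 2% missing
/ 1% zero entries. The log-normal marginal is a testing convention
typical of metabolomics abundances, not a claim about any particular
dataset; the generator omits feature–feature correlation, batch effects
and intensity-dependent missingness, so power numbers from it are upper
bounds for real studies. `simulate_pathways()` adds random signed
gene+compound graphs with one enriched pathway whose members carry
planted effects, giving the pathway module a recoverable ground truth.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and restores the caller's
RNG state. The test suite exercises: null-calibration at 2,000 features,
Q² null behaviour over 100 replicates of n = 40, outlier detection over
200 replicates of 10-level ladders, and pathway recovery over tens of
seeded collections — sizes chosen so the full suite runs in well under a
minute per module on a single core while keeping Monte-Carlo assertions
comfortably away from their thresholds.

## Known limitations

Profile-mode spectra are rejected, not centroided; vendor raw formats and
ion mobility are out of scope. The targeted module does no untargeted
feature finding, isotope-pattern scoring, or chimeric-MS2 deconvolution.
Pathway analysis works from offline files — there is no live database
retrieval — and the permutation-based p-value combination is an
approximation whose calibration depends on the permutation count.
Calibration reports no LOD/LOQ and performs no formal bioanalytical
validation.
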