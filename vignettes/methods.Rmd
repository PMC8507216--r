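---
title: "Methods: CT radiomics modelling of time from stroke onset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT radiomics modelling of time from stroke onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`radonset` classifies the time from stroke onset (TFS) in M1 middle
cerebral artery occlusion into the thrombolysis-relevant classes
*early* (≤ 4.5 h) and *late* (> 4.5 h) from non-contrast CT. The premise
is physiological: cytotoxic edema progresses with time, so the MCA
territory becomes gradually more hypodense and texturally more
heterogeneous. The pipeline quantifies the territory with a 396-feature
radiomics vector, distills it into a scalar **rad-score**, and augments it
with screened clinical covariates in a logistic **combined model**

$$\mathrm{logit}\,P(\text{early}) = \gamma_0 + \gamma_1\,\text{rad-score}
  + \sum_j \gamma_j\, x_j,$$

where the rad-score itself is the penalized-logistic linear predictor
$\beta_0 + \sum_k \beta_k z_k$ over the standardized selected features.
The positive class throughout is *early*, so scores are oriented toward
thrombolysis eligibility.

# The synthetic cohort generator

No patient data ship with the package; a seeded generator emulates the
study conditions instead.

* **Stratum sizes.** The replica cohort holds exactly 46 early and 77
  late subjects (a `sample` mode draws class by Bernoulli(46/123)
  instead). The development/validation split replicates 85/38 by explicit
  sizes with stratified largest-remainder apportionment, rather than by
  rounding 0.7 × 123 (which gives 86).
* **Age** is truncated-normal on [18, 100] years, kept real-valued. The
  targets are mean ± SD 75.17 ± 12.39 (early) and 70.12 ± 12.97 (late).
  Because truncating N(75.17, 12.39²) at 100 would bias the mean down by
  about 0.7 years, the parent parameters are solved (closed-form truncated
  moments, Nelder–Mead) so the *truncated* distribution matches the
  targets exactly.
* **ASPECTS** is drawn from explicit probability vectors on 0..10 fixed in
  the default configuration, giving large-sample median (IQR) 8 (5–9) for
  the early and 6 (3–9) for the late stratum. Only the median/IQR are
  anchored; the full shape is a declared emulation choice.
* **NIHSS** is a discretized log-normal with `meanlog = log(median)` and
  `sdlog = log(q75/q25) / (2 Φ⁻¹(0.75))` per stratum (right-skewed
  positive score), clamped to 0–42.
* **Binary covariates** (sex, hypertension, diabetes, hyperlipidemia,
  atrial fibrillation, smoking, alcohol, HVS, ICA occlusion, side) are
  Bernoulli at the per-stratum prevalences of the default configuration;
  **collateral grade** uses a 0–3 distribution with median 1 and IQR 1–1.
* The master seed defaults to 20210123; every stochastic operation takes
  an explicit seed that overrides it, and identical seeds reproduce
  cohorts, phantoms, perturbations and splits bit for bit.

Within-class distribution shapes beyond the anchored summaries are
modelling choices, not inferences from data.

# The phantom generator

Each subject gets a CT-like volume (default 48³ voxels at 1 mm): a
background at 35 HU with spatially correlated Gaussian texture (SD 3 HU,
correlation length 1.5 voxels — typical brain-CT noise), a hemispheric
VOI template (radius 0.42 × the smallest extent) standing in for the MCA
territory, and an ellipsoidal lesion at the VOI core. Class effects:

* density decrement 1.5 HU (early) vs 3 HU (late) — deliberately subtle;
* extra lesion texture SD 1.5 vs 2.5 HU with correlation length 1.2 vs
  2.0 voxels (late lesions are more heterogeneous);
* lesion extent = `0.05 + 0.6 (10 − ASPECTS)/10` of the VOI volume, so a
  lower ASPECTS yields a larger lesion.

The lesion region is the exact `extent`-quantile of an anisotropic
ellipsoidal distance over the VOI, which makes the ASPECTS–extent rule
deterministic and strictly monotone. Initial defaults with background
noise of 1.5 HU made the classes linearly separable (validation AUC 1.0);
the shipped defaults were set once to the CT-realistic values above so
that the synthetic task, like the clinical one, is hard but learnable.

Rater variability is emulated by `perturb_mask()`: boundary-layer voxels
flip (inner removed, outer added) under a correlated noise field with
per-voxel probability `magnitude`, so the expected Dice overlap decreases
monotonically in `magnitude` and magnitude 0 is the identity.

What the phantoms do *not* emulate: skull/bone, CSF spaces, scanner
artifacts, partial-volume effects at tissue interfaces, or any CTA
content. Passing tests on phantoms therefore demonstrate the correctness
and internal consistency of the pipeline, not clinical performance.

# Preprocessing

Resampling is trilinear for intensities and nearest-neighbour for the
mask, to a 1 mm isotropic grid with output extent
`round(extent_mm / target)`. Intensities are windowed to [0, 80] HU (the
brain window) and mapped affinely to [0, 1] inside the mask only.
Discretization uses 64 fixed bins on [0, 1] with
`level = min(n_bins, floor(v·n_bins) + 1)`; values on an internal edge go
to the higher bin. Fixed bins over a fixed window keep gray levels
comparable across subjects, which matters because several texture
features weight absolute levels.

# The feature grid

The default inventory is 42 + 9 + 10 + 144 + 180 + 11 = 396 named
features. Conventions that needed fixing:

* Texture directions are the four in-plane angles applied per axial slice
  and accumulated across slices; `AllDirection` is the arithmetic mean and
  the population (divisor 4) SD over the four angles.
* GLCM displacement at 45°/135° means `offset` steps of the unit lattice
  vector (chessboard metric).
* The RLM `offset` is the sampling step of the ray: rays are sampled
  every `step` voxels and maximal same-level in-mask runs of consecutive
  samples are counted; step 1 is the classic run-length matrix, and an
  out-of-mask sample breaks a run.
* GLSZM zones are maximal 26-connected 3D components of equal-level
  voxels (computed as graph components of the equal-level adjacency).
* `SurfaceArea` uses exposed-voxel-face counting. A consequence worth
  knowing: the face-counted area of a digitized sphere converges to 1.5×
  the analytic area, so `Sphericity` of a ball converges to 2/3, not 1 —
  the tests assert that limit.
* Percentiles are nearest-rank (`ceil(p·n)`-th order statistic); histogram
  `Entropy`/`Uniformity`/`Mode` come from a 64-bin equal-width histogram.
* A constant intensity shift by an exact multiple of the bin width shifts
  all levels by an integer, which leaves every GLCM feature and the
  structural run/zone features invariant but *not* the gray-level-weighted
  emphases (`Low/HighGreyLevel...`); the invariance tests cover exactly
  the invariant subset.
* Degenerate cases are explicit: no valid pairs is an undefined-matrix
  error, zero marginal variance returns `Correlation`/
  `HaralickCorrelation` = 0 with a flag, and undefined angles propagate
  `NA` through the aggregation.

Every texture family is verified against brute-force enumeration oracles
(nested-loop pair/run/zone counting) on random ≤ 6×6×3 volumes at
|Δ| ≤ 1e−10.

# Selection and modelling

Standardization (mean 0, population SD 1) is estimated on the development
split only and re-applied, frozen, to validation data; re-standardizing an
already-standardized table is an error, which is how leakage is made
structurally impossible. The univariate filter routes each feature by
within-class Shapiro–Wilk normality (α = 0.05) to an equal-variance t test
or a Mann–Whitney U (exact when feasible, tie-corrected normal
approximation otherwise). Redundancy elimination is greedy: candidates
ordered by ascending univariate p (ties broken lexicographically) are
accepted iff |Spearman ρ| < 0.9 against all previously accepted features.
The survivor count of this stage is data-dependent by design — it is not
forced to any particular value. LASSO selection uses a 100-value
log-spaced λ grid spanning four decades below the data-derived maximum,
10-fold class-stratified CV with a recorded fold seed, and the
deviance-minimum λ. The rad-score uses the LASSO coefficients directly by
default; `refit = TRUE` re-estimates unpenalized coefficients on the
selected features, covering both readings of how such signatures are
assembled.

Clinical screening routes continuous covariates by normality, the ordinal
scores (ASPECTS, collateral grade) through Mann–Whitney, and binary
covariates through Pearson chi-square without continuity correction
(Fisher's exact when an expected cell is below 5). The combined model is
a plain ML logistic fit; quasi-separation (non-finite/huge coefficients
or fitted probabilities at the 1e−8 boundaries) triggers a ridge fallback
(penalty 1e−6) that is flagged on the object. Variables enter in a single
pass at p < 0.05 — no backward steps.

# Evaluation

* **DeLong machinery** (AUC variance, Wald 95% CI truncated to [0, 1],
  paired two-ROC test) is delegated to `pROC` behind the package's
  interface and cross-checked in the tests against exhaustive
  pair-counting AUC and a worked placement-value example; a degenerate
  variance of the paired difference reports p = 1 with a flag.
* **Operating points** maximize Youden's J with ties broken by higher
  sensitivity, then lower threshold.
* **McNemar** compares correctness-discordance with the exact two-sided
  binomial test for b + c < 25 and continuity-corrected chi-square above.
* **Hosmer–Lemeshow** uses equal-frequency deciles of predicted risk
  (ties grouped), statistic `Σ (O−E)²/(E(1−E/n_g))`, df = g − 2.
* **Decision curves** use `NB(p_t) = TP/n − (FP/n)·p_t/(1−p_t)` on a 0.01
  grid against treat-all and treat-none; the beneficial range is the
  longest contiguous run where the model strictly beats both comparators,
  reported to two decimals. With a strict inequality on a fine grid, pure
  noise produces short spurious runs (typically a few grid points), so an
  *empty* range is not a meaningful null expectation; the tests instead
  verify the net-benefit invariants everywhere and that informative
  models earn ranges an order of magnitude longer than null ones.
* **ICC**: inter-rater reliability uses ICC(2,1) (two-way random,
  absolute agreement, single measures), intra-rater ICC(3,1) (two-way
  mixed, consistency); both are available for either use through `mode`.
  Zero between-subject variance reports 0 with a flag.
* **Spearman** feature–clinical correlations use mid-ranks with the
  t-approximation p-value.

# Numerical and design choices

* Floats in CSV artifacts are serialized with 17 significant digits and
  JSON with full precision, so run manifests digest identically across
  reruns of the same configuration.
* All SD conventions are population (divisor n) unless a standard test
  dictates otherwise; this is asserted in the tests.
* glmnet's λ path, fold assignment and thresholds are fully pinned by the
  recorded seed, making `lasso_select()` bit-reproducible.
* The connected-component labelling and maximum-diameter computations are
  exact (graph components; convex-hull-bounding axis-extremal candidate
  reduction), not approximations.

# Problem sizes used by the test-suite studies

Simulation-based checks run at sizes chosen to make their statistical
assertions sharp but cheap: generator calibration at n = 10,000 per
stratum; LASSO recovery with 6 informative + 94 noise features at
n = 300 over 100 seeds (≥ 80 must recover ≥ 4 signal features); DeLong CI
coverage over 1,000 binormal replicates of 100 + 100 subjects;
Hosmer–Lemeshow uniformity over 200 replicates of n = 2,000; the
end-to-end determinism check runs the full 123-subject pipeline twice at
the default 48³ phantom resolution. The feature-level signal generator
(`simulate_signal_table()`) plants a 0.5 log-odds effect per informative
feature plus age (+0.03 per year) and ASPECTS (+0.15 per point) effects,
oriented as in the clinical generator (early-window patients older, with
higher ASPECTS).

# Known limitations

* Phantoms exercise the pipeline, not clinical validity; absolute AUCs on
  synthetic cohorts depend on the chosen effect sizes.
* The 396-feature inventory is a reconstruction of a commercial kit's
  unpublished membership: the family totals and the naming grid are
  pinned, individual definitions follow the field's standard forms.
* The 2.5D direction scheme (in-plane angles accumulated over slices) is
  the default; a full 13-direction 3D mode is intentionally out of scope.
* DeLong CIs are the only interval machinery; no bootstrap.
* No DICOM ingestion, no skull stripping, no automated VOI segmentation —
  the mask is an input by contract.
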