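---
title: "Multiphase delta-radiomics for TACE response: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiphase delta-radiomics for TACE response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltarad)
```

## The problem

Transcatheter arterial chemoembolization (TACE) is a standard locoregional
therapy for hepatocellular carcinoma (HCC). Whether a given tumor will
respond is decided months later by RECIST follow-up; the question this
pipeline addresses is whether the pre-treatment, four-phase
contrast-enhanced CT appearance of the tumor already predicts that outcome.
Cases are grouped by RECIST category into an *ease* (response: CR, PR) and
a *relief* (non-response: SD, PD) group, and a binary classifier is built
from quantitative image features of the tumor volume of interest (VOI).

The package implements the complete analysis as reusable, tested R
functions: VOI feature extraction, inter-phase change-rate features, a
three-stage feature-selection cascade, a soft-margin kernel SVM trained by
sequential minimal optimization, and ROC-based evaluation — all exercised
end-to-end on a synthetic phantom cohort, since no patient images are
distributed.

## Feature model

Each case consists of four aligned phases (arterial early, mid, late, and
the hepatobiliary phase) plus one binary tumor mask. Per phase the package
extracts a fixed 43-feature block:

* **12 first-order features** — mean, median, minimum, maximum, range,
  population variance, skewness, excess kurtosis, mean absolute deviation
  on the raw in-mask intensities, and energy, entropy, uniformity on the
  normalized gray-level histogram. Histogram energy and uniformity are
  synonyms (both the angular second moment of the histogram); the registry
  carries both names, and the duplication is harmless because the
  correlation filter removes one of them downstream.
* **24 texture features**, direction-averaged: 9 from the gray-level
  co-occurrence matrix (GLCM), 11 from the run-length matrix (GLRLM) and 4
  from the zone-size matrix (GLZSM). GLCM and GLRLM are computed per axial
  slice along the four in-plane angles 0°, 45°, 90°, 135° and accumulated
  over slices (a "2.5D" convention that matches the four named angles);
  the four directional values are averaged, so 24 × 4 = 96 directional
  evaluations feed 24 final features. The zone-size matrix is inherently
  direction-free; it is computed once over the 3D VOI (26-connectivity
  components of equal gray level) and replicated across directions so the
  accounting holds and the average is a no-op.
* **7 morphological features** — volume, surface area (exposed voxel
  faces), density (mean in-mask intensity), maximum 3D diameter over
  surface voxels, sphericity, compactness and surface-to-volume ratio, all
  in physical units derived from the voxel spacing.

Texture matrices require discrete gray levels. Intensities are quantized
to `G` equal-width bins over the in-mask range (default `G = 64`,
configurable); this fixed-bin-count scheme is the most common radiomics
convention and bounds matrix sizes. A constant VOI maps entirely to level
1, which keeps the degenerate limits well defined (entropy 0, energy 1).
All entropies use log base 2. Degenerate-distribution conventions:
skewness and kurtosis of a constant sample are 0; the correlation of a
zero-variance GLCM is 1. GLCM homogeneity is the inverse difference
moment, sum over p/(1 + (i − j)²).

## Multiphase assembly and change rates

The multiphase static vector has **115 features**: the 36 dynamic
(first-order + texture) features of each of the three arterial phases plus
the 7 morphological features (36 × 3 + 7 = 115). Tumor geometry does not
change between phases, so morphology enters once (its density uses the
arterial-early intensities).

Variation between phases carries information of its own. For every dynamic
feature x and every adjacent phase pair (r earlier, l later) the package
forms the relative change rate

$$\tilde{x}_{l-r} = \frac{x_l - x_r}{x_r},$$

giving **108 delta features** (36 × 3 transitions: early→mid, mid→late,
late→hepatobiliary). The hepatobiliary block contributes through the last
transition. When a reference value is numerically zero (|x_r| < 1e-12)
the change rate is undefined; the pipeline returns 0 with a warning rather
than propagating infinities — zero references only occur for degenerate
phantoms. Note the useful identity tested in the suite:
$\tilde{x}_{l-r} = -\tilde{x}_{r-l} / (1 + \tilde{x}_{r-l})$.

Five nested feature sets are exposed for experiments: S1 morphology (7),
S2 static dynamic (108), S3 delta (108), S4 static + morphology (115), S5
everything (223). The published description of the set composition is not
fully recoverable, so this five-set structure is the package's declared
reconstruction; it preserves all stated counts.

## Selection cascade

Selection runs in a fixed order, each stage only removing columns:

1. **Correlation filter** (`drop_correlated`): greedy keep-first scan in
   registry order; a column is dropped when |Pearson r| ≥ 0.9 (default)
   against any earlier kept column. Deterministic; zero-variance columns
   are kept and flagged (their correlation is undefined, treated as 0).
2. **Welch t-screen** (`t_screen`): unequal-variance two-sample t per
   column; keep p < 0.05. No multiple-testing correction — the screening
   is deliberately raw, matching the published cascade; this is
   scientifically debatable and is why the downstream LASSO and the
   nested evaluation matter.
3. **LASSO** (`lasso_select`): L1-penalized logistic regression (glmnet),
   penalty chosen by cross-validated binomial deviance with the
   one-standard-error rule (falling back to the deviance minimum when the
   1-SE model is empty); selected features are the nonzero coefficients.

The threshold 0.9, alpha 0.05 and the keep-first tie-break are package
defaults, stated here because the source analysis reports no values.

## The classifier

The soft-margin kernel SVM is implemented from its optimization problems.
The primal minimizes ½‖N‖² + C Σ θ over weights N, bias a and slacks
θ_r ≥ 0 subject to y_r(Nᵀφ(x_r) + a) ≥ 1 − θ_r; the package solves the
kernelized Lagrangian dual

$$\max_\beta \sum_r \beta_r - \tfrac12 \sum_{i,l} \beta_i \beta_l y_i y_l
W(x_i, x_l), \qquad 0 \le \beta_r \le C, \quad \sum_r \beta_r y_r = 0,$$

with W one of the canonical kernels (linear, polynomial, RBF). The solver
is SMO with maximal-violating-pair selection and full gradient
maintenance, stopping when the KKT violation gap falls below `tol`
(default 1e-3; the unit suite verifies the box constraint, the dual
equality, KKT complementarity, the analytic two-point solution, and
agreement of the dual objective with a dense projected-gradient QP solver
to 1e-6). The bias is averaged over free support vectors. Defaults: C = 1;
RBF gamma 1/(p · Var(X)). A decision value of exactly zero predicts +1.
Class weighting is not implemented (the study design is balanced 24/24).

## Evaluation

Labels come from RECIST via the ease/relief mapping; ease is the positive
class. Three split schemes are provided: stratified hold-out, stratified
k-fold (default, k = 5) and bootstrap with out-of-bag testing. The central
design decision is that **the entire selection cascade is refit inside
every training split** — selection on the full cohort before splitting
leaks test information and inflates AUC. The leaky variant remains
available as `paper_mode = TRUE` for comparison, since the source analysis
does not describe its leakage control.

Out-of-fold decision values are pooled into one ROC (threshold sweep over
unique scores, simultaneous steps on ties, anchored at (0,0) and (1,1));
AUC is the trapezoidal area, identical to the tie-halved concordant-pair
fraction. The operating point maximizes the Youden index with ties broken
toward the lower (more sensitive) threshold. AUC grades follow the
conventional bands: > 0.9 excellent, 0.7–0.9 good, otherwise average.

## The phantom generator

No patient data are deposited, so the generator is a first-class module
that emulates the study's conditions: a balanced cohort (default 24 + 24)
of four-phase volumes on a 48³ grid at 1 mm isotropic spacing. Each case
is an ellipsoidal VOI (semi-axes 8–16 mm, jittered center) filled with a
phase- and class-dependent mean plus spatially correlated Gaussian texture
(white noise filtered by a separable Gaussian kernel, then standardized).

The two classes differ in three planted properties, chosen to give each
feature family a recoverable signal:

* **enhancement dynamics** — responders: mean profile (110, 160, 135, 95)
  across the four phases, i.e. strong arterial enhancement with washout;
  non-responders: the flat profile (110, 125, 120, 112). These HU-like
  values are in the range of contrast-enhanced liver lesions and drive
  the delta features.
* **heterogeneity** — noise SD 12 for responders, doubled for
  non-responders (more heterogeneous texture in non-responding tumors).
* **texture grain** — Gaussian correlation length 2 voxels (ease) vs 1
  voxel (relief), separating co-occurrence, run and zone statistics.

A per-case log-normal intensity gain (SD 0.1) emulates scanner/injection
gain variability; it is shared across a case's phases, so change rates are
invariant to it while absolute per-phase intensities jitter. RECIST labels
are drawn within the correct class (responders CR/PR, non-responders
SD/PD); there is no label noise.

What the phantom does **not** emulate: liver background anatomy, realistic
tumor shapes, CT physics (beam hardening, iodized-oil artifacts), phase
misregistration, and inter-reader mask variability. Passing the end-to-end
tests therefore demonstrates that the pipeline recovers a signal of the
planted kind at realistic size and noise — not clinical performance on
real cohorts, whose reported sensitivity/specificity/AUC cannot be
reproduced without the undeposited images.

A tabular analogue (`generate_feature_table`) draws class-shifted normal
columns (default effect 1.5 SD) plus pure-noise columns and optional exact
duplicates, for fast calibration tests of the selection stages: t-screen
type-I error at the nominal alpha, duplicate removal by the correlation
filter, and LASSO recovery of planted columns.

## Numerical and scale choices

* Quantization: `G = 64` levels by default; the texture oracles in the
  test suite run at `G` 4–8 on ≤ 8³ grids where brute-force enumeration is
  exact and fast.
* The SMO tolerance is 1e-3 for pipeline use and tightened to 1e-6–1e-8 in
  oracle comparisons; the iteration cap (100 × max(m, 100)) is never
  reached in the shipped experiments and is reported via `converged`.
* Maximum 3D diameter is computed exactly over surface voxels with
  chunked distance evaluation to bound memory.
* Unit and pipeline tests run on reduced phantoms (16³–24³ grids, 4–20
  cases) chosen so the whole suite completes in minutes; the acceptance
  checks use the full default conditions (48³, 24 + 24, seed 1).
* All stochastic stages (phantom, fold assignment, LASSO CV) are driven by
  explicit integer seeds; reruns are bit-identical.

## Known limitations

* 2.5D texture only; no 13-direction 3D variants and no filtered/wavelet
  feature classes.
* The five-set composition and the 24-feature texture split (9 + 11 + 4)
  are reconstructions constrained by the published counts and the named
  members (sum entropy, cluster shade, run-length non-uniformity, HIE,
  HILAE — all present).
* The t-screen is uncorrected for multiplicity by design fidelity.
* Binary classification only; no probability calibration; no class
  weights.
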