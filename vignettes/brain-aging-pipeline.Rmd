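---
title: "Harmonized brain-aging indices for multi-site ROI volume cohorts"
author: "BrainSpare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonized brain-aging indices for multi-site ROI volume cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BrainSpare)
```

## The problem

Cohort studies of brain aging compare regional gray-matter volumes (ROI
volumes, mm^3) between a clinical group and controls, with images acquired on
many scanners. Two obstacles dominate: scanner-specific location and scale
effects that masquerade as biology, and the need to compress ~145 correlated
ROI volumes into interpretable indices. This package implements a complete
analysis chain for that setting:

1. **ComBat-GAM harmonization** — per-ROI location/scale batch correction
   with empirical-Bayes shrinkage, preserving covariate effects including a
   nonlinear age trend, applied twice: across scanners within the study,
   then from the study to a large reference cohort whose space the index
   models live in.
2. **SPARE indices** — a brain-age index (SPARE-BA: linear support vector
   regression predicting age from ROI volumes of healthy controls; values
   above chronological age mean advanced brain aging) and an AD-signature
   index (SPARE-AD: linear SVM separating amyloid-positive AD cases from
   controls; positive scores mean AD-like atrophy).
3. **A years-equivalent statistic** — the group difference in SPARE-BA
   expressed in years of aging, as the ratio of the group coefficient to the
   age coefficient of a linear mixed model.
4. **Association stages** — group contrasts, single-covariate scans,
   multivariable backward elimination, region-wise scans under
   Benjamini–Hochberg FDR control, and cognition-domain associations, with
   longitudinal risk factors summarized by time-weighted means.

Because the motivating cohort data are not public, the package ships a
synthetic-data generator that reproduces the statistical structure every
stage assumes, with known injected effects, so the whole chain is testable
end to end.

## Harmonization model

For ROI $v$, subject $i$ on batch (scanner) $b$:

$$y_{iv} = \alpha_v + f_v(\text{age}_i) + X_i \beta_v +
  \sigma_v\,(\gamma_{bv} + \delta_{bv}\,\varepsilon_{iv})$$

where $f_v$ is a penalized cubic regression spline (basis dimension 10,
smoothing chosen per ROI by generalized cross-validation over a log-spaced
grid), $X_i$ holds linear covariate terms (sex, ICV, diagnosis one-hot with
controls as reference), $\gamma_{bv}$ and $\delta_{bv}$ are the batch
location (standardized units) and scale (multiplicative) effects, and
$\sigma_v$ is the pooled residual SD. Batch indicators are unpenalized
columns of the same design, so residuals are exactly orthogonal to batch and
the size-weighted mean of the location estimates is zero by construction.

The raw per-batch estimates $\hat\gamma_{bv}, \hat\delta^2_{bv}$ are shrunk
by parametric empirical Bayes — normal prior on $\gamma$, inverse-gamma on
$\delta^2$, prior moments estimated across ROIs within each batch — iterated
to a relative tolerance of $10^{-4}$ (cap 100 iterations; non-convergence is
an error that reports the last change). Harmonized values are

$$y^*_{iv} = \frac{(y_{iv} - \hat\mu_{iv})/\sigma_v - \gamma^*_{bv}}
  {\delta^*_{bv}}\,\sigma_v + \hat\mu_{iv},$$

with $\hat\mu_{iv}$ the covariate-model prediction. With a **reference
batch**, standardization is anchored at that batch (its coefficients and
residual variance define $\alpha_v, \sigma_v$) and its effects are fixed at
$\gamma^* = 0, \delta^* = 1$, so reference rows pass through bit-identical.

Two properties of the empirical-Bayes step matter for interpretation and are
covered by tests rather than assumed:

* Shrinkage pulls per-ROI batch effects toward the batch's cross-ROI prior
  mean. A *common* injected shift (the same mm^3 on every ROI) is removed
  essentially exactly, while per-ROI deviations retain sampling-scale
  residuals — the same behavior as the reference implementation in `sva`.
  Shrinkage vanishes as batches grow.
* After any location-removing harmonization, a scanner ANOVA on the
  harmonized residuals is conservative (p-values pile near 1), not uniform;
  the tests therefore check that no residual or spurious scanner effect
  survives at the nominal rate, and that the *generator's* null is uniform
  before harmonization.

**Two-step design.** Step 1 harmonizes across study scanners with
covariates {age, sex, ICV, diagnosis}. Step 2 treats the whole study as one
batch against the pooled reference with covariates {age, sex, diagnosis}
and the reference as reference batch. Design choices where the setting was
genuinely open: the reference cohort is held fixed (reference-batch mode is
the default, since the index models are trained in the reference space;
joint re-estimation is available by simply not setting a reference batch),
and ICV is *not* a step-2 covariate, following the narrower published
covariate roster for the study-to-reference step.

## SPARE indices

Both indices are linear models over ROI volumes standardized with
training-set constants that are frozen into the model. SPARE-BA is an
$\varepsilon$-insensitive linear SVR ($\varepsilon = 0.1$ years) trained on
controls only (n >= 50 enforced); SPARE-AD is a linear soft-margin SVM
trained on AD cases versus controls (each class n >= 20), its score the
signed decision value oriented so AD is positive. The regularization
constant is selected by inner 5-fold cross-validation over the grid
$10^{-3} \dots 10^3$ — walked in increasing order with early stopping once
the cross-validated criterion (MAE for BA, balanced accuracy for AD)
plateaus for two consecutive steps, because the linear-SVM regularization
path is flat beyond its optimum while high-cost fits dominate runtime;
search-phase fits use a loosened optimizer tolerance, the final fit the
default one. Held-out accuracy reported in `trainingMeta` comes from an
outer 5-fold loop with the selection repeated per fold. A linear kernel is
used for both indices (interpretability; the published description
specifies linear only for the classifier). No post-hoc brain-age bias
correction is applied; the years-equivalent statistic below is
self-calibrating because regression-dilution attenuation affects its
numerator and denominator alike.

## The years-equivalent statistic

With SPARE-BA scores $s_i$, the mixed model

$$s_i = \beta_0 + \beta_G\,\text{group}_i + \beta_A\,\text{age}_i +
  \beta_I\,\text{ICV}_i + u_{scanner(i)} + e_i$$

gives the brain-aging gap $\beta_G / \beta_A$ in years, with a delta-method
standard error from the fixed-effect covariance. A non-positive age
coefficient is an error (the brain-age model is degenerate, the ratio
meaningless). ICV is standardized internally for numerical stability; the
ratio is invariant to affine ICV rescaling. Scanner enters as a random
intercept; with a single scanner the model falls back to fixed effects with
a warning. The worked published-scale example — group coefficient 6.16,
age coefficient 1.04 — yields 5.92, "approximately 6 years".

## Longitudinal summaries

Quantitative risk factors observed at irregular visits are summarized by the
time-weighted mean $\sum w_i v_i / \sum w_i$, $w_i = t_i - t_{i-1}$, with
$t_0 = 0$ at baseline. Two ambiguities were settled as follows: a baseline
visit gets zero weight ("interval since the last measurement" is undefined
there), except that a single-visit series returns its value; and the window
beyond the last visit adds no weight (no last-value carry-forward), because
the rule weights elapsed intervals between measurements only. Event-type
covariates become ever-event flags within the window and a cumulative
severe-hypoglycemia count binned as 0 / 1–5 / >5 events.

## Association stages

Covariate scans fit one linear model per covariate, adjusted for age, sex
and scanner (fixed effects), reporting signed t values; constant covariates
are flagged, not fitted. Backward elimination starts from the joint
candidate model, removes the least significant candidate with p >= 0.10
(refitting after every single removal; ties resolved toward the
lexicographically first name), then drops candidates with p >= 0.05 in one
final refit; age, sex and scanner are never removed. The region-wise scan
fits `volume ~ group + age + sex + ICV + scanner` per ROI (ICV included by
default; a toggle exists since its inclusion in regional models is a
judgment call), reports $\beta$ divided by the ROI residual SD as a
standardized effect size, and adjusts p-values across ROIs — and only
across ROIs — by Benjamini–Hochberg. Cognitive domain scores are unweighted
means of per-test z-scores computed against reference means/SDs, with
configurable per-test sign flips for timed tests where higher raw scores are
worse; subjects missing some tests of a domain get the mean of the available
ones (flagged), subjects missing all of them get `NA`. All p-values are
two-sided.

## The synthetic cohort generator

`generateCohort()` and `generateReferenceCohort()` emulate the cohort
structure of the motivating study: by default 416 study subjects and 99
controls aged 44–74 on 24 scanners, a reference pool of 2764 controls plus
221 AD-pattern cases, and 145 ROIs. Per ROI the generating model is

$$y_{iv} = \text{baseline}_v - r_v\,q(\text{age}^{\text{eff}}_i) +
  b^{sex}_v(\text{male}_i - 0.5) + b^{icv}_v(\text{ICV}_i - \overline{\text{ICV}})
  + \text{shift}_{bv} + \text{scale}_{bv}\,\varepsilon_{iv}$$

with $q$ a monotone quadratic ramp that plateaus at high age (a nonlinear,
monotone-decreasing volume trend without committing to a specific atlas),
age-sensitive ROIs ($r_v > 0$) forming a configurable fraction of the
atlas, and a disjoint AD-signature subset (~15% of ROIs, emulating temporal
regions) that receives the AD atrophy effect in units of the analytic
marginal SD. Accelerated aging in the study group is an **age shift** of
`agingOffsetYears` on the age-sensitive ROIs only — not a volume shift — so
the years-equivalent statistic has a ground truth in years and, because the
signature ROIs are untouched, SPARE-BA and SPARE-AD dissociate by
construction. Scanner assignment is balanced-random within each group so
group and scanner effects are separable. ROI-level parameters (baselines,
slopes, coefficients, role assignment) are drawn once under a fixed internal
seed: the user seed changes subjects, noise and site effects, never the
underlying curves, and an identical configuration is bit-reproducible.

The magnitudes the study itself does not report — per-scanner shift SD
(100 mm^3), log-scale SD (0.15), residual noise SD (120 mm^3), affected
fraction (0.5) — are exposed in `SimConfig` with defaults chosen once to
give per-ROI age signals several times the noise over the 30-year span,
which is what makes a desk-scale brain-age model (~1 year held-out MAE on
500 training controls) realistic. A `studyShift` field adds a global
study-versus-reference offset for exercising the second harmonization step.

What the generator does **not** emulate, and what passing tests therefore
cannot show about real data: spatial correlation between ROIs beyond the
shared ICV/sex factors, non-Gaussian site effects, scanner-by-age
interactions, heavier-tailed measurement error, longitudinal within-subject
imaging, and selection effects in who gets scanned. Results on it validate
the machinery — effect recovery, calibration, error control — not anatomy.

## Problem sizes and numerical choices

The test-suite simulations use 100–500 subjects per cohort, 20–100 ROIs and
2–10 scanners; the end-to-end recovery check runs 20 seeds at 500 study +
500 reference subjects, 100 ROIs, 10 scanners, and expects the 6-year
offset back within ±1.5 years on the seed average. GCV searches 40
log-spaced smoothing values; the EB tolerance is $10^{-4}$; cohorts with a
single batch yield an identity harmonization model; fewer than four ROIs
disable cross-ROI shrinkage (no prior moments to estimate). Degenerate
inputs error early and informatively: batches under 3 subjects,
rank-deficient designs (naming the collinear columns), unknown batch labels
at apply time, covariate rosters that do not match the fitted model, ROI
rosters that do not match a SPARE model, out-of-(0,1] p-values. Ages outside
the fitted range are linearly extrapolated by the spline basis with a
warning.

## Limitations

The harmonization is cross-sectional (no within-subject longitudinal
ComBat) and ROI-level (no voxel-wise correction). The SPARE models here are
trained on synthetic reference cohorts — the package does not reproduce any
published model weights. Backward elimination inherits the usual caveats of
stepwise selection (post-selection inference is not corrected). The
years-equivalent statistic assumes an approximately linear age trend of the
index over the cohort's age range; strong nonlinearity would make "years"
age-dependent.
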