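---
title: "Single-cell AFM mechanics of red blood cells: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell AFM mechanics of red blood cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcmech)
library(dplyr)
```

## The measurement and the model

An AFM force spectroscopy experiment on a red blood cell records
force-distance (FD) cycles: the piezo drives a conical tip toward the cell
until a setpoint force (here 2 nN) is reached, then retracts. Per cycle the
instrument stores piezo height and cantilever force for the approach and
retract segments. `rbcmech` converts these raw cycles to force versus
indentation depth and extracts five mechanical parameters per curve:

* **Apparent Young's modulus E (Pa).** The shallow-contact regime follows
  the Sneddon model for a conical indenter on an elastic half-space,
  \[ F(\delta) = \frac{2 E \tan\alpha}{\pi (1 - \nu^2)}\, \delta^2 , \]
  with tip half-angle $\alpha$ and Poisson ratio $\nu = 0.5$
  (incompressible cell). The model is linear in $E$, so the least-squares
  estimate over the fit window is closed-form. The fit is restricted to
  approach samples with force in 0-250 pN, which for a cell of roughly
  1-1.5 kPa corresponds to several hundred nanometres of indentation. $E$
  is *apparent*: no substrate decoupling is attempted (deliberately out of
  scope -- see Limitations).
* **AFM stiffness S (N/m).** The OLS slope of force versus indentation
  over the 250-750 pN window, where the response is approximately linear
  and the thin cell is squeezed against the dish. $S$ mixes cell and
  substrate contributions on purpose: at these depths the deformation
  resembles what the cell experiences in capillaries, and as a comparative
  marker the substrate contribution is common to all measurements.
* **Dissipated energy DE (J) and hysteresis H.** Trapezoidal areas under
  the approach ($A_E$) and retract ($A_R$) branches over the common
  indentation support give $DE = A_E - A_R$ and $H = DE / A_E$.
* **Work of adhesion WA (J).** The magnitude of the integrated retract
  force over the contiguous below-baseline dip after pull-off. Most curves
  have no dip; WA is then 0 and no flag is raised.

Maps of 8 x 8 = 64 curves cover one cell plus bare dish. Pixels whose
contact height lies within 500 nm of the substrate plane (the robust 10th
percentile of contact heights) are masked out; features are averaged over
cell pixels per cell, then over cells (unweighted) per patient -- a
two-level mean in which cells, not pixels, are the replicates. The cell
height is the apex contact height above the plane.

## Contact-point detection

Instrument exports carry no contact point, so detection is automatic and
three-staged: (1) a linear baseline is fitted to the far 30% of the
approach piezo range and removed; (2) the first sustained crossing of
`max(3 x baseline RMS, 10 pN)` gives an initial contact estimate; (3) the
estimate is refined by back-extrapolating the Sneddon law -- over the
low-force window $\sqrt{F}$ is linear in indentation, and the intercept of
that regression relocates the contact point. On noiseless synthetic curves
this recovers the true contact point to well under a sample spacing; the
unit tests hold it to two spacings with 5 pN noise. Indentation is piezo
travel minus cantilever deflection, $\delta = (z_0 - z) - (F - b)/k$;
reported ~600 nm indentations at 2 nN presuppose exactly this correction.

Failures are flags, not exceptions (`no_contact`, `noisy_baseline`,
`low_max_force`): a force map routinely contains invalid pixels, and the
pipeline's job is to drop them from aggregation while counting them.

## Numerical and design choices

* **Window membership.** Samples whose force lies inside the closed
  window; no edge interpolation; at least 10 samples or the fit refuses
  (classed error). Simple and exactly testable.
* **Negative retract forces.** Excluded (clipped at 0) from $A_R$, so $H$
  stays in $[0, 1]$ even on adhesive curves; the dip energy is reported
  separately as WA. The alternative reading (dip included in $A_R$, so $H$
  can exceed 1) is available via
  `processing_config(include_negative_retract = TRUE)`; we default to the
  fraction reading because $H$ is defined as a normalized energy.
* **Retract support.** The approach is clipped at contact
  ($\delta \ge 0$), but the retract keeps its negative-indentation tail:
  that is where the adhesion dip physically lives (positive tip-sample
  separation after pull-off).
* **Slope axis.** $S$ is fitted against indentation (tip-sample distance),
  not piezo height, so it is a sample property in N/m comparable across
  cantilevers of different stiffness.
* **Units.** SI throughout (N, m, Pa, J); presentation layers convert
  (mN/m for logistic coefficients, 1e-16 J for dissipation displays).
* **Per-feature exclusion.** A rim pixel whose approach never reaches
  750 pN loses its slope but keeps its modulus: features are dropped
  per-feature, not per-pixel, which maximizes usable data.
* **Cell/substrate threshold** of 500 nm: far above piezo noise, far below
  the ~2.5 um cell apex. Raising it can only shrink the mask (a tested
  monotonicity property).

## The statistics layer

The cohort table (one patient per row: group, sex, demographics,
blood-panel biochemistry, per-patient mechanical means) flows through:

* **`summarize_cohort()`** -- medians (Q1, Q3) per group,
  Wilcoxon-Mann-Whitney p (exact when the pooled untied sample is at most
  20, normal approximation with tie correction otherwise), Fisher/chi-square
  for categorical variables (Fisher when any expected cell count is below
  5), and the DeLong ROC-AUC with 95% CI per marker. Missing values are
  dropped pairwise -- complete-case per analysis is unbiased under
  missingness completely at random, which is how the generator creates
  holes.
* **`roc_auc_delong()` / `compare_roc()`** -- DeLong variance components
  via pROC; `direction = "auto"` orients each marker so the AUC is the
  better of the two directions, as biomarker tables conventionally report
  (an RBC-count *decrease* in cases still yields AUC > 0.5). Curve
  comparison fixes a common direction, which the paired DeLong difference
  requires.
* **`fit_logistic()`** -- at most two predictors without a warning (16
  cases cannot support more), McFadden pseudo-R^2 (the `Pseudo R2` of
  common econometric output), LR chi-square model test, separation
  diagnostics.
* **`stepwise_aic()`** -- backward-forward `stats::step()` from the full
  model on all candidates passing the univariate p < 0.25 screen. Moves
  happen only on strict AIC improvement, so ties resolve toward the
  smaller model. Note a property of AIC itself: a pure-noise candidate
  survives with asymptotic probability $P(\chi^2_1 > 2) \approx 0.157$,
  so with three noise candidates the *exactly-the-signal* selection rate
  sits near $0.843^3 \approx 0.60$; the informative variable itself is
  essentially always retained. The tests assert both facts.
* **`loocv_accuracy()`** -- an explicit leave-one-out loop with a 0.5
  threshold; failed folds are flagged and counted rather than silently
  dropped. Cross-checked against `boot::cv.glm` in the tests.
* **`spearman_matrix()`** -- Spearman rho on pairwise-complete pairs; a
  correlation is flagged significant only when p < 0.05 *and* the pairwise
  n reaches 80% Fisher-z power to detect the observed $|\rho|$. The power
  filter is our concrete stand-in for an under-specified "power analysis"
  step: it keeps small-sample flukes from being flagged while still
  reporting every coefficient.
* **`cullen_frey()`** -- sample skewness^2 and (non-excess) kurtosis of
  pooled values plus a seeded bootstrap cloud (>= 200 replicates). The
  moment convention matches `fitdistrplus::descdist(method = "sample")`,
  against which it is tested. Pooled single-cell moduli are right-skewed
  and land near the log-normal locus of the plane.
* **`predict_mc_probability()`** -- the reference bivariate probability
  function combining AFM stiffness and RBC count. The published closed
  form carries no intercept while the fitted reference model reports one
  (7.84); both behaviours are exposed and the no-intercept form is the
  default, following the closed form verbatim. Without the intercept the
  absolute probabilities are shifted, but the function remains strictly
  increasing in stiffness and decreasing in RBC count, and probability
  *contours* are unaffected.

## What the synthetic generator emulates -- and what it does not

The generator exists so that every stage is testable with known ground
truth, and it doubles as the power-analysis engine for the study design.

**Curves.** Forward Sneddon parabola to 250 pN, optionally blending into a
stiffer linear regime (controllable slope, emulating the growing substrate
contribution), retract scaled by a hysteresis ratio, optional triangular
adhesion dip (default 100 pN x 200 nm, i.e. WA = 1e-17 J), Gaussian force
noise, 2 nN setpoint, all folded back into piezo coordinates. **Maps.**
Spherical-cap cell (apex 2.64 um, footprint radius 3.75 um) centred on a
pixel of a 12 um scan, stiff-substrate pixels elsewhere. **Cohort.** 22
controls / 16 cases; per-variable group medians and IQRs from the
calibration table (`default_cohort_targets()`); log-normal families for
the right-skewed mechanical variables, truncated normals for biochemistry;
missing-completely-at-random holes (default 8%) in the biochemical panel;
adhesion on 5% of control and 25% of case curves, reflecting its sporadic,
case-dominated occurrence. Cell-level values scatter log-normally
(sigma = 0.35) around patient means, mean-centred so patient aggregates
stay calibrated.

Deliberately **not** simulated: correlations among biochemical variables
(drawn independently -- the dependence structure is unreported),
viscoelastic time/rate dependence, rouleaux formation, instrument drift
beyond a linear baseline, and any link between biochemistry and mechanics
within a group. Consequently, passing tests demonstrate that the pipeline
recovers what the forward model puts in and that the statistical layer has
its nominal operating characteristics; they do not validate the biological
claims on real cohorts, whose raw data are not publicly deposited.

A consequence worth knowing: at the calibrated 22/16 design the Wilcoxon
test on stiffness rejects in roughly 60% of generator replicates -- the
published single-cohort significances are plausible but not guaranteed
outcomes at this sample size, which is precisely why the tests assert
majorities and operating characteristics, not single p-values.

## Problem sizes used by the test-suite

Chosen to make the checks sharp while keeping the default run quick: 1,000
random curves for the hysteresis/dissipation identity; 100 random
instances (n <= 30) for the DeLong-versus-pair-counting identity; 2,000
simulated markers (n = 40, true AUC 0.75) for CI coverage; 20 replicates
of n = 4,000 for logistic coefficient recovery; 100 seeds for stepwise
selection; 10 replicate draws of n = 1e5 for the log-normal closed-form
moment check (the kurtosis estimator's per-draw sampling SD is ~5.6% at
that n, so the Monte-Carlo mean is the quantity with a 5% handle); and a
full seeded simulate-to-report pipeline run on the default 22/16 cohort.

## Known limitations

* $E$ and $S$ are uncorrected for substrate stiffness and tip geometry
  error; they are comparative markers, not material constants.
* The contact-point refinement assumes the shallow regime is Sneddon-like;
  grossly non-parabolic contacts fall back to the threshold crossing.
* With 16 cases, every multivariate result is fragile; the package warns
  above two predictors rather than refusing.
* The Cullen-Frey plane summarizes shape through two moments only; it
  suggests families, it does not test them.
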