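---
title: "Benchmarking ROI single-value summary measures for task fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking ROI single-value summary measures for task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roisum)
```

## The model

A task fMRI study reduces each subject's 4-D BOLD series to a 3-D contrast
map by a per-voxel linear model. `roisum` implements the minimal version of
that chain and everything downstream of it, so that the *summary-measure*
question — which single number best represents an ROI — can be studied with
full control of the ground truth.

**First level.** For voxel $v$ with timecourse $y_v$ and design matrix $X$
(task boxcar + intercept at minimum), ordinary least squares gives
$\hat\beta_v = c^\top (X^\top X)^{-1} X^\top y_v$ for a contrast vector $c$,
with $t_v = \hat\beta_v / \sqrt{\hat\sigma^2_v\, c^\top (X^\top X)^{-1} c}$
on $T - k$ degrees of freedom. No prewhitening, motion regressors or
high-pass filtering are modeled: the synthetic noise is white, so OLS is the
correct estimator for the data the generator produces. Voxels with exactly
zero residual variance (possible only on noise-free synthetic input) carry
$t = +\infty$, a documented sentinel that survives any threshold — never
`NaN`.

**Thresholding.** "Activated" voxels are those with
$t_v > t_{1-p,\,\mathrm{df}}$, one-sided, uncorrected, default $p = 0.05$.
The one-sided choice is deliberate: the measures are defined around
positive task activation, and a two-sided rule would admit strongly
*de*activated voxels into sets meant to represent activation. The B variant
of a measure applies this mask first and reports a missing value when
nothing survives — the same convention the peak-cluster measures use, so
missingness propagates identically everywhere.

**The ten measures.** Measures 1–2 are the ROI mean/median of
$\hat\beta$; 3 weights voxels by the first eigenimage (the leading spatial
singular vector of the time-centered ROI timecourse matrix, sign-fixed so
the weights sum positive, summary $\sum w_i \beta_i / \sum w_i$); 4 keeps
the top-$q$-percentile voxels by $t$ (count $\lceil q/100 \cdot m\rceil$, so
a nonempty candidate set always yields at least one voxel); 5 is the beta
at the ROI peak (max $t$); 6 grows a 26-connected set of $N$ voxels from
the peak by greedy best-first search on $t$; 7 averages the voxels within a
sphere around the peak, restricted to the ROI so outside voxels cannot
contaminate the summary; 8 keeps voxels whose timecourses Pearson-correlate
with the peak's at $r$ or above *and* are 26-connected to the peak
("correlated and clustered together"); 9 and 10 are the mean and the extent
of the suprathreshold cluster containing the peak, with no maximum cluster
size.

Determinism is enforced everywhere a selection could be ambiguous: voxels
are ranked by $t$ with ties broken by the smallest lexicographic
$(i, j, k)$ index — in peak finding, percentile cuts and greedy growth.
26-connectivity (faces, edges, corners) is used for every cluster notion.

**Group statistics.** Two groups are compared by the pooled-variance
Student t test with Cohen's
$d = (\bar x_1 - \bar x_2)/s_\mathrm{pooled}$; $k$ groups by one-way ANOVA
with $\omega^2 = (SS_b - (k-1)MS_w)/(SS_t + MS_w)$. Welch's correction is
available by flag but pooling is the default, matching the classical
analysis tools of the era the measures come from. $\omega^2$ is reported
unclamped: its null expectation is then approximately zero, and individual
negative values are informative rather than hidden (clamp at display time
if needed). The ANOVA is the omnibus test; an ordered-trend alternative was
considered and rejected as the default because the measure comparison only
needs a common yardstick across measures.

## The synthetic cohort generator

`simulation_config()` defaults describe one realistic study condition and
are not tuned per experiment:

* **Grid**: 3-mm isotropic voxels — the common-space resolution of group
  fMRI.
* **Design**: 120 volumes at TR 2 s, four 30-s control blocks alternating
  with four 30-s task blocks (`block_length = 15`). The boxcar is not
  HRF-convolved by default: with 30-s blocks the convolved regressor
  correlates with the boxcar at > 0.98, and the canonical-HRF flag exists
  for when the distinction matters.
* **Activation**: a Gaussian blob (default FWHM 12 mm) of amplitude drawn
  per subject from its group's normal distribution, centered at the nominal
  center plus per-axis Gaussian jitter (default SD 6 mm), rounded to the
  nearest voxel and clipped inside the grid — clipped, not resampled, so
  the generator never loops. The 6-mm jitter reproduces the qualitative
  observation that a 10-mm sphere at a literature coordinate misses most
  individual peaks.
* **Groups**: 50 + 50 subjects, amplitudes 1.0 vs 1.25 (SD 0.5) — a
  standardized difference of 0.5, the conventional "medium" effect.
* **Noise**: white Gaussian, baseline 100 and noise SD 1, i.e. a temporal
  SNR of 100 at blob-free voxels, typical of 3-T acquisitions. TSNR is
  defined as timecourse mean over standard deviation; the SD uses the
  $n-1$ denominator (the definition in the literature does not fix one;
  the sample SD is the estimator of choice for a finite series).
* **Covariates**: age, WRAT, task accuracy i.i.d. Gaussian per group, sex
  Bernoulli; group offsets in the covariate means control matching
  difficulty.

What the generator deliberately does **not** emulate: physiological and
structured noise, motion, spatial autocorrelation of noise, multi-session
or event-related designs, anatomical variability beyond peak jitter.
Passing tests therefore certify the *selection logic and statistics* of the
measures, not their behavior under every artifact of real data.

## Matched resampling and the localization test

`covariate_match()` finds a subset of one group whose covariates all pass
two-sample t tests at $p > 0.2$ against a reference (binary covariates are
coded 0/1 and t-tested like the rest — a blanket rule, kept for fidelity to
common practice). The search — rejection sampling over random subsets
followed by greedy single-swap refinement, 10,000 evaluations by default —
is the package's own design: simple, deterministic under a seed, and
testable against exhaustive enumeration on small pools. Failed matches in
`replicate_comparison()` are redrawn and counted; more than 50% failures
aborts with a diagnostic, since matching is then masking a structural
covariate difference.

`centroid_permutation_test()` summarizes each group by the centroid of its
subjects' peak coordinates and takes the Euclidean distance between
centroids (the maximum over pairs for three or more groups). Group labels
are randomly reassigned (sizes preserved) and the observed distance is
placed in the null distribution; the percentile counts strict
inferiorities, so ties push toward the conservative side. Sampling with
replacement is the default (matching the usual 1000-shuffle practice); an
exhaustive mode enumerates all balanced relabelings for two small groups
and anchors the sampled mode in tests.

## Numerical choices and degenerate inputs

* Zero-variance timecourses correlate 0 with everything (excluded by
  measure 8); the peak's self-correlation is 1 by definition.
* An all-zero centered timecourse matrix makes the eigenimage weights
  degenerate; equal weights are substituted.
* Identical samples give $t = 0, p = 1$; zero pooled variance with unequal
  means is an error, not a silent infinity.
* The empty activation set is a *missing value* for B-variant and cluster
  measures, an *error* for the task-activated ROI (an ROI must have at
  least one voxel).
* The task-activated ROI uses Bonferroni familywise correction over the
  anatomical voxel count: conservative, exactly testable, and free of
  random-field assumptions the synthetic data would not satisfy anyway.
  The "joint map" across groups is the union of per-group suprathreshold
  masks by default (activation present in either group); intersection is a
  flag.

## Problem sizes in the shipped experiments

The acceptance experiments (in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) use scaled-down grids and series chosen so each
Monte-Carlo answer is stable at its replicate count:

* **Null calibration** — 1000 independent null cohorts (script: 400),
  50 + 50 subjects, 8×8×8 grid, T = 24, 6-mm blob, 4-mm jitter, noise SD
  0.6, 33-voxel spherical ROI, full 16-spec battery; pooled rejection rate
  at $\alpha = .05$ should be nominal.
* **Effect recovery** — planted amplitude difference of 0.8 pooled SDs,
  200 cohorts, T = 120 (the full blocked design), no jitter, noise SD 0.5:
  under these conditions the per-voxel beta SE (≈ 0.09 a.u.) is small
  against the 0.5 a.u. between-subject amplitude SD, the stated
  precondition for the peak measure's d to recover the planted value
  (predicted attenuation to ≈ 0.79; the argmax-t selection adds a small
  positive bias).
* **Power ordering** — 500 cohorts (script: 300) with a compact 6-mm blob
  (≈ 10 strongly activated voxels) jittering with 4-mm SD inside a
  15-mm-radius ROI of 515 voxels, noise SD 0.6 at T = 24. This is the
  regime the measures were designed for: the per-voxel beta SE (≈ 0.25
  a.u.) is comparable to the ROI-mean's diluted signal, so whole-ROI
  averaging pays a noise penalty that peak-tracking measures (4, 6, 7, 8)
  avoid. With per-volume SNR this low, the r ≥ 0.7 correlation threshold
  of measure 8 is rarely attainable by non-peak voxels and the measure
  behaves like the peak measure — which still outpowers the mean here.

## Known limitations

* White noise only; structured noise would lower every measure's power and
  could reorder close competitors.
* The anatomical-ROI strategy is exercised with synthetic box/sphere masks;
  no atlas machinery is included.
* Measure 8's behavior depends strongly on per-volume SNR (see above); on
  real data, shared physiological signal inflates timecourse correlations
  and the measure selects larger sets than the white-noise simulation
  suggests.
* The percentile-count convention $\lceil q/100 \cdot m\rceil$ and the
  restriction of peak spheres to the ROI are implementation decisions on
  points the measure definitions leave open; both are documented at the
  function level and frozen by tests.
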