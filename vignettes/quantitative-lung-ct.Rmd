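---
title: "Quantitative lung CT from sparse slices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative lung CT from sparse slices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungquant)
```

## The problem

In the acute respiratory distress syndrome (ARDS) and related conditions,
lung aeration is lost preferentially in the dependent (dorsal, in supine
position) regions. Quantitative CT measures this loss voxel by voxel, but a
whole-chest spiral acquisition carries a radiation dose that is hard to
justify for repeated measurements in critically ill patients, and its
hundreds of slices must all be segmented. `lungquant` implements and
validates a cheaper design: quantify a small number of thin axial slices
separated by a fixed feed, extrapolate whole-lung quantities from them, and
acquire only those slices prospectively (a sequential scan), cutting both
dose and post-processing workload roughly in proportion to the feed.

## Voxel model

Lung tissue is modeled as a mixture of gas (−1000 HU, 0 g/ml) and
lean tissue (≈0 HU, ≈1 g/ml), so density is linear in HU:

$$\rho(\mathrm{HU}) = \frac{\mathrm{HU} + 1000}{1000} \ \mathrm{g/ml}.$$

Each voxel is assigned to one of four aeration compartments:
hyper-aerated (−1000 to −901 HU), normally aerated (−900 to −501 HU),
poorly aerated (−500 to −101 HU), non-aerated (−100 to +100 HU).
Compartment results are reported as mass percent of total lung weight
(TLW); total lung volume (TLV) is the anatomical mask volume.

Two numerical conventions make this model total and exactly
mass-conserving:

* **Clamping.** HU are clamped to [−1000, +100] before density and
  classification. Masked voxels outside the range (dense consolidation
  slightly above +100 HU, noise excursions below −1000 HU) are counted at
  the clamp rather than dropped — dropping them would silently bias TLW.
  As a consequence the four fractions always sum to exactly 100%.
* **Boundary ownership.** On integer HU each printed bound belongs to the
  interval that lists it; for continuous data the tiling splits halfway
  between printed bounds (−900.5, −500.5, −100.5). This reproduces the
  printed integer thresholds while remaining total on real-valued data.

## Sparse-slice extrapolation

For a per-slice quantity $Q_i$ (mass, volume, or one compartment's mass)
measured on $N$ slices of thickness $t$ at feed $f$:

$$Q_{lung} = \sum_{i=1}^{N-1} f\,\frac{Q_i + Q_{i+1}}{2t}
           + \frac{Q_1 + Q_N}{2}.$$

This is trapezoidal integration of the per-slice profile, in units of
slices, plus an end-cap term. Properties the test suite verifies:

* at $f = t$ the sum telescopes to $\sum_i Q_i$ exactly (relative error
  below 1e−12 on phantom stacks), so the estimator is consistent;
* the formula is linear, so extrapolated compartment masses sum to the
  extrapolated total mass and fractions still sum to 100%;
* for constant $Q_i = m$ it reduces to $(N-1)\,f\,m/t + m$.

Design choices, each deliberate:

* **Start offset 0.** Retrospective extraction keeps slices
  $0, f/t, 2f/t, \dots$ from the cranial end. This makes slice counts
  deterministic (a 240-mm coverage at 20-mm feed gives 12 slices; a
  250-slice 1-mm stack gives 13) and runs reproducible; the offset remains
  a parameter for sensitivity studies.
* **No interpolation.** The feed must be an integer multiple of the slice
  thickness; anything else raises an error rather than introducing
  unvalidated smoothing.
* **End-cap term applied as printed**, even when the first or last slice
  contains no lung. The resulting edge bias is quantified on the phantom
  cohort instead of being patched away.
* Slice geometry is half-open and 0-based internally: slice $i$ occupies
  $[i\,t, (i+1)\,t)$ mm from the cranial end.

## Agreement statistics

Bland–Altman bias is the mean of the paired differences
(test − reference); the limits of agreement are bias ± 1.96 SD with the
sample ($n-1$) standard deviation. The 1.96 multiplier (not a small-sample
t quantile) is the classic convention and is exposed as a parameter.
Spearman's ρ is the Pearson correlation of average ranks. Median (IQR)
summaries use type-7 (linear interpolation) quantiles; no convention is
universal here, so the type is a parameter. Repeated-measures variants and
LOA confidence intervals are out of scope.

## Dosimetry model

The dose comparator is intentionally idealized: CTDI scales linearly with
the current-time product; DLP = CTDI × irradiated length, where the
irradiated length is the full coverage for a spiral scan and $N \times t$
for a sequential one; effective dose is $E = k \cdot \mathrm{DLP}$. The
conversion coefficient $k$ (mSv·mGy⁻¹·cm⁻¹) is species- and
protocol-specific and therefore a required argument with no default; the
cohort configuration uses 0.02, the value implied by published pig-protocol
E/DLP ratios. Over-ranging (the extra spiral rotations beyond the planned
coverage) and tube-current modulation are not modeled, so scanner-reported
DLP will exceed this estimate; the model is meant for protocol-to-protocol
comparison, where those effects largely cancel. With typical parameters
(180 mAs spiral over 240 mm vs 50 mAs sequential, 12 × 1 mm slices) the
residual dose is $(12/240)\times(50/180) \approx 1.4\%$, i.e. a ~98.6%
reduction.

## The synthetic thorax phantom

No public HU-calibrated injured-lung volumes with ground truth exist at the
scale needed for automated validation, so the package generates its own:

* **Geometry.** Two ellipsoidal lung fields (default semi-axes
  28 × 45 × 122 mm) inside a soft-tissue torso ellipsoid. The torso's
  cranio-caudal semi-axis exceeds the field of view, as in a real chest
  acquisition where the scan range cuts the torso; this also guarantees the
  chest wall encloses the lungs everywhere in the grid. Default grid
  160 × 160 × 250 voxels at 1 mm isotropic: ≈244 mm lung extent and
  ≈1.2–1.3 l TLV, matching typical adult-pig and human chest scans.
* **Aeration gradient.** Gas fraction decays with normalized ventro-dorsal
  depth $d$ as
  $g(d) = g_{max} - (g_{max} - g_{min})\,\mathrm{logistic}((d - c)/w)$,
  with $w = 0.10$. Severity $s \in [0,1]$ moves the floor
  ($g_{min} = g_{max} - (g_{max} - 0.03)s$) and the transition center
  ($c = 1 - 0.55 s$): $s = 0$ is healthy (gas fraction ≥ 0.9 everywhere),
  $s = 1$ consolidates the dependent quartile (gas fraction ≤ 0.1).
  Noise-free lung HU are $-1000 g + 40 (1 - g)$, always in [−1000, +100].
  The defaults ($s = 0.95$) give a compartment mix of roughly
  1.4/18.8/51.5/28.4% hyper/normal/poor/non: all four compartments
  coexist with substantial dependent non-aeration. A single logistic in
  depth cannot simultaneously match every published compartment median —
  the poorly aerated band is intrinsically mass-heavy — and the phantom
  aims for this qualitative pattern, not a specific cohort's values.
* **Noise.** Additive Gaussian noise in HU with
  $\sigma = \sigma_{ref}\sqrt{\mathrm{mAs}_{ref}/\mathrm{mAs}}$
  ($\sigma_{ref} = 20$ HU at 180 mAs), the standard quantum-noise scaling.
  No streak, beam-hardening or motion artifacts: the aeration statistics
  under test are threshold-based, and Gaussian HU noise is the component
  that matters for them.
* **Determinism.** A phantom is a pure function of (spec, seed): the seed
  drives a local RNG stream that never touches the caller's.
* **Ground truth.** TLV, TLW and fractions are computed voxel-wise on the
  noise-free field by an independent code path in the generator; on
  noise-free phantoms the analysis pipeline must reproduce them to 1e−9
  relative, which is tested.

**What the phantom does not emulate** — and hence what passing tests do
not show about real data: airways and vessels, non-ellipsoidal lobar
anatomy, breathing motion, pleural effusions as distinct structures, and
scanner reconstruction kernels. The phantom validates the *geometry and
arithmetic* of sparse-slice extrapolation (which depends on the smoothness
of per-slice profiles, well emulated by ellipsoids), not biological
between-scan variability; published in-vivo limits of agreement are wider
than the phantom cohort's for that reason.

## Segmentation: a deliberate simplification

Published quantitative-CT studies segment lungs semi-automatically with
manual refinement. `segment_lungs()` replaces this with a fully automatic
surrogate: threshold at −200 HU, remove border-connected outside air, keep
the up-to-two largest components above 50 ml, then 3-D morphological
closing with a 3-voxel ball (hand-written in Rcpp; 26-connectivity
throughout). On moderately injured phantoms this reaches Dice ≥ 0.95
against the generator's exact mask. Its known failure mode is severe
dependent consolidation: tissue at −100..+100 HU touching the pleura is
indistinguishable from the chest wall by thresholding, and a 3-voxel
closing cannot bridge a multi-centimeter consolidated slab, so Dice drops
to ≈0.75 at severity 1 (while recall of the *aerated* lung stays above
0.97). The tests assert this measured behavior rather than an aspirational
accuracy. For real data, and for all validation experiments in this
package, a curated mask is the pathway of record — the cohort experiments
use the generator's exact masks so that extrapolation accuracy is measured
independently of segmentation accuracy.

## Cohort experiments and problem sizes

`run_cohort_experiment()` generates a seeded phantom cohort (default 12
subjects at the full 160 × 160 × 250 grid), draws per-subject severity
uniformly from [0.9, 1.0] (non-aerated fractions spanning roughly 3–45%,
echoing heterogeneous ICU cohorts) and jitters lung semi-axes by a few
percent (cranio-caudal extents ≈220–250 mm), analyzes every subject's full
stack as the reference, extrapolates at every feed in 2..50 mm, and
reports per-feed Bland–Altman tables. The unit tests use a coarser
64 × 64 × 80 grid over the same field of view, which preserves every
geometric property at a fraction of the cost; the acceptance script runs
the 12-subject full-grid cohort and a 32-subject sweep cohort end to end.

Expected behavior, verified by the suite: at 20-mm feed the cohort biases
are a small fraction of a percentage point with limits of agreement well
inside ±7 percentage points for every compartment fraction and within ±2%
relative for TLW/TLV; the LOA half-width for the non-aerated fraction
increases in trend with feed (Spearman ρ ≥ 0.8 across feeds 2..50), the
expected degradation of trapezoidal estimation with coarser sampling.

## Known limitations

* The phantom's smooth per-slice profiles flatter the extrapolation
  relative to real lungs with abrupt cranio-caudal aeration changes;
  in-vivo agreement limits are set by biology (ventilation history between
  scans) that no phantom reproduces.
* The segmenter is not a substitute for expert masks on patient data (see
  above).
* The dose model ignores over-ranging and modulation; absolute doses are
  underestimates, ratios are not.
* Slice-thickness bias in hyper-aeration assessment (thin slices inflate
  the hyper-aerated fraction) is not corrected; all comparisons here hold
  thickness fixed at 1 mm, where the effect cancels between reference and
  extrapolation.
* Large airways are not excluded from the lung mask; the phantom has no
  airways, so this choice is untestable here and is simply documented.
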