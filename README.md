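# lungquant

Quantitative lung CT aeration analysis with sparse-slice extrapolation.

Quantitative CT is the reference method for measuring how much of an
injured lung is aerated: every lung voxel's Hounsfield unit (HU) value maps
linearly to tissue density, and voxels are classified into four aeration
compartments. Applying it clinically is hampered by the radiation dose of a
whole-chest spiral scan and by the segmentation workload of hundreds of
slices. `lungquant` implements an alternative workflow for researchers in
intensive-care imaging: acquire (or retrospectively extract) a handful of
thin axial slices separated by a fixed feed, quantify only those, and
extrapolate whole-lung quantities with a trapezoidal formula — then verify,
on synthetic phantoms with known ground truth, how well the extrapolation
agrees with the full-stack analysis and how much dose it saves.

## The model

**Density.** Lung tissue density is linear in HU:
`rho(HU) = (HU + 1000) / 1000` g/ml, with HU clamped to [−1000, +100].

**Compartments** (mass as percent of total lung weight, TLW):
hyper-aerated −1000..−901 HU, normally aerated −900..−501 HU, poorly
aerated −500..−101 HU, non-aerated −100..+100 HU.

**Extrapolation.** For a quantity Q measured on N slices of thickness t at
feed f,

    Q_lung = sum_{i=1}^{N-1} f (Q_i + Q_{i+1}) / (2 t) + (Q_1 + Q_N) / 2.

At f = t the formula telescopes exactly to the full-stack sum. The same
formula is applied to lung mass, volume and each compartment mass;
fractions are recomputed from the extrapolated masses.

**Agreement.** Bland–Altman bias and 95% limits of agreement
(bias ± 1.96 SD of the paired differences), plus Spearman's ρ.

**Dose.** Idealized comparator: CTDI scales linearly with mAs, DLP =
CTDI × irradiated length (the full coverage for a spiral scan, N × t for a
sequential one), E = k × DLP with an explicit conversion coefficient k.

## Worked example

```r
library(lungquant)

# a synthetic injured thorax: 160 x 160 x 250 grid, 1 mm voxels,
# dependent consolidation, image noise for a 180 mAs acquisition
ph <- generate_phantom(phantom_spec(seed = 3), mAs = 180)

quantify_lung(ph$volume, ph$mask)
#> lung_quant: TLV 1287.7 ml, TLW 686.8 g
#>   fractions (% of TLW): hyper 1.24, normal 18.42, poor 51.76, non 28.58

# whole-lung values extrapolated from 13 slices interleaved by 20 mm
sl <- quantify_slices(ph$volume, ph$mask)
extrapolate(extract_subset(sl, f = 20))
#> lung_quant: TLV 1279.1 ml, TLW 682.2 g
#>   fractions (% of TLW): hyper 1.23, normal 18.44, poor 51.63, non 28.70
```

TLV is the anatomical (mask) volume; TLW the lung weight under the linear
density model; the four fractions sum to 100% of TLW. Here the 20-mm
extrapolation reproduces the full 250-slice analysis to within ~0.7% while
quantifying 13 slices instead of 250 — and a prospective sequential
acquisition of those 13 slices at 50 mAs would deliver ~1.5% of the
spiral-scan dose:

```r
spiral <- scan_protocol("spiral", mAs = 180, t = 1, ctdi_ref = 4.4, mAs_ref = 180)
seq50  <- scan_protocol("sequential", mAs = 50, t = 1, ctdi_ref = 4.4,
                        mAs_ref = 180, feed = 20)
dose_reduction(dose_report(spiral, 240, k = 0.02),
               dose_report(seq50, plan_sequential(240, 1, 20), k = 0.02))
#> [1] 0.9861111
```

A full seeded cohort experiment (phantom cohort → reference and
extrapolated analyses → per-feed Bland–Altman tables → dose comparison) is
one call: `run_cohort_experiment(cohort_config())`. A thin CLI with
subcommands (`phantom`, `segment`, `analyze`, `validate-feed`, `agree`,
`dose-compare`, `run-cohort`) is at `inst/cli/lungquant`.

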