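---
title: "GluCEST simulation, correction, and cohort analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GluCEST simulation, correction, and cohort analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`glucestr` implements a glutamate-weighted chemical exchange saturation
transfer (GluCEST) analysis chain for single-slice 7T brain imaging, and a
synthetic-data generator that lets every stage be exercised against known
ground truth. The chain is:

1. **Forward model** — a two-pool (water + glutamate amine)
   Bloch-McConnell simulator producing z-spectra under continuous-wave
   saturation.
2. **Phantoms and cohorts** — synthetic single-slice acquisitions (CEST
   stack, WASSR stack, three flip-angle B1 images, tissue labels) and
   19-subject smoker/non-smoker cohorts.
3. **Field mapping** — per-voxel B0 from the WASSR stack and relative B1
   (kappa) from the flip-angle images.
4. **Contrast** — B0-corrected asymmetry at ±3.0 ppm,
   `100 * (Z(-3) - Z(+3)) / Z(-3)`, rescaled per voxel by a
   simulation-derived B1 calibration.
5. **ROI summaries and cohort statistics** — regional means over gray
   matter, white matter, and seven cortical regions; Wilcoxon rank-sum
   group comparisons; age regressions with R²; volume-contrast
   correlations.

# The spin model

The simulator propagates the 6-state Bloch-McConnell system — transverse
and longitudinal magnetization of a water pool `a` and a dilute solute
pool `b` in the frame rotating at the saturation frequency — under
constant RF amplitude. Because the generator is constant during a CW
block, the solution is computed with the matrix exponential of the 6×6
generator (`expmat`, Padé scaling-and-squaring), which is exact to
floating-point accuracy and stiff-safe at any exchange rate. An
independent dense ODE integration (`deSolve::radau` with analytic
Jacobian, `rtol = 1e-11`) serves as the oracle in the test suite; the two
agree to better than 1e-6 at all 18 CEST offsets.

Default pool parameters are literature-informed 7T gray-matter values, all
overridable:

| parameter | default | unit | rationale |
|---|---|---|---|
| water T1 / T2 | 1.8 / 0.04 | s | 7T gray-matter-like |
| solute T1 / T2 | 1.0 / 0.008 | s | small-metabolite values |
| exchange rate | 5500 | 1/s | glutamate amine at physiological pH |
| solute shift | +3.0 | ppm | amine resonance downfield of water |
| solute fraction | 3·[Glu]/111000 | — | 3 amine protons vs 111 M water protons |

1 ppm is `gyromagnetic_ratio * field_strength * 1e-6` Hz (≈297.6 Hz at
the default 6.99 T, γ = 42.577 MHz/T). Positive ppm is downfield of
water; offsets are stored ascending.

The CEST protocol (3.06 µT RMS, 800 ms, 99% duty cycle, offsets ±1.8 to
±4.2 ppm in 0.3 ppm steps) is modeled as one CW block: with 1% pulse-train
gaps the CW approximation is accurate to well below the other error terms.
With 10 mM glutamate these defaults give a GluCEST contrast of about 1.5%.
In vivo asymmetry at 3 ppm is several times larger because creatine,
protein amides, and other exchanging species contribute to the same
offset; those pools are deliberately outside this model (see
*Limitations*), so absolute phantom contrast is lower than in-vivo
values while the structure of the analysis is preserved.

## WASSR saturation is a spoiled sub-pulse train

The WASSR scheme (0.29 µT RMS, 200 ms) is near resonance, where a single
hard CW block would end with a coherent nutation: the on-resonance flip is
about 15.5 rad, which imprints ripples of ~0.05 amplitude on the sampled
dip and (we measured) biases the per-voxel minimum by up to ~0.03 ppm.
Real saturation modules apply trains of short pulses with spoiling in
between, and measured WASSR dips are smooth. We therefore model WASSR
saturation as a train of forty 5 ms CW sub-pulses with ideal transverse
spoiling between sub-pulses; this removes the ripples (residual
dip-position error ~0.001 ppm) while keeping the same matrix-exponential
machinery (one `expmat` per offset, reused across sub-pulses).

# The synthetic data generator

`make_phantom()` builds an elliptical brain with a white-matter core, a
gray-matter band, and seven disjoint gray-matter patches standing in for
the cortical regions (cingulate gyrus, juxtapositional lobule cortex,
paracingulate gyrus, frontal pole, middle frontal gyrus, precentral gyrus,
postcentral gyrus). Defaults:

* grid 96 × 64 (the acquisition-matched 240 × 168 is a flag away;
  tests and replicate studies use 48 × 32 for speed — grid size only
  changes voxel counts, not the physics);
* glutamate 10 mM in gray matter, 6 mM in white matter, patch values
  8.8–10.8 mM;
* a smooth random B0 field scaled to ±0.3 ppm and a smooth relative-B1
  field in [0.8, 1.2] (seeded low-order polynomial surfaces);
* additive Gaussian noise of SD 0.005 relative to the unit equilibrium
  signal on every frame (Rician available by flag; at this SNR the
  Gaussian approximation is adequate);
* saturation frames are magnitude images (|Mz|); the three flip-angle
  images follow the signed calibration model `S = S0 cos(κα)` for α ∈
  {20°, 40°, 80°}.

`make_cohort()` draws the study design: two groups of ten recruited one
female and one male per age decade (20–69), with one randomly chosen
smoker marked unusable, leaving 10 + 9 analyzable subjects. Per-subject
regional glutamate is
`base + group_effect + age_slope · (age − 45) + N(0, subject_sd)` with a
0.5 mM between-subject SD by default and no injected group or age effects
— the default cohort is a true null. The same seed and configuration
reproduce a cohort byte-for-byte.

## The dictionary forward model

Replicate studies push hundreds of cohorts through the full pipeline.
There the per-voxel matrix-exponential simulation is replaced by trilinear
interpolation in a precomputed dictionary `Z(glutamate, κ, offset)`
(`default_dictionaries()`: 1–16 mM × κ 0.65–1.35 × 0.05/0.02 ppm offset
grids) — the standard lookup-table approach for CEST forward models. B0
enters through `Z(offset; b0) = Z(offset − b0; 0)`. Dictionary and exact
engines agree to ~1e-3 in Z (tested); the exact engine remains the
default for single phantoms.

# Field mapping

**B0.** Each voxel's WASSR spectrum is interpolated with a natural cubic
spline. The default estimator is the maximum-symmetry center frequency
(MSCF): the center `c` minimizing `sum_d (Z(c+d) − Z(c−d))²` over
mirrored evaluations of the interpolant (0.005 ppm evaluation grid,
coarse-to-fine candidate search, parabolic refinement). A plain
spline-minimum estimator is also provided (`method = "spline_min"`).
MSCF is the default for a measured reason: at 0.29 µT × 200 ms direct
water saturation is nearly complete at the dip bottom, so the minimum
position is ill-conditioned under noise (spline-argmin RMSE ≈ 0.024 ppm
at noise SD 0.005), while the symmetry matching uses the full dip walls
(RMSE ≈ 0.001 ppm, and ≤ 0.0005 ppm noiseless). The estimate is invariant
to global intensity rescaling, and all-zero or non-finite spectra are
marked invalid rather than raising. A sub-0.001 ppm bias remains in
noiseless phantoms because the amine wing makes the dip very slightly
asymmetric.

**Relative B1.** Per voxel, `κ` minimizes `Σ_i (S_i − S0 cos(κ α_i))²`
with `S0` profiled out in closed form, searched over [0.3, 2] at 1e-3
resolution. `cos(κα)` is non-injective at large `κα`, so near-ties are
broken toward the κ closest to 1.

**Brain mask.** Voxels whose mean WASSR signal falls below 5% of the
stack's 99th-percentile intensity are background.

# Contrast and corrections

**B0 correction** interpolates each sign branch of the CEST stack
separately with natural cubic splines and evaluates at `(±3.0 + b0)` —
the voxel's displaced water frame. No extrapolation is ever performed:
evaluation points outside the sampled branch magnitude range [1.8, 4.2]
ppm (i.e. |b0| > 1.2 ppm) invalidate the voxel. When b0 = 0 the sample
points are knots and the acquired ±3 ppm frames are returned exactly.

**Asymmetry** is normalized by the negative-offset image (the GluCEST
convention); `z_neg ≤ 0` invalidates a voxel. The percent value is
invariant to global rescaling of the stack.

**B1 correction** uses a simulation-derived lookup: the calibration curve
`C(κ)` is the simulated contrast over κ ∈ [0.5, 1.5] (step 0.01) at the
default 10 mM pool, and each voxel is rescaled by `C(1)/C(κ)`. Because
contrast is nearly proportional to the solute fraction, the ratio is
essentially concentration-independent, so one curve serves all tissues.
κ outside the calibration span invalidates the voxel. Scanner-side B1
correction methods vary between sites and are rarely documented in enough
detail to reconstruct; a lookup ratio derived from the same forward model
is self-consistent and parameter-free at run time. On a noiseless
uniform-glutamate phantom with a κ gradient of 0.8→1.2 the corrected map's
coefficient of variation is ~0.05% versus ~16% uncorrected; a solute-free
phantom stays below 0.003% absolute after all corrections.

# ROI summaries and statistics

Regional means and SDs are computed over valid voxels only; gray matter
includes the seven cortical patches. Empty regions are flagged missing
(never reported as zero) and regions with fewer than 10 valid voxels are
flagged low-confidence. Normalized gray/white-matter volumes are voxel
count fractions of total brain — appropriate for single-slice data with
uniform voxel size.

Group comparisons use the two-sided Wilcoxon rank-sum test with R's
default behavior (exact enumeration when both groups have n < 50 and the
pooled sample has no ties; normal approximation with tie and continuity
corrections otherwise), which makes per-subject tables reproducible in a
standard R environment. A fully tied pooled sample returns p = 1 by
convention. Age regressions are ordinary least squares of contrast on age
with `R² = 1 − SSE/SST` and the slope's two-sided t-test; a zero-variance
response is reported as degenerate (R² = 0, p = 1). Contrast is the
response and age the predictor (R² is direction-free; the slope is per
year). No multiple-testing correction is applied: p-values are reported
per region, mirroring common practice for exploratory regional tables.

The "subcortical" comparisons of the study design map to the gray/white
matter rows here; the seven cortical regions are tabulated individually.

## Null calibration of the discrete exact test

With group sizes (10, 9) the exact two-sided p-value is a discrete
statistic whose null CDF has steps up to ~0.065, so even a perfectly
calibrated implementation fails a naive Kolmogorov-Smirnov comparison of
pooled p-values to U(0,1). The calibration check therefore uses the
randomized probability integral transform against the exact discrete null
(`wilcoxon_exact_p_null()` / `wilcoxon_p_pit()`): under the null the PIT
values are exactly uniform, and the KS test applies cleanly. The test
suite pools PIT values across the nine per-region tests of 200 null
replicate cohorts.

## Replicate-study conditions

The parameter-recovery study injects a −0.1 mM/year cingulate-gyrus
glutamate slope in smokers (≈ −0.015 percent-contrast/year under the
default protocol), against 0.5 mM between-subject SD and 0.005 frame
noise — a moderate, detectable decline for a 9-subject group spanning
five decades. Two hundred replicate cohorts are run end-to-end
(dictionary engine, 48 × 32 grid); the recovered cingulate-gyrus smoker
slope is negative in well over 95% of replicates.

# Numerical choices

* Matrix-exponential propagation for all CW blocks; spoiled 5 ms
  sub-pulse trains for WASSR (see above).
* Natural cubic splines everywhere an interpolant is needed; never
  extrapolated. Spline evaluation is linear in the samples, so per-voxel
  interpolation is implemented as products with precomputed cardinal
  bases.
* κ grid search at 1e-3 with ties toward 1; MSCF candidate search at
  0.02 ppm refined to 0.005 ppm with parabolic interpolation.
* Voxel validity is propagated through every stage; invalid voxels carry
  `NA` and are excluded from all statistics.
* Every random quantity (fields, noise, ages, subject seeds) derives from
  a single integer seed; identical seed + configuration reproduces every
  output byte-for-byte.

# Limitations

* Two pools only: no magnetization transfer, NOE, amide, or other amine
  contributions, so absolute contrast is below in-vivo asymmetry values;
  conclusions about pipeline behavior transfer, absolute percentages do
  not.
* Phantom anatomy is schematic (ellipses and discs); no motion, coil
  sensitivity profiles, or partial-volume mixing beyond hard labels, and
  all subjects share the same geometry — volume-contrast correlations on
  purely synthetic cohorts are therefore degenerate unless geometry
  variation is introduced.
* The B1 correction assumes the monotone calibration regime κ ∈
  [0.5, 1.5]; stronger B1 errors invalidate voxels rather than being
  corrected.
* Passing synthetic tests shows the estimators and statistics are
  implemented correctly under the stated acquisition model; it does not
  validate the model against scanner data.
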