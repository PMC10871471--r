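# glucestr

Glutamate-weighted CEST (GluCEST) MRI analysis for single-slice 7T brain
imaging, with a fully synthetic test bench.

GluCEST imaging saturates the glutamate amine protons resonating ~3 ppm
downfield of water and reads out the saturation transferred to water. The
contrast is the asymmetry of the z-spectrum around the water line,

```
GluCEST% = 100 * (Z(-3 ppm) - Z(+3 ppm)) / Z(-3 ppm)
```

which is only meaningful after two per-voxel corrections: the static field
(B0) shifts each voxel's water line, so the ±3 ppm points must be read off
a spline interpolant of the offset stack at the displaced positions; and
the transmit field (B1) scales the effective saturation power, so the raw
asymmetry must be rescaled by a calibration factor `C(1)/C(κ)` where κ is
the voxel's relative B1.

The package is aimed at researchers building or validating CEST pipelines.
It provides:

* a two-pool (water + glutamate amine) **Bloch-McConnell simulator**
  (matrix-exponential propagation; spoiled sub-pulse trains for
  near-resonance saturation),
* a **phantom and cohort generator** with known ground truth — CEST stack
  (±1.8…±4.2 ppm, 0.3 ppm steps), WASSR stack (0…±1.5 ppm, 0.15 ppm
  steps), three flip-angle B1 images, tissue labels, and a 10 non-smoker +
  9 usable-smoker cohort with one female and one male per age decade,
* **field mapping**: WASSR B0 (maximum-symmetry center frequency on a
  natural-spline interpolant) and three-flip-angle relative B1
  (`S = S0 cos(κα)` with S0 profiled out),
* **B0/B1-corrected GluCEST maps** with strict validity propagation,
* **ROI summaries** over gray/white matter and seven cortical regions,
  plus normalized tissue volumes,
* **cohort statistics**: exact two-sided Wilcoxon rank-sum group
  comparisons per region, OLS age regressions with R², and
  volume-contrast correlations, assembled into a regions × groups results
  table.

## Worked example

Simulate a noisy phantom, estimate its field maps, and build the corrected
contrast map:

```r
library(glucestr)

ph  <- make_phantom(phantom_config(noise_sd = 0.005), seed = 20240216)
fm  <- fit_field_maps(ph)
map <- glucest_pipeline_map(ph, fm, b1_calibration_curve())

bm <- ph$truth$brain_mask & fm$valid
sqrt(mean((fm$b0[bm]    - ph$truth$b0_map[bm])^2))    # 0.0011  (ppm)
sqrt(mean((fm$kappa[bm] - ph$truth$kappa_map[bm])^2)) # 0.0037
head(regional_means(map, ph$truth$label_map), 3)
#>       region mean_percent sd_percent n_voxels missing low_confidence
#> 1 WholeBrain        1.327      0.949     3648   FALSE          FALSE
#> 2         GM        1.497      0.931     2540   FALSE          FALSE
#> 3         WM        0.938      0.875     1108   FALSE          FALSE
```

The true B0 field (±0.3 ppm) comes back with ~0.001 ppm RMSE and the true
relative-B1 field (0.8–1.2) with ~0.004 RMSE; gray matter (10 mM
glutamate) shows ~1.5% contrast and white matter (6 mM) ~0.9% under the
two-pool model (in-vivo asymmetry is higher because other exchanging pools
contribute — see the methods vignette).

An end-to-end synthetic study, from cohort generation to the
Table-1-style results bundle:

```r
run <- run_pipeline(cohort_config(), seed = 20240216,
                    output_dir = "results/cohort")
run$results$table1          # 10 regions x 2 groups: mean, SD, Wilcoxon p
run$results$age_regressions # per region x group: slope, R^2, p
```

The numbered scripts under `analysis/` run these workflows and write
their tables under `results/`: `01_phantom_maps.R` (single-phantom maps
and recovery), `02_cohort_statistics.R` (default cohort and statistics),
`03_replicate_calibration.R` (replicate-cohort slope recovery and null
calibration).

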