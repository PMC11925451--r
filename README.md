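# laminarfmri

Laminar (cortical depth-dependent) and columnar analysis of block-design BOLD
fMRI, with a synthetic-data generator that plants the structures the analysis
is meant to recover.

The package is aimed at high-field (7T) visual-neuroscience studies of the
kind that ask how color, binocular disparity and naturalistic-texture
information are organized in the second visual area (V2): interdigitated
thin/pale/thick stripe columns running perpendicular to the V1–V2 border,
depth-specific response selectivity between the white-matter and pial
surfaces, and layer-specific informational connectivity that separates
feedforward (superficial → middle) from feedback (deep ↔ deep) signal flow
between areas of the visual hierarchy.

## What it computes

For a condition pair (A, B) with GLM response amplitudes β, selectivity is

    SI = (β_A − β_B) / (β_A + β_B)

computed from ROI-averaged betas per stripe compartment, per equi-volume
depth bin (deep 0–0.33, middle 0.33–0.67, superficial 0.67–1; the depth of a
voxel at geometric position ρ in a column with inner/outer surface areas
A_in, A_out is the volume fraction α solving
ρ = (−A_in + √(α·A_out² + (1−α)·A_in²)) / (A_out − A_in)),
and per eccentricity bin (0–3°, 3–6°, 6–18°). Supporting machinery:

- **Synthetic generator** — abstract cortical sheet (u, v) × depth with
  per-voxel area labels, stripe maps, eccentricity, curvature-driven
  equi-volume depths; block designs convolved with a plateau-normalized
  gamma block response; planted laminar gains, pial-vein bias, voxel-scale
  tuning scatter, spatially smoothed noise, and block-level response
  variability shared between chosen region–layer pairs.
- **GLM** — per-condition betas and per-block t-score patterns (one
  regressor per block), Legendre drift nuisance, OLS.
- **Stripe segmentation** — threshold + connected components on the
  z-scored color-minus-disparity differential map; pale = between thin and
  thick; Dice overlap against the planted map.
- **Test–retest reliability** — inter-session pattern correlation with a
  Monte-Carlo family-wise-error null of smooth maps matching the spatial
  autocorrelation (Gaussian+exponential mixture) fitted to GLM residuals.
- **Informational connectivity** — two-stage feature selection (top 20%
  visually responsive, then 200 voxels per tail of the differential t
  distribution), L2-normalized block patterns, leave-one-run-out linear
  max-margin decoding, correlation of block-by-block decision distances per
  pathway, Fisher z, one-sample t, Benjamini–Hochberg FDR.
- **Group statistics** — repeated-measures ANOVA, paired t,
  subject-resampling bootstrap for stripe differences.

## Worked example

```r
library(laminarfmri)
library(dplyr)

cfg <- default_config(n_subjects = 1, n_runs = 10)
sim <- simulate_subject(cfg, subject = 1)
fits <- lapply(sim$datasets, fit_dataset_glm)
vein <- vein_mask_from_fits(fits, sim$patch)

laminar_profile(fits$texture, sim$patch, "V2", vein_mask = vein)
#> # A tibble: 3 x 7
#>   area  bin         beta_a beta_b n_vox      si contrast...
#> 1 V2    deep          2.06   1.70  2090 0.0962
#> 2 V2    middle        2.29   2.10  2090 0.0420
#> 3 V2    superficial   3.09   3.06  2090 0.00380
```

Texture selectivity is strongest in the deep bin — the planted feedback-like
laminar profile — while the raw betas still rise toward the surface (the
vein-driven superficial gain that the SI ratio cancels). Segmenting stripes
and scoring them against the planted map:

```r
dmap <- differential_map(fits$color, fits$disparity, sim$patch)
est  <- segment_stripes(dmap, sim$patch, z = 0.8)
stripe_dice(est, sim$stripes)
#> # A tibble: 3 x 2
#>   compartment  dice
#> 1 thin        0.953
#> 2 thick       0.970
#> 3 pale        0.960
```

A full multi-subject study with group statistics, reliability and the
connectivity pathway matrix:

```r
study <- run_study(default_config(n_subjects = 10))
study$group_connectivity %>% arrange(q) %>%
  select(contrast, lower, upper, direction, mean_r, t) %>% head(2)
#> contrast  lower upper direction    mean_r     t
#> texture   V2    V4    feedback     0.398   9.61
#> color     V2    V3ab  feedforward  0.061   1.64
```

Only the planted V4→V2 deep-layer texture coupling survives FDR; all other
pathway × contrast cells stay at their null. `plot_laminar_profiles()`,
`plot_compartment_profiles()` and `plot_connectivity_matrix()` draw the
standard figures; `run_pipeline(cfg, out_dir)` writes every table as CSV with
a provenance log.

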