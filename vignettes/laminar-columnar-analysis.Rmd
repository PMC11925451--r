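---
title: "Laminar and columnar analysis of synthetic BOLD data: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar and columnar analysis of synthetic BOLD data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(laminarfmri)
```

This vignette is the package's account of its science: the generative model
behind the synthetic data, the analysis models layered on top of it, the
parameters that matter and why their defaults are what they are, and the
places where the design was genuinely open.

## The scientific setting

High-field fMRI at millimetre resolution can resolve two mesoscale
organizations of early visual cortex: *columnar* structure in the cortical
sheet (in V2, interdigitated thin/pale/thick stripes preferring color,
orientation and disparity, running perpendicular to the V1–V2 border) and
*laminar* structure across cortical depth (middle layers receive feedforward
input, superficial layers send feedforward output, deep layers receive
feedback). Combining the two lets a study ask not just *where* a stimulus
property is represented but *which direction of signal flow* carries it: a
selectivity profile peaking in the deep bin, together with deep–deep
informational connectivity from a higher area, is the signature of feedback.

The package implements that full analysis chain, driven by a generator that
plants each structure explicitly so every stage can be validated by
parameter recovery.

## The generative model

A subject is an abstract cortical sheet: four areas (V1, V2, V3ab, V4), each
a `nu` × `nv` grid of 1 mm columns with `n_depth = 3` voxels per column. The
sheet is not a FreeSurfer mesh; cortical folding enters only through
per-column inner/outer surface areas `A_inner = exp(−c)`, `A_outer = exp(c)`
with a sinusoidal curvature profile `c(v)`, which is exactly what the
equi-volume depth computation consumes. Voxels sit at equally spaced
geometric depths ρ = 1/6, 3/6, 5/6 of the thickness, and each voxel's
stored depth is the *volume fraction* α enclosed below it, the closed-form
inverse of the equi-volume mapping. On a flat cortex α = ρ; on curved
columns the three samples shift so that equal-volume bins, not equal
thickness bins, receive them.

The response of voxel *v* to block *b* of condition *c* is

    amplitude(v, c) · gain(v) · m(region(v), b)

convolved with the canonical block response, plus spatially smoothed
Gaussian noise that is independent over time.

**Amplitudes.** `amplitude(v, c) = base · (1 ± sel_eff(v)/2)` so that a
voxel's planted selectivity index is `sel_eff/2`. `sel_eff` combines:

- compartment selectivity in V2 (color: thin 0.40, pale 0.10, thick 0;
  disparity mirrored), uniform area-level selectivity elsewhere;
- for texture, area-level selectivity (V1 0.08, V2 0.15, V3ab 0.30,
  V4 0.35) with *no* columnar structure, rising linearly with eccentricity
  (floor 0.4 at 0°) — the organization the compartment null and the
  eccentricity profile recover;
- a contrast-specific laminar profile: color (0.8, 0.8, 1.4) across
  (deep, middle, superficial), disparity flat, texture (1.8, 1.0, 0.7) in
  V1/V2 only — superficial color, flat disparity, deep texture;
- per-voxel tuning scatter, `N(0, 0.15)`, drawn once per subject and
  contrast. This is the voxel-scale heterogeneity of real maps, and it is
  load-bearing: multivoxel patterns are L2-normalized before decoding, so a
  spatially uniform condition difference is pure common mode and vanishes
  under normalization. Without tuning scatter there is nothing for a
  classifier to decode;
- a per-subject, per-area multiplicative factor `N(1, 0.1)` providing
  between-subject variability.

**Gains.** A depth-bin gain (0.8, 1.0, 1.3) and a global pial-vein factor
`1 + 0.3·depth²` model the superficial drift of gradient-echo BOLD; 5% of
columns carry a draining vein with an extra `1 + 2·depth` gain. Gains
multiply both conditions equally, so selectivity indices are unaffected in
expectation — but vein columns dominate ROI averages, which is what the
top-5% vein exclusion corrects.

**Block-level variability and couplings.** Every (area × depth-bin) region
receives a block multiplier `m = 1 + σ_j (w·s_b + sqrt(1 − w²)·e)`, with
`σ_j = 0.2`, `e` independent per region and block, and `s_b` a
standard-normal latent shared by the two region–layers of a coupling entry.
The default truth couples (V2 deep, V4 deep) for the texture contrast with
`w = 0.8`. Note the parametrization: `w` sets the *correlation* between the
two regions' block amplitudes while the amplitude variance stays `σ_j`
regardless of `w`. The alternative — adding `w·s_b` on top of the jitter —
would give coupled regions ±80% response swings, physiologically
implausible, and would contaminate their laminar selectivity estimates with
condition-imbalance noise an order of magnitude larger than everywhere
else.

**Noise.** White Gaussian noise smoothed on each (u, v) depth slice with a
Gaussian kernel (FWHM 2 mm, conversion FWHM = σ·√(8 ln 2)), rescaled to a
marginal sd of 1.5% signal change per TR, i.i.d. across timepoints and
depth slices. Smoothing a white field with a kernel of scale σ yields a
Gaussian ACF of scale σ√2 — the value the residual-ACF round-trip test
expects.

**Design.** 24 s blocks in alternation, five per condition per run, ten
runs per experiment, TR 2.4 s. A 16 s lead/trail fixation does not tile the
TR grid (272 s = 113.33 TR), so the generator uses 16.8 s, the nearest
TR-compatible value (273.6 s = 114 TR); run length mismatches beyond a
quarter TR are configuration errors.

What the generator does *not* emulate: hemodynamic nonlinearity, motion,
physiological noise, spatial displacement by draining veins (the vein bias
is gain-only), and the geometric distortions of a real surface
reconstruction. Tests passing on this generator therefore validate the
*statistical logic* of the pipeline — estimator correctness, calibration of
nulls, recovery under realistic SNR — not robustness to real-data artifacts.

## Analysis choices worth recording

**Block response.** The canonical block regressor is a boxcar convolved
with the single-gamma impulse `h(t) = (t/p)^q exp(q − q t/p)`, p = 5 s,
q = 4, evaluated in closed form through the incomplete gamma function and
normalized so a sustained block plateaus at 1 — betas are therefore in
percent-signal-change units. Per-block models fit all blocks of a run in a
single model (one regressor per block), and drift is a per-run Legendre
basis of order 2.

**Depth bins.** The printed bin boundaries overlap at 0.33/0.67; half-open
intervals [0, 0.33), [0.33, 0.67), [0.67, 1] resolve them
deterministically. Vein exclusion ranks whole columns (the sheet's notion
of a vertex) by the all-conditions-vs-baseline beta averaged over depth,
and removes the top 5% per area, propagating across all depths.

**Stripe segmentation.** Manual stripe delineation is replaced by a
deterministic procedure: the column-level color-minus-disparity
differential map (restricted to columns with positive mean activation) is
lightly smoothed (1.5 mm FWHM normalized convolution — enough to suppress
voxel-scale tuning scatter without eroding 3 mm bands), z-scored, and
thresholded at ±z; connected components above +z are thin candidates, below
−z thick; unlabeled columns flanked along u by one thin and one thick band
become pale, and at the map edges pale is extended outward by the median
interior pale width (the two-sided rule cannot apply beyond the outermost
band). The default z = 0.8 balances band coverage against false blobs at
the generator's scatter level; the compartment-selectivity ordering is
verified to be stable over z ∈ {0.5, 1, 1.5, 2}. Aggregation order is fixed
as SI-of-mean-betas (not mean of voxel SIs), matching ROI-averaged response
computation, and the two differ — a hand case in the tests demonstrates it.

**Stripe geometry.** The default stripe cycle is 12 mm (thin, pale, thick,
pale at 3 mm each), within the range reported for human V2, and each
subject's stripe system sits at a random phase. Phase randomization is not
cosmetic: with a fixed phase, band positions align with the sheet's
eccentricity map and grid edges identically in every subject, and
millimetre-scale sampling asymmetries between thin and thick bands become a
consistent group-level confound on the texture compartment null.

**Reliability.** The second session is the same subject (same stripes,
tuning scatter, veins, selectivity factors) with independent noise and
block variability. The spatial ACF of session-1 GLM residuals is estimated
by FFT-based 2D autocorrelation collapsed radially and fitted with
`a·exp(−r²/2b²) + (1−a)·exp(−r/c)` by Levenberg–Marquardt on the raw
residual function (the mixture routinely converges to the a = 1 boundary on
Gaussian fields, where nls-object construction fails). Null second-session
maps are sampled by spectral filtering of white noise on a padded torus
grid whose target covariance is the fitted ACF; the held-fixed reference
map is the session-1 map, following the asymmetric test–retest procedure.
The FWE p uses the add-one rule, one-sided (positive reliability is the
hypothesis). Type-I calibration groups repeats into pools sharing a null
sample: conditional on the pool, the p of an independent pair is exactly
uniform, so pooling buys an order-of-magnitude speedup without biasing the
rate. In the original volumetric workflow simulated volumes pass through a
surface projection before correlating; on the sheet model that projection
is the identity — a fidelity gap to keep in mind.

**Informational connectivity.** Feature selection (top 20% by
activation-vs-baseline t, then 200 voxels per tail of the differential t;
for stage 1 the two conditions are summed, as both contain stimulation) is
recomputed inside every cross-validation fold from training runs only; the
tests assert both that including the held-out run changes the selection and
that the proper pipeline keeps shuffled-label accuracy at chance while a
leaky variant inflates it. Patterns are L2-normalized, the classifier is a
linear soft-margin SVM with C = 1 (no class weighting), and distances are
geometric, `(w·x + b)/‖w‖`, so folds are comparable.

The pathway correlation is computed per fold over held-out blocks and
averaged across folds (plain mean; Fisher z enters only at group
inference). One subtlety dominates the null behaviour: both regions see the
same stimulus sequence *and* inherit the same deterministic block-position
profile — run-edge blocks have less temporally collinear regressors, hence
higher-SNR patterns and larger margins — so raw signed distances correlate
between *any* two regions. Each series is therefore residualized on its
mean evidence per (block position × condition) cell across runs before
correlating, which removes the design-locked component and isolates genuine
block-level covariation of stimulus information. The raw behaviour remains
available as `evidence = "signed"`, and a concatenate-across-folds mode as
`corr_mode = "concatenated"`.

Pathways follow the canonical microcircuit: feedforward = (lower area,
superficial) × (higher area, middle); feedback = (deep, deep); adjacent
pairs V1–V2, V2–V3ab, V2–V4. Group inference is a one-sample t on Fisher-z
values per pathway × contrast with Benjamini–Hochberg correction across the
whole tested family (18 cells here: 3 pairs × 2 directions × 3 contrasts).
Per-fold correlations use only the held-out run's blocks — the literal
reading of fold-wise distance extraction.

**Group statistics.** The one-way repeated-measures ANOVA is the classical
within-subject decomposition (`F = MS_cond / MS_cond×subj`), validated
against `aov()`'s Error-stratum table, with an explicit degenerate flag for
zero interaction variance rather than an infinite F surprise. The stripe
bootstrap resamples *subjects* with replacement (the resampling unit is not
stated unambiguously in the field's descriptions; subject-level treats the
subject as the unit of inference), 10,000 iterations by default, two-sided
add-one p against zero. Like any percentile bootstrap of a mean it is
anticonservative at very small cohorts (the resampling variance shrinks by
(n−1)/n); its type-I rate is verified at moderate n, and rejections at
n = 10 should be read with that bias in mind. Where a family of ANOVAs needs
FWE control, Bonferroni across the family with post hoc tests corrected
only when the ANOVA survives is the intended gatekeeping rule.

## Problem sizes and defaults

The default study is 10 subjects × 3 experiments × 10 runs on 2,200
columns (50 × 44) per area with 3 depth samples — the smallest geometry
that sustains the canonical 400-voxel feature selection per region-layer
after the top-20% filter and 5% vein exclusion. Noise and effect-size
defaults are set so that recovery holds at these sizes with realistic
margins (single-voxel block-level t around 4, ROI selectivity indices of a
few hundredths to ~0.2), chosen once and documented here; they are the
study conditions, not tuning knobs. The calibration analyses (reliability
type-I rate, connectivity false-positive rate over cohorts, coupling
monotonicity) run on reduced geometries (e.g. 24 × 10 columns, 20-voxel
tails, 4–6 runs) because they repeat the pipeline tens to hundreds of
times; the statistical contracts they check are size-free.

## Known limitations

- Depth sampling is sparse (one voxel per bin by default); partial-volume
  mixing between bins, a dominant effect at 1 mm resolution, is not
  modelled.
- The sheet is flat and periodic-free; no geodesic distances, no surface
  projection step in the reliability null.
- Noise is temporally white; slow drifts exist only through the drift
  regressors in the fitting model, not the generator (the GLM's drift
  columns are therefore exercised as nuisance capacity, not necessity).
- The informational-connectivity null calibration assumes the block
  multiplier model; exotic shared structure (e.g. global arousal affecting
  all regions coherently) would require the same position/condition
  residualization logic extended to a global regressor.
- `w` couples exactly two region-layers per entry; overlapping couplings on
  the same region are not composed.
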