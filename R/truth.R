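# Ground-truth generative parameters: every effect the analysis stages are
# meant to recover is planted here, in percent-signal-change units.

#' Stimulus contrasts and their condition pairs
#'
#' The three experiments: chromatic vs achromatic gratings (color),
#' disparity-defined vs flat random-dot stereograms (disparity), and
#' naturalistic texture vs spectrally matched noise (texture).
#' @return named list of length-2 condition label vectors.
#' @export
contrast_conditions <- function() {
  list(color = c("Chr", "Ach"),
       disparity = c("3D", "2D"),
       texture = c("T", "N"))
}

#' Ground-truth parameters for the synthetic BOLD generator
#'
#' Encodes the response structure the analysis recovers: stripe-compartment
#' selectivity for color and disparity, area- and eccentricity-dependent
#' texture selectivity with no columnar structure, contrast-specific laminar
#' selectivity profiles (superficial for color, flat for disparity, deep for
#' texture), a common superficial response gain with pial-vein bias, block
#' level response-amplitude variability shared between coupled region-layer
#' pairs, and spatially autocorrelated noise.
#'
#' @param base_amplitude mean response amplitude per contrast (percent signal
#'   change).
#' @param stripe_selectivity per contrast, named selectivity of the V2 stripe
#'   compartments (a voxel's condition-A-vs-B modulation is
#'   `base * (1 +/- sel * depth_profile / 2)`).
#' @param area_selectivity per contrast, uniform (non-columnar) selectivity of
#'   areas outside the stripe system; for texture this is the per-area base
#'   selectivity everywhere.
#' @param texture_ecc_floor fraction of the texture selectivity present at 0
#'   degrees eccentricity; selectivity grows linearly to its full value at the
#'   eccentricity maximum.
#' @param depth_profile per contrast, multiplicative selectivity factor per
#'   depth bin (deep, middle, superficial).
#' @param texture_depth_areas areas in which the texture depth profile
#'   applies (elsewhere flat, mirroring a feedback effect confined to the
#'   early areas).
#' @param laminar_gain common response gain per depth bin (applies to all
#'   conditions equally, so selectivity indices are unaffected).
#' @param vein_bias slope of the global pial-vein gain `1 + vein_bias * depth^2`.
#' @param vein_columns list(`frac`, `gain`): fraction of columns that carry a
#'   draining vein and their extra gain `1 + gain * depth`.
#' @param shared_variability tibble of couplings (`area_a`, `bin_a`, `area_b`,
#'   `bin_b`, `contrast`, `w`): a block-level standard-normal latent shared by
#'   the two region-layers, entering their block amplitude with weight `w`
#'   relative to the independent jitter (so `w` in [0, 1] sets how correlated
#'   the two regions' block-level response fluctuations are).
#' @param amp_jitter_sd standard deviation of the independent block-level
#'   amplitude jitter of every (area x depth-bin) region.
#' @param subject_sd between-subject standard deviation of the multiplicative
#'   selectivity factor (drawn per subject, contrast and area).
#' @param voxel_sel_sd standard deviation of the voxel-level selectivity
#'   scatter (a fixed random tuning map per subject and contrast, on top of
#'   the compartment/area mean selectivity); this heterogeneity is what makes
#'   multivoxel patterns decodable after L2 normalization.
#' @param noise_sd voxel noise standard deviation (percent signal change per
#'   TR, after spatial smoothing).
#' @param noise_fwhm_mm spatial smoothness (FWHM) of the noise field.
#' @param seed default RNG seed of the generator.
#' @return a `ground_truth` list.
#' @export
ground_truth <- function(
    base_amplitude = c(color = 2, disparity = 2, texture = 2),
    stripe_selectivity = list(
      color = c(thin = 0.40, pale = 0.10, thick = 0.00),
      disparity = c(thin = 0.00, pale = 0.10, thick = 0.40)),
    area_selectivity = list(
      color = c(V1 = 0.15, V2 = NA, V3ab = 0.08, V4 = 0.25),
      disparity = c(V1 = 0.15, V2 = NA, V3ab = 0.30, V4 = 0.08),
      texture = c(V1 = 0.08, V2 = 0.15, V3ab = 0.30, V4 = 0.35)),
    texture_ecc_floor = 0.4,
    depth_profile = list(
      color = c(deep = 0.8, middle = 0.8, superficial = 1.4),
      disparity = c(deep = 1.0, middle = 1.0, superficial = 1.0),
      texture = c(deep = 1.8, middle = 1.0, superficial = 0.7)),
    texture_depth_areas = c("V1", "V2"),
    laminar_gain = c(deep = 0.8, middle = 1.0, superficial = 1.3),
    vein_bias = 0.3,
    vein_columns = list(frac = 0.05, gain = 2),
    shared_variability = tibble(
      area_a = "V2", bin_a = "deep", area_b = "V4", bin_b = "deep",
      contrast = "texture", w = 0.8),
    amp_jitter_sd = 0.2,
    subject_sd = 0.1,
    voxel_sel_sd = 0.15,
    noise_sd = 1.5,
    noise_fwhm_mm = 2,
    seed = 1) {
  truth <- list(base_amplitude = base_amplitude,
                stripe_selectivity = stripe_selectivity,
                area_selectivity = area_selectivity,
                texture_ecc_floor = texture_ecc_floor,
                depth_profile = depth_profile,
                texture_depth_areas = texture_depth_areas,
                laminar_gain = laminar_gain,
                vein_bias = vein_bias,
                vein_columns = vein_columns,
                shared_variability = shared_variability,
                amp_jitter_sd = amp_jitter_sd,
                subject_sd = subject_sd,
                voxel_sel_sd = voxel_sel_sd,
                noise_sd = noise_sd,
                noise_fwhm_mm = noise_fwhm_mm,
                seed = seed)
  if (noise_sd < 0) stop_input("`noise_sd` must be >= 0")
  if (nrow(truth$shared_variability) > 0 &&
      any(truth$shared_variability$w < 0 | truth$shared_variability$w > 1)) {
    stop_input("coupling weights `w` must lie in [0, 1]")
  }
  if (!all(is.finite(base_amplitude)) || any(base_amplitude < 0)) {
    stop_input("`base_amplitude` must be finite and non-negative")
  }
  structure(truth, class = "ground_truth")
}

#' Default study configuration
#'
#' The full study conditions: ten simulated subjects, three experiments per
#' subject (color, disparity, texture) with ten runs of five blocks per
#' condition each, on a four-area patch with 2000 columns per area.
#'
#' @param n_subjects number of simulated subjects.
#' @param n_runs runs per experiment.
#' @param seed master seed; subject seeds are derived deterministically.
#' @param patch patch geometry, see [patch_config()].
#' @param truth generator parameters, see [ground_truth()].
#' @return a nested configuration list understood by [run_study()] and
#'   [run_pipeline()].
#' @export
default_config <- function(n_subjects = 10, n_runs = 10, seed = 0,
                           patch = patch_config(), truth = ground_truth()) {
  list(
    n_subjects = n_subjects,
    seed = seed,
    patch = patch,
    stripe = list(cycle_mm = 12, duty = c(0.25, 0.25, 0.25, 0.25),
                  phase = "random"),
    design = list(n_runs = n_runs, blocks_per_condition = 5,
                  block_duration_s = 24, fixation_s = 16.8, TR_s = 2.4),
    truth = truth,
    analysis = list(drift_order = 2, z_threshold = 0.8, vein_fraction = 0.05,
                    top_frac = 0.2, n_tail = 200, svm_cost = 1,
                    corr_mode = "per_fold", evidence = "residual",
                    fdr_alpha = 0.05)
  )
}
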