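# Synthetic BOLD generator: plants stripe/laminar/eccentricity selectivity,
# vein gain, block-level shared amplitude variability and spatially smooth
# noise, then convolves with the canonical block response.

fwhm_to_sigma <- function(fwhm) fwhm / sqrt(8 * log(2))

# Truncated 1D Gaussian kernel and its padded convolution operator: an
# n x (n + 2m) matrix so that S %*% padded_field yields the interior of the
# smoothed field (stationary, no edge attenuation).
smooth_operator <- function(n, sigma, spacing) {
  m <- ceiling(3 * sigma / spacing)
  k <- stats::dnorm(seq(-m, m) * spacing, sd = sigma)
  S <- matrix(0, n, n + 2 * m)
  for (i in seq_len(n)) S[i, i:(i + 2 * m)] <- k
  list(S = S, m = m, k = k)
}

# Smooth white noise on per-area (u, v) grids, independently per depth slice
# and timepoint, rescaled so the marginal voxel sd is exactly `sd`.
# Returns a (nu * nv * n_depth) x nT matrix in patch row order (u fastest,
# then v, then depth sample).
smooth_area_noise <- function(nu, nv, n_depth, nT, sd, fwhm, spacing) {
  if (fwhm <= 0) {
    return(matrix(rnorm(nu * nv * n_depth * nT, sd = sd), ncol = nT))
  }
  sigma <- fwhm_to_sigma(fwhm)
  su <- smooth_operator(nu, sigma, spacing)
  sv <- smooth_operator(nv, sigma, spacing)
  pu <- nu + 2 * su$m
  pv <- nv + 2 * sv$m
  nslice <- n_depth * nT
  G <- matrix(rnorm(pu * pv * nslice), nrow = pu)
  A1 <- su$S %*% G                                   # nu x (pv * nslice)
  A1 <- aperm(array(A1, c(nu, pv, nslice)), c(2, 1, 3))
  A2 <- sv$S %*% matrix(A1, nrow = pv)               # nv x (nu * nslice)
  A2 <- aperm(array(A2, c(nv, nu, nslice)), c(2, 1, 3))
  scale <- sd / sqrt(sum(su$k^2) * sum(sv$k^2))
  # (nu, nv, n_depth * nT) -> rows ordered u fastest, v, then depth
  matrix(A2, nrow = nu * nv * n_depth) * scale
}

#' Planted per-voxel response amplitudes
#'
#' The noiseless response amplitude of every voxel to the two conditions of a
#' contrast: `base * (1 +/- sel_eff / 2)` where `sel_eff` combines stripe or
#' area selectivity, the contrast's laminar selectivity profile, the texture
#' eccentricity ramp, and an optional per-area subject factor. A voxel's
#' planted selectivity index is therefore `sel_eff / 2`.
#'
#' @param patch a `cortical_patch`.
#' @param stripes a `stripe_map` for the patch.
#' @param truth a [ground_truth()] object.
#' @param contrast one of `"color"`, `"disparity"`, `"texture"`.
#' @param area_factor optional named per-area multiplicative selectivity
#'   factor (default 1), used for between-subject variability.
#' @param sel_scatter optional per-voxel selectivity scatter (the subject's
#'   fixed random tuning map; default all zero).
#' @return voxel x 2 matrix of amplitudes, columns named by condition.
#' @export
planted_amplitudes <- function(patch, stripes, truth, contrast,
                               area_factor = NULL, sel_scatter = NULL) {
  conds <- contrast_conditions()[[contrast]]
  areas <- levels(patch$area)
  if (is.null(area_factor)) area_factor <- setNames(rep(1, length(areas)), areas)
  bin <- cut_depth_bin(patch$depth)
  g <- truth$depth_profile[[contrast]][as.character(bin)]
  if (contrast == "texture") {
    g[!(as.character(patch$area) %in% truth$texture_depth_areas)] <- 1
    ecc_max <- max(patch$ecc)
    ramp <- truth$texture_ecc_floor +
      (1 - truth$texture_ecc_floor) * patch$ecc / max(ecc_max, 1e-9)
    sel <- truth$area_selectivity$texture[as.character(patch$area)] * ramp
  } else {
    sel <- truth$area_selectivity[[contrast]][as.character(patch$area)]
    in_v2 <- patch$area == "V2"
    sel[in_v2] <- truth$stripe_selectivity[[contrast]][
      as.character(stripes$compartment[in_v2])]
  }
  if (is.null(sel_scatter)) sel_scatter <- 0
  sel_eff <- (sel + sel_scatter) * g * area_factor[as.character(patch$area)]
  base <- truth$base_amplitude[[contrast]]
  amp <- cbind(base * (1 + sel_eff / 2), base * (1 - sel_eff / 2))
  dimnames(amp) <- list(NULL, conds)
  amp
}

# Common multiplicative response gain: laminar gain x global pial-vein bias
# x extra gain of vein-carrying columns. Applies to both conditions equally.
voxel_gain <- function(patch, truth, vein_columns) {
  bin <- cut_depth_bin(patch$depth)
  gain <- truth$laminar_gain[as.character(bin)] *
    (1 + truth$vein_bias * patch$depth^2)
  is_vein <- patch$column_id %in% vein_columns
  gain[is_vein] <- gain[is_vein] * (1 + truth$vein_columns$gain * patch$depth[is_vein])
  unname(gain)
}

#' Simulate a block-design BOLD dataset
#'
#' Builds per-run voxel x timepoint matrices (percent signal change): each
#' block contributes `amplitude x gain x (1 + w s_b + jitter)` times the
#' canonical block response, where `s_b` is a standard-normal block-level
#' latent shared between the region-layer pairs coupled in
#' `truth$shared_variability`, and every (area x depth-bin) region also
#' receives independent block-level jitter. Spatially smoothed Gaussian noise
#' (FWHM `truth$noise_fwhm_mm`), i.i.d. over time, is added. Fully
#' reproducible given `seed`.
#'
#' @inheritParams planted_amplitudes
#' @param design a [make_block_design()] object whose conditions match the
#'   contrast.
#' @param seed RNG seed; per-run noise streams are derived from it.
#' @param vein_columns column ids carrying a draining vein; drawn at random
#'   (`truth$vein_columns$frac` of columns) when `NULL`.
#' @param sel_scatter per-voxel selectivity scatter; drawn
#'   `N(0, truth$voxel_sel_sd)` when `NULL`. Pass the subject's map to keep
#'   it fixed across sessions.
#' @param drop_noise set the noise to zero (noiseless limit for exactness
#'   tests).
#' @return a `bold_dataset` list: `runs` (list of voxel x timepoint
#'   matrices), `design`, `patch`, `stripes`, `truth`, `contrast`,
#'   `conditions`, and a `planted` list holding the realized amplitudes,
#'   gains, block multipliers and latents.
#' @export
simulate_bold <- function(patch, stripes, design, truth,
                          contrast = c("color", "disparity", "texture"),
                          seed = truth$seed, area_factor = NULL,
                          vein_columns = NULL, sel_scatter = NULL,
                          drop_noise = FALSE) {
  contrast <- match.arg(contrast)
  if (nrow(stripes) != nrow(patch)) {
    stop_input("stripe map and patch have different voxel counts")
  }
  conds <- contrast_conditions()[[contrast]]
  if (!identical(sort(design$conditions), sort(conds))) {
    stop_input("design conditions do not match contrast ", contrast)
  }
  geom <- patch_geometry(patch)
  bin <- cut_depth_bin(patch$depth)
  region <- interaction(patch$area, bin, drop = FALSE)
  n_regions <- nlevels(region)
  n_blocks_run <- length(design$conditions) * design$blocks_per_condition
  n_blocks <- design$n_runs * n_blocks_run

  if (is.null(vein_columns)) {
    cols <- unique(patch$column_id)
    vein_columns <- with_seed(derive_seed(seed, 7),
      sample(cols, ceiling(truth$vein_columns$frac * length(cols))))
  }
  if (is.null(sel_scatter)) {
    sel_scatter <- with_seed(derive_seed(seed, 19),
                             rnorm(nrow(patch), sd = truth$voxel_sel_sd))
  }
  amp <- planted_amplitudes(patch, stripes, truth, contrast, area_factor,
                            sel_scatter)
  gain <- voxel_gain(patch, truth, vein_columns)

  couplings <- truth$shared_variability
  couplings <- couplings[couplings$contrast == contrast, , drop = FALSE]
  latents <- with_seed(derive_seed(seed, 13), {
    s <- if (nrow(couplings)) {
      matrix(rnorm(nrow(couplings) * n_blocks), nrow(couplings), n_blocks)
    } else {
      matrix(0, 0, n_blocks)
    }
    E <- matrix(rnorm(n_regions * n_blocks), n_regions, n_blocks)
    list(s = s, E = E)
  })
  # Block multiplier: 1 + amp_jitter_sd * (w s_b + sqrt(1 - w^2) e_rb) for
  # coupled regions, 1 + amp_jitter_sd * e_rb otherwise, so the coupling
  # weight sets the correlation between the two regions' block amplitudes
  # without changing either region's amplitude variance.
  shared <- matrix(0, n_regions, n_blocks)
  wreg <- rep(0, n_regions)
  if (nrow(couplings)) {
    reg_lab <- function(a, b) paste(a, b, sep = ".")
    for (i in seq_len(nrow(couplings))) {
      for (lab in c(reg_lab(couplings$area_a[i], couplings$bin_a[i]),
                    reg_lab(couplings$area_b[i], couplings$bin_b[i]))) {
        j <- match(lab, levels(region))
        if (is.na(j)) stop_input("coupling names unknown region ", lab)
        shared[j, ] <- couplings$w[i] * latents$s[i, ]
        wreg[j] <- couplings$w[i]
      }
    }
  }
  mult <- 1 + truth$amp_jitter_sd *
    (shared + sqrt(1 - wreg^2) * latents$E)

  reg_idx <- as.integer(region)
  runs <- vector("list", design$n_runs)
  for (r in seq_len(design$n_runs)) {
    Xb <- build_design_matrix(design, r, "per_block", drift_order = 0)
    B <- Xb$matrix[, Xb$condition_columns, drop = FALSE]   # T x blocks
    cond_of_block <- Xb$block_info$condition
    bidx <- (r - 1) * n_blocks_run + seq_len(n_blocks_run)
    W <- amp[, cond_of_block, drop = FALSE] * gain *
      mult[reg_idx, bidx, drop = FALSE]
    Y <- W %*% t(B)
    if (!drop_noise && truth$noise_sd > 0) {
      noise <- with_seed(derive_seed(seed, 100 + r), {
        do.call(rbind, lapply(levels(patch$area), function(a) {
          smooth_area_noise(geom$nu, geom$nv, geom$n_depth,
                            design$n_timepoints, truth$noise_sd,
                            truth$noise_fwhm_mm, geom$spacing_mm)
        }))
      })
      Y <- Y + noise
    }
    runs[[r]] <- Y
  }
  structure(list(runs = runs, design = design, patch = patch,
                 stripes = stripes, truth = truth, contrast = contrast,
                 conditions = conds,
                 planted = list(amplitudes = amp, gain = gain,
                                vein_columns = vein_columns, mult = mult,
                                latents = latents$s, region = region,
                                sel_scatter = sel_scatter)),
            class = "bold_dataset")
}

#' Simulate one subject's full session
#'
#' One cortical patch and stripe map per subject (deterministic from the
#' config), subject-specific vein columns and per-area selectivity factors,
#' and one [simulate_bold()] dataset per contrast.
#'
#' @param config a [default_config()] list.
#' @param subject subject index (seeds are derived from `config$seed` and
#'   this index).
#' @return list with `patch`, `stripes`, `datasets` (named by contrast),
#'   `area_factor`, `vein_columns`, `subject`, `seed`.
#' @export
simulate_subject <- function(config = default_config(), subject = 1) {
  seed_s <- derive_seed(config$seed, subject)
  patch <- make_cortical_patch(config$patch)
  phase <- config$stripe$phase
  if (identical(phase, "random")) {
    # each subject's stripe system sits at its own phase, as in real cortex
    phase <- with_seed(derive_seed(seed_s, 3),
                       runif(1, 0, config$stripe$cycle_mm))
  }
  stripes <- make_stripe_map(patch, cycle_mm = config$stripe$cycle_mm,
                             duty = config$stripe$duty, phase = phase)
  areas <- levels(patch$area)
  cols <- unique(patch$column_id)
  vein_columns <- with_seed(derive_seed(seed_s, 7),
    sample(cols, ceiling(config$truth$vein_columns$frac * length(cols))))
  contrasts <- names(contrast_conditions())
  area_factor <- with_seed(derive_seed(seed_s, 5), {
    lapply(setNames(contrasts, contrasts), function(ct) {
      setNames(1 + rnorm(length(areas), sd = config$truth$subject_sd), areas)
    })
  })
  sel_scatter <- with_seed(derive_seed(seed_s, 9), {
    lapply(setNames(contrasts, contrasts), function(ct) {
      rnorm(nrow(patch), sd = config$truth$voxel_sel_sd)
    })
  })
  datasets <- lapply(setNames(contrasts, contrasts), function(ct) {
    des <- make_block_design(
      contrast_conditions()[[ct]],
      n_runs = config$design$n_runs,
      blocks_per_condition = config$design$blocks_per_condition,
      block_duration_s = config$design$block_duration_s,
      fixation_s = config$design$fixation_s,
      TR_s = config$design$TR_s)
    simulate_bold(patch, stripes, des, config$truth, contrast = ct,
                  seed = derive_seed(seed_s, match(ct, contrasts)),
                  area_factor = area_factor[[ct]],
                  vein_columns = vein_columns,
                  sel_scatter = sel_scatter[[ct]])
  })
  list(patch = patch, stripes = stripes, datasets = datasets,
       area_factor = area_factor, vein_columns = vein_columns,
       sel_scatter = sel_scatter, subject = subject, seed = seed_s)
}
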