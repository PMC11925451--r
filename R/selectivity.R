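# Stimulus-selectivity indices, laminar / eccentricity / stripe-compartment
# profiles, and automated stripe segmentation from differential maps.

#' Stimulus selectivity index
#'
#' `SI = (beta_A - beta_B) / (beta_A + beta_B)`: the normalized response
#' difference between a condition pair (chromatic vs achromatic, disparity vs
#' flat, texture vs noise). Antisymmetric in its arguments and bounded in
#' `[-1, 1]` when both betas are positive. A zero denominator yields `NA`
#' (the voxel is dropped from aggregation).
#'
#' @param beta_a,beta_b response amplitudes (vectors recycle).
#' @return numeric vector of selectivity indices.
#' @examples
#' selectivity_index(1.5, 0.5) # 0.5
#' @export
selectivity_index <- function(beta_a, beta_b) {
  denom <- beta_a + beta_b
  out <- (beta_a - beta_b) / denom
  out[denom == 0] <- NA_real_
  out
}

# Retained-voxel filter: drop all depths of vein-excluded columns.
apply_vein_mask <- function(patch, vein_mask) {
  if (is.null(vein_mask)) return(patch)
  bad <- vein_mask$column_id[vein_mask$excluded]
  patch[!(patch$column_id %in% bad), ]
}

roi_profile <- function(fit, patch, groups, group_name) {
  conds <- colnames(fit$betas)[1:2]
  df <- tibble(voxel_id = patch$voxel_id,
               grp = groups,
               beta_a = fit$betas[patch$voxel_id, conds[1]],
               beta_b = fit$betas[patch$voxel_id, conds[2]])
  out <- df %>%
    group_by(grp) %>%
    summarise(beta_a = mean(beta_a), beta_b = mean(beta_b),
              n_vox = dplyr::n(), .groups = "drop") %>%
    mutate(si = selectivity_index(beta_a, beta_b))
  names(out)[names(out) == "grp"] <- group_name
  out
}

#' Laminar selectivity profile
#'
#' ROI-averaged betas per depth bin (all retained voxels of the area; vein
#' excluded columns dropped), then the selectivity index of the averaged
#' betas — the aggregation order matters and is fixed as SI-of-mean-betas.
#'
#' @param fit a `dataset_glm` whose first two beta columns are the contrast's
#'   condition pair.
#' @param patch the `cortical_patch`.
#' @param area area label to profile.
#' @param vein_mask optional [remove_pial_veins()] mask.
#' @return tibble with `area`, `bin`, `beta_a`, `beta_b`, `n_vox`, `si`.
#' @export
laminar_profile <- function(fit, patch, area, vein_mask = NULL) {
  roi <- apply_vein_mask(patch[patch$area == area, ], vein_mask)
  if (nrow(roi) == 0) stop_input("no retained voxels in area ", area)
  bins <- cut_depth_bin(roi$depth)
  if (any(table(bins) == 0)) {
    stop_input("empty depth bin in area ", area, ": ",
               paste(names(which(table(bins) == 0)), collapse = ", "))
  }
  out <- roi_profile(fit, roi, bins, "bin")
  dplyr::bind_cols(tibble(area = area), out)
}

#' Eccentricity selectivity profile
#'
#' Same averaging contract as [laminar_profile()], binned by eccentricity
#' with half-open edges (a voxel at 3 degrees falls in the 3-6 bin).
#'
#' @inheritParams laminar_profile
#' @param bin_edges eccentricity bin edges in degrees.
#' @param labels bin labels; defaults to central/parafoveal/peripheral for
#'   three bins.
#' @return tibble with `area`, `ecc_bin`, `beta_a`, `beta_b`, `n_vox`, `si`.
#' @export
eccentricity_profile <- function(fit, patch, area,
                                 bin_edges = c(0, 3, 6, 18),
                                 vein_mask = NULL, labels = NULL) {
  roi <- apply_vein_mask(patch[patch$area == area, ], vein_mask)
  if (is.null(labels)) {
    labels <- if (length(bin_edges) == 4) {
      c("central", "parafoveal", "peripheral")
    } else {
      paste(head(bin_edges, -1), tail(bin_edges, -1), sep = "-")
    }
  }
  bins <- cut(roi$ecc, breaks = bin_edges, labels = labels,
              right = FALSE, include.lowest = TRUE)
  if (any(is.na(bins))) stop_input("eccentricities outside `bin_edges`")
  if (any(table(bins) == 0)) {
    stop_input("empty eccentricity bin: ",
               paste(names(which(table(bins) == 0)), collapse = ", "))
  }
  out <- roi_profile(fit, roi, bins, "ecc_bin")
  dplyr::bind_cols(tibble(area = area), out)
}

#' Column-level differential activation map
#'
#' The color-minus-disparity differential response used to segment stripes:
#' `(beta_Chr - beta_Ach) - (beta_3D - beta_2D)`, averaged across the depth
#' samples of each V2 column, restricted to columns whose mean activation
#' across all stimulus conditions exceeds zero.
#'
#' @param fit_color,fit_disparity `dataset_glm` fits of the two experiments.
#' @param patch the `cortical_patch`.
#' @param area area to map (default `"V2"`).
#' @return tibble with `column_id`, `u`, `v`, `value` (one row per retained
#'   column).
#' @export
differential_map <- function(fit_color, fit_disparity, patch, area = "V2") {
  roi <- patch[patch$area == area, ]
  d <- (fit_color$betas[roi$voxel_id, 1] - fit_color$betas[roi$voxel_id, 2]) -
    (fit_disparity$betas[roi$voxel_id, 1] - fit_disparity$betas[roi$voxel_id, 2])
  act <- rowMeans(cbind(fit_color$betas[roi$voxel_id, 1:2],
                        fit_disparity$betas[roi$voxel_id, 1:2]))
  tibble(column_id = roi$column_id, u = roi$u, v = roi$v,
         value = d, act = act) %>%
    group_by(column_id, u, v) %>%
    summarise(value = mean(value), act = mean(act), .groups = "drop") %>%
    filter(act > 0) %>%
    select(column_id, u, v, value)
}

# Flood-fill connected components (4-neighborhood) of a logical matrix.
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      id <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[id] != 0L) next
      lab[id] <- cur
      i <- (id - 1L) %% nrow(mask) + 1L
      j <- (id - 1L) %/% nrow(mask) + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] >= 1 && nb[1] <= nrow(mask) && nb[2] >= 1 && nb[2] <= ncol(mask)) {
          nid <- nb[1] + (nb[2] - 1L) * nrow(mask)
          if (mask[nid] && lab[nid] == 0L) stack <- c(stack, nid)
        }
      }
    }
  }
  lab
}

#' Segment thin / thick / pale stripes from a differential map
#'
#' Deterministic threshold-and-components substitute for manual stripe
#' delineation: the differential map is z-scored across its columns, connected
#' components above `+z` become thin-stripe candidates, components below `-z`
#' thick-stripe candidates, and unlabelled columns lying between a thin and a
#' thick band along `u` (within the same `v` row) become pale. Columns absent
#' from `differential` (mean activation <= 0) are labelled `none`, as are all
#' non-V2 voxels.
#'
#' @param differential a [differential_map()] tibble (`column_id`, `u`, `v`,
#'   `value`).
#' @param patch the `cortical_patch`.
#' @param z threshold on the standardized differential map.
#' @param area the striped area (default `"V2"`).
#' @param smooth_fwhm_mm light Gaussian smoothing of the column map before
#'   standardization (normalized convolution, missing columns ignored);
#'   suppresses voxel-scale tuning scatter relative to the millimetre-scale
#'   bands. 0 disables.
#' @return a `stripe_estimate` tibble (`voxel_id`, `column_id`,
#'   `compartment`) covering every voxel of `patch`, with attribute
#'   `threshold = z`. Empty segmentations (no suprathreshold columns) are
#'   returned with a warning.
#' @export
segment_stripes <- function(differential, patch, z = 1, area = "V2",
                            smooth_fwhm_mm = 1.5) {
  uu <- sort(unique(differential$u))
  vv <- sort(unique(differential$v))
  iu <- match(differential$u, uu)
  iv <- match(differential$v, vv)
  vmat <- matrix(NA_real_, length(uu), length(vv))
  vmat[cbind(iu, iv)] <- differential$value
  if (smooth_fwhm_mm > 0) {
    spacing <- min(diff(uu), diff(vv))
    sg <- fwhm_to_sigma(smooth_fwhm_mm)
    m <- ceiling(3 * sg / spacing)
    k <- stats::dnorm(seq(-m, m) * spacing, sd = sg)
    conv1 <- function(M, along) {
      if (along == 2) M <- t(M)
      out <- matrix(0, nrow(M), ncol(M))
      for (j in seq_along(k)) {
        sh <- j - m - 1
        src <- seq_len(nrow(M)) + sh
        ok <- src >= 1 & src <= nrow(M)
        out[ok, ] <- out[ok, ] + k[j] * M[src[ok], ]
      }
      if (along == 2) t(out) else out
    }
    w <- ifelse(is.na(vmat), 0, 1)
    v0 <- ifelse(is.na(vmat), 0, vmat)
    num <- conv1(conv1(v0, 1), 2)
    den <- conv1(conv1(w, 1), 2)
    sm <- num / den
    sm[is.na(vmat)] <- NA
    vmat <- sm
  }
  zval <- (vmat[cbind(iu, iv)] - mean(vmat, na.rm = TRUE)) /
    sd(vmat, na.rm = TRUE)
  zmat <- matrix(NA_real_, length(uu), length(vv))
  zmat[cbind(iu, iv)] <- zval
  pos <- !is.na(zmat) & zmat > z
  neg <- !is.na(zmat) & zmat < -z
  if (!any(pos) && !any(neg)) {
    warning("no suprathreshold columns; empty stripe estimate")
  }
  lab <- matrix("unlabelled", length(uu), length(vv))
  lab[label_components(pos) > 0] <- "thin"
  lab[label_components(neg) > 0] <- "thick"
  lab[is.na(zmat)] <- "none"
  # pale: nearest labelled bands on both sides along u are one thin, one thick;
  # at the map edges, where the outer band lies beyond the grid, pale is
  # extended outward by the typical interior pale width.
  for (j in seq_along(vv)) {
    row <- lab[, j]
    lab_idx <- which(row %in% c("thin", "thick"))
    if (length(lab_idx) < 2) next
    for (i in which(row == "unlabelled")) {
      left <- lab_idx[lab_idx < i]
      right <- lab_idx[lab_idx > i]
      if (length(left) && length(right)) {
        pair <- sort(c(row[max(left)], row[min(right)]))
        if (identical(pair, c("thick", "thin"))) lab[i, j] <- "pale"
      }
    }
    runs <- rle(lab[, j])
    pale_w <- stats::median(runs$lengths[runs$values == "pale"])
    if (!is.na(pale_w)) {
      first <- min(lab_idx)
      last <- max(lab_idx)
      before <- which(lab[, j] == "unlabelled" & seq_along(row) < first &
                        seq_along(row) >= first - pale_w)
      after <- which(lab[, j] == "unlabelled" & seq_along(row) > last &
                       seq_along(row) <= last + pale_w)
      lab[c(before, after), j] <- "pale"
    }
  }
  lab[lab == "unlabelled"] <- "none"
  col_lab <- tibble(column_id = differential$column_id,
                    compartment = lab[cbind(iu, iv)])
  out <- patch %>%
    select(voxel_id, column_id, area_ = area) %>%
    left_join(col_lab, by = "column_id") %>%
    mutate(compartment = ifelse(area_ != area | is.na(compartment),
                                "none", compartment),
           compartment = factor(compartment, levels = compartment_levels)) %>%
    select(voxel_id, column_id, compartment)
  structure(out, threshold = z, class = c("stripe_estimate", class(out)))
}

#' Stripe-compartment selectivity profile
#'
#' Selectivity index of compartment-averaged betas for the thin, thick and
#' pale stripes.
#'
#' @inheritParams laminar_profile
#' @param stripes a `stripe_estimate` (or ground-truth `stripe_map`).
#' @return tibble with `compartment`, `beta_a`, `beta_b`, `n_vox`, `si`.
#' @export
compartment_profile <- function(fit, patch, stripes, vein_mask = NULL) {
  comp <- stripes$compartment[match(patch$voxel_id, stripes$voxel_id)]
  roi <- apply_vein_mask(patch[comp != "none", ], vein_mask)
  comp <- stripes$compartment[match(roi$voxel_id, stripes$voxel_id)]
  comp <- factor(as.character(comp), levels = c("thin", "thick", "pale"))
  if (any(table(comp) == 0)) {
    stop_input("empty compartment: ",
               paste(names(which(table(comp) == 0)), collapse = ", "))
  }
  roi_profile(fit, roi, comp, "compartment")
}

#' Dice overlap between estimated and ground-truth compartments
#'
#' @param estimate a `stripe_estimate`.
#' @param truth_map the planted `stripe_map`.
#' @param compartments which labels to score.
#' @return tibble with `compartment`, `dice`.
#' @export
stripe_dice <- function(estimate, truth_map,
                        compartments = c("thin", "thick", "pale")) {
  est <- estimate$compartment[match(truth_map$voxel_id, estimate$voxel_id)]
  tibble(compartment = compartments,
         dice = vapply(compartments, function(cp) {
           a <- est == cp
           b <- truth_map$compartment == cp
           2 * sum(a & b) / (sum(a) + sum(b))
         }, numeric(1)))
}
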