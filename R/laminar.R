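# Equi-volume cortical depth, three-bin depth assignment, pial-vein exclusion.

#' Equi-volume cortical depth
#'
#' Maps a cumulative volume fraction `alpha` (measured from the white-matter
#' surface) to the geometric depth fraction `rho` of the surface that encloses
#' that volume, assuming the local surface area varies linearly from `A_inner`
#' (white matter) to `A_outer` (pial) across the thickness. On a flat cortex
#' (`A_inner == A_outer`) the two coordinates coincide; on a gyral crown
#' (`A_outer > A_inner`) equi-volume laminae are compressed towards the white
#' matter, and conversely in a sulcal fundus.
#'
#' @param alpha cumulative volume fraction(s) in `[0, 1]`.
#' @param A_inner,A_outer local surface-area elements (mm^2), strictly positive.
#' @return geometric depth fraction(s) in `[0, 1]`, strictly increasing in
#'   `alpha` and continuous in the flat limit.
#' @examples
#' equivolume_depth(0.5, 1, 2) # (-1 + sqrt(2.5)) / 1
#' equivolume_depth(0.5, 1, 1) # flat: 0.5
#' @export
equivolume_depth <- function(alpha, A_inner, A_outer) {
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1)) {
    stop_input("`alpha` must lie in [0, 1]")
  }
  if (any(A_inner <= 0) || any(A_outer <= 0)) {
    stop_input("`A_inner` and `A_outer` must be positive")
  }
  n <- max(length(alpha), length(A_inner), length(A_outer))
  alpha <- rep_len(alpha, n)
  ai <- rep_len(A_inner, n)
  ao <- rep_len(A_outer, n)
  d <- ao - ai
  flat <- abs(d) < 1e-12 * pmax(ai, ao)
  out <- alpha
  if (any(!flat)) {
    out[!flat] <- (-ai[!flat] +
      sqrt(alpha[!flat] * ao[!flat]^2 + (1 - alpha[!flat]) * ai[!flat]^2)) /
      d[!flat]
  }
  pmin(pmax(out, 0), 1)
}

#' Inverse equi-volume transform: geometric depth to volume fraction
#'
#' The volume enclosed between the white-matter surface and the surface at
#' geometric depth `rho`, as a fraction of the full cortical volume of the
#' column; the exact inverse of [equivolume_depth()].
#'
#' @param rho geometric depth fraction(s) in `[0, 1]`.
#' @inheritParams equivolume_depth
#' @return volume fraction(s) in `[0, 1]`.
#' @export
equivolume_alpha <- function(rho, A_inner, A_outer) {
  if (any(!is.finite(rho)) || any(rho < 0) || any(rho > 1)) {
    stop_input("`rho` must lie in [0, 1]")
  }
  (2 * A_inner * rho + (A_outer - A_inner) * rho^2) / (A_inner + A_outer)
}

#' Assign voxels to the three canonical depth bins
#'
#' Splits equi-volume depth into deep `[0, 0.33)`, middle `[0.33, 0.67)` and
#' superficial `[0.67, 1]` bins (half-open boundaries resolve the printed
#' overlap at 0.33/0.67 deterministically).
#'
#' @param patch a `cortical_patch`, or any data frame with `voxel_id` and
#'   `depth` columns.
#' @return a tibble with `voxel_id`, `depth`, `bin`.
#' @examples
#' assign_depth_bins(tibble::tibble(voxel_id = 1:3, depth = c(0, 0.33, 1)))
#' @export
assign_depth_bins <- function(patch) {
  if (any(patch$depth < 0 | patch$depth > 1)) {
    stop_input("depths must lie in [0, 1]")
  }
  tibble(voxel_id = patch$voxel_id, depth = patch$depth,
         bin = cut_depth_bin(patch$depth))
}

#' Exclude pial-vein cortical columns
#'
#' Ranks cortical columns ("vertices") by their mean signal change from
#' baseline over all stimulus conditions and excludes the top fraction; the
#' exclusion propagates to all depths of an excluded column. Ties at the
#' cutoff are broken by excluding the smaller `column_id` first, so the mask
#' is deterministic.
#'
#' @param column_signal data frame with one row per cortical column:
#'   `column_id` and `mean_signal` (the all-conditions-vs-baseline response
#'   averaged across the column's depth samples).
#' @param fraction fraction of columns to exclude (default 0.05, i.e. the top
#'   5 percent).
#' @return a `vein_mask` tibble with `column_id`, `excluded`.
#' @examples
#' remove_pial_veins(tibble::tibble(column_id = 1:100, mean_signal = rnorm(100)))
#' @export
remove_pial_veins <- function(column_signal, fraction = 0.05) {
  check_number(fraction, "fraction", lower = 1e-12, upper = 1 - 1e-12)
  if (anyDuplicated(column_signal$column_id)) {
    stop_input("`column_signal` must contain one row per column")
  }
  n <- nrow(column_signal)
  n_excl <- ceiling(fraction * n)
  ord <- order(-column_signal$mean_signal, column_signal$column_id)
  out <- tibble(column_id = column_signal$column_id,
                excluded = logical(n))
  out$excluded[ord[seq_len(n_excl)]] <- TRUE
  structure(out, fraction = fraction,
            class = c("vein_mask", class(out)))
}

#' Per-column mean signal for vein ranking
#'
#' Computes, for each cortical column of `patch`, the mean over depth samples
#' of the all-conditions-vs-baseline GLM response, the quantity the pial-vein
#' exclusion ranks.
#'
#' @param fit a `bold_glm` fit (per-condition mode), see [fit_glm()].
#' @param patch the `cortical_patch` the fit was computed on.
#' @return tibble with `column_id`, `mean_signal`.
#' @export
column_mean_signal <- function(fit, patch) {
  ms <- rowMeans(fit$betas)
  tibble(column_id = patch$column_id, signal = ms) %>%
    group_by(column_id) %>%
    summarise(mean_signal = mean(signal), .groups = "drop")
}
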