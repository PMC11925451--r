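# Synthetic cortical geometry: an abstract 2D sheet (u, v) x depth grid.
# v = 0 is the V1-V2 border; stripes run along v (perpendicular to the border).

#' Default cortical patch geometry
#'
#' Geometry of the synthetic cortical sheet: per-area column grids, depth
#' samples per column, the eccentricity map and a curvature profile from which
#' local inner/outer surface areas are derived.
#'
#' @param areas ordered area labels, lower to higher in the visual hierarchy.
#' @param nu,nv number of columns along `u` (parallel to the area border) and
#'   `v` (perpendicular) per area.
#' @param spacing_mm grid spacing in millimetres.
#' @param n_depth depth samples per column (equally spaced geometric depths).
#' @param ecc_range eccentricity range in degrees of visual angle.
#' @param ecc_axis axis along which eccentricity increases linearly: `"u"`
#'   (default, so stripe cycles sample all eccentricities) or `"v"`.
#' @param curvature list with `type` (`"flat"` or `"sinusoidal"`), `amplitude`
#'   and `period_mm`; controls the per-column inner/outer surface areas.
#' @return a list usable as the `config` of [make_cortical_patch()].
#' @export
patch_config <- function(areas = c("V1", "V2", "V3ab", "V4"),
                         nu = 50, nv = 44, spacing_mm = 1, n_depth = 3,
                         ecc_range = c(0, 18), ecc_axis = c("u", "v"),
                         curvature = list(type = "sinusoidal",
                                          amplitude = 0.3, period_mm = 25)) {
  list(areas = areas, nu = nu, nv = nv, spacing_mm = spacing_mm,
       n_depth = n_depth, ecc_range = ecc_range,
       ecc_axis = match.arg(ecc_axis), curvature = curvature)
}

#' Generate a synthetic cortical patch
#'
#' Builds a tibble of voxels on an abstract cortical sheet: per-area `(u, v)`
#' column grids with `n_depth` voxels per column at equally spaced geometric
#' depths. Each voxel's stored `depth` is its equi-volume depth fraction
#' (0 = white-matter surface, 1 = pial surface) computed from the local
#' inner/outer surface areas via [equivolume_depth()]'s inverse, so that a
#' curved cortex yields depth bins of equal volume rather than equal thickness.
#'
#' @param config geometry specification, see [patch_config()].
#' @return a `cortical_patch` tibble with columns `voxel_id`, `column_id`,
#'   `area`, `u`, `v`, `k` (depth sample index), `rho` (geometric depth
#'   fraction), `depth` (equi-volume fraction), `ecc`, `A_inner`, `A_outer`.
#' @examples
#' patch <- make_cortical_patch(patch_config(nu = 8, nv = 4))
#' dplyr::count(patch, area)
#' @export
make_cortical_patch <- function(config = patch_config()) {
  cf <- utils::modifyList(patch_config(), config)
  if (cf$nu < 1 || cf$nv < 1 || cf$n_depth < 1) {
    stop_input("patch grid dimensions (nu, nv, n_depth) must be positive")
  }
  if (length(cf$areas) < 1) stop_input("at least one area is required")
  u <- (seq_len(cf$nu) - 1) * cf$spacing_mm
  grid_one <- function(area_idx) {
    area <- cf$areas[area_idx]
    # V1 sits at v < 0, all later areas stack at v >= 0 away from the border
    v0 <- (area_idx - 2) * cf$nv * cf$spacing_mm
    v <- v0 + (seq_len(cf$nv) - 0.5) * cf$spacing_mm
    g <- tidyr::expand_grid(v = v, u = u)
    g$area <- area
    g
  }
  cols <- dplyr::bind_rows(lapply(seq_along(cf$areas), grid_one))
  cols$column_id <- seq_len(nrow(cols))

  curv <- switch(cf$curvature$type,
    flat = rep(0, nrow(cols)),
    sinusoidal = cf$curvature$amplitude *
      sin(2 * pi * cols$v / cf$curvature$period_mm),
    stop_input("unknown curvature type: ", cf$curvature$type)
  )
  cols$A_inner <- exp(-curv)
  cols$A_outer <- exp(curv)

  span <- function(x) if (diff(range(x)) == 0) rep(0, length(x)) else
    (x - min(x)) / diff(range(x))
  if (cf$ecc_axis == "u") {
    frac <- span(cols$u)
  } else {
    frac <- unsplit(lapply(split(cols$v, cols$area), span), cols$area)
  }
  cols$ecc <- cf$ecc_range[1] + frac * diff(cf$ecc_range)

  rho <- (seq_len(cf$n_depth) - 0.5) / cf$n_depth
  patch <- tidyr::expand_grid(cols, k = seq_len(cf$n_depth)) %>%
    mutate(rho = rho[k],
           depth = equivolume_alpha(rho, A_inner, A_outer)) %>%
    mutate(area = factor(area, levels = cf$areas)) %>%
    arrange(area, k, v, u) %>%
    mutate(voxel_id = dplyr::row_number()) %>%
    select(voxel_id, column_id, area, u, v, k, rho, depth, ecc,
           A_inner, A_outer)

  bins <- table(patch$area, cut_depth_bin(patch$depth))
  if (cf$n_depth >= 3 && any(bins == 0)) {
    stop_input("patch geometry leaves an area without voxels in some depth bin")
  }
  structure(as_tibble(patch), geometry = cf,
            class = c("cortical_patch", class(patch)))
}

#' Geometry metadata of a cortical patch
#' @param patch a `cortical_patch`.
#' @return the geometry config list the patch was built from.
#' @export
patch_geometry <- function(patch) attr(patch, "geometry")

#' Generate a ground-truth stripe map
#'
#' Labels V2 voxels with interdigitated thin/pale/thick/pale bands that are
#' periodic along `u` and constant along `v`, i.e. stripe-shaped columns
#' running perpendicular to the V1-V2 border. Voxels outside V2 are labelled
#' `none`.
#'
#' @param patch a `cortical_patch`.
#' @param cycle_mm length of one full thin + pale + thick + pale cycle (mm).
#' @param duty fractions of the cycle occupied by (thin, pale, thick, pale),
#'   summing to 1.
#' @param phase offset of the cycle origin along `u` (mm).
#' @return a `stripe_map` tibble with columns `voxel_id`, `compartment`.
#' @examples
#' patch <- make_cortical_patch(patch_config(nu = 16, nv = 4))
#' table(make_stripe_map(patch, cycle_mm = 8)$compartment)
#' @export
make_stripe_map <- function(patch, cycle_mm = 8,
                            duty = c(0.25, 0.25, 0.25, 0.25), phase = 0) {
  check_number(cycle_mm, "cycle_mm", lower = 1e-9)
  if (length(duty) != 4 || any(duty < 0) || abs(sum(duty) - 1) > 1e-8) {
    stop_input("`duty` must be 4 non-negative fractions (thin, pale, thick, pale) summing to 1")
  }
  edges <- cumsum(c(0, duty)) * cycle_mm
  pos <- (patch$u - phase) %% cycle_mm
  band <- findInterval(pos, edges, rightmost.closed = FALSE, left.open = FALSE)
  band[band > 4] <- 4
  lab <- c("thin", "pale", "thick", "pale")[band]
  lab[patch$area != "V2"] <- "none"
  out <- tibble(voxel_id = patch$voxel_id,
                compartment = factor(lab, levels = compartment_levels))
  structure(out, cycle_mm = cycle_mm, duty = duty, phase = phase,
            class = c("stripe_map", class(out)))
}

#' Build a counterbalanced block design
#'
#' Conditions alternate in fixed-length stimulus blocks between lead and trail
#' fixation periods; the starting condition rotates across runs so the
#' condition order is counterbalanced over the session.
#'
#' @param conditions character vector of condition labels (e.g. `c("Chr", "Ach")`).
#' @param n_runs number of runs.
#' @param blocks_per_condition stimulus blocks per condition per run.
#' @param block_duration_s block duration in seconds.
#' @param fixation_s lead/trail fixation duration in seconds.
#' @param TR_s repetition time in seconds.
#' @param tol_tr largest acceptable mismatch between the run length and a whole
#'   number of TRs, as a fraction of one TR.
#' @return a `block_design` list with the design parameters, `n_timepoints`,
#'   and an `onsets` tibble (`run`, `block`, `onset_s`, `condition`).
#' @examples
#' d <- make_block_design(c("T", "N"), n_runs = 2, blocks_per_condition = 5)
#' d$n_timepoints
#' @export
make_block_design <- function(conditions, n_runs, blocks_per_condition,
                              block_duration_s = 24, fixation_s = 16.8,
                              TR_s = 2.4, tol_tr = 0.25) {
  if (length(conditions) < 1) stop_input("at least one condition is required")
  check_number(n_runs, "n_runs", lower = 1)
  check_number(blocks_per_condition, "blocks_per_condition", lower = 1)
  check_number(block_duration_s, "block_duration_s", lower = 1e-9)
  check_number(TR_s, "TR_s", lower = 1e-9)
  k <- length(conditions)
  n_blocks <- k * blocks_per_condition
  run_s <- 2 * fixation_s + n_blocks * block_duration_s
  n_tr <- round(run_s / TR_s)
  if (abs(run_s / TR_s - n_tr) > tol_tr) {
    stop_input(sprintf(
      "run length %.1f s is not a whole number of TRs (%.2f TRs at TR = %.2f s); adjust fixation_s or TR_s",
      run_s, run_s / TR_s, TR_s))
  }
  onsets <- dplyr::bind_rows(lapply(seq_len(n_runs), function(r) {
    ord <- conditions[((seq_len(n_blocks) - 1 + (r - 1)) %% k) + 1]
    tibble(run = r, block = seq_len(n_blocks),
           onset_s = fixation_s + (seq_len(n_blocks) - 1) * block_duration_s,
           condition = ord)
  }))
  structure(list(conditions = conditions, n_runs = n_runs,
                 blocks_per_condition = blocks_per_condition,
                 block_duration_s = block_duration_s, fixation_s = fixation_s,
                 TR_s = TR_s, n_timepoints = as.integer(n_tr), onsets = onsets),
            class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf(
    "<block_design> %d condition(s) [%s], %d run(s) x %d blocks of %gs, %gs fixation, TR %gs (%d timepoints)\n",
    length(x$conditions), paste(x$conditions, collapse = ", "), x$n_runs,
    length(x$conditions) * x$blocks_per_condition, x$block_duration_s,
    x$fixation_s, x$TR_s, x$n_timepoints))
  invisible(x)
}
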