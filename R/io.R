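# Dataset serialization: one 4D NIfTI per run (voxels unfolded on the
# (u, v, depth-sample) grid), a voxel-metadata CSV, and design/truth JSON.

patch_grid_indices <- function(patch) {
  uu <- sort(unique(patch$u))
  vv <- sort(unique(patch$v))
  list(iu = match(patch$u, uu), iv = match(patch$v, vv),
       ik = patch$k, dims = c(length(uu), length(vv), max(patch$k)))
}

#' Write a BOLD dataset to disk
#'
#' Writes one 4D NIfTI volume per run (the sheet unfolded onto a
#' `(u, v, depth-sample)` voxel grid), a voxel metadata CSV (including the
#' stripe compartment), and design + generator-parameter JSON.
#'
#' @param dataset a `bold_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bold_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- patch_grid_indices(dataset$patch)
  nT <- dataset$design$n_timepoints
  for (r in seq_along(dataset$runs)) {
    arr <- array(0, c(g$dims, nT))
    idx <- cbind(g$iu, g$iv, g$ik)
    for (t in seq_len(nT)) {
      arr[cbind(idx, t)] <- dataset$runs[[r]][, t]
    }
    RNifti::writeNifti(RNifti::asNifti(arr),
                       file.path(dir, sprintf("run_%02d.nii.gz", r)))
  }
  meta <- dataset$patch %>%
    mutate(iu = g$iu, iv = g$iv,
           compartment = dataset$stripes$compartment[
             match(voxel_id, dataset$stripes$voxel_id)])
  readr::write_csv(meta, file.path(dir, "voxels.csv"))
  des <- dataset$design
  jsonlite::write_json(
    list(conditions = des$conditions, n_runs = des$n_runs,
         blocks_per_condition = des$blocks_per_condition,
         block_duration_s = des$block_duration_s,
         fixation_s = des$fixation_s, TR_s = des$TR_s,
         contrast = dataset$contrast,
         geometry = patch_geometry(dataset$patch),
         onsets = des$onsets),
    file.path(dir, "design.json"), auto_unbox = TRUE, digits = NA)
  tr <- dataset$truth
  tr$shared_variability <- as.data.frame(tr$shared_variability)
  jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a BOLD dataset written by [write_bold_dataset()]
#'
#' @param dir dataset directory.
#' @return a `bold_dataset` (the `planted` diagnostics of the generator are
#'   not persisted).
#' @export
read_bold_dataset <- function(dir) {
  des_js <- jsonlite::read_json(file.path(dir, "design.json"),
                                simplifyVector = TRUE)
  design <- make_block_design(des_js$conditions, des_js$n_runs,
                              des_js$blocks_per_condition,
                              des_js$block_duration_s, des_js$fixation_s,
                              des_js$TR_s)
  meta <- readr::read_csv(file.path(dir, "voxels.csv"),
                          show_col_types = FALSE)
  geometry <- des_js$geometry
  geometry$curvature <- as.list(geometry$curvature)
  patch <- meta %>%
    select(-iu, -iv, -compartment) %>%
    mutate(area = factor(area, levels = geometry$areas))
  patch <- structure(as_tibble(patch), geometry = geometry,
                     class = c("cortical_patch", class(as_tibble(patch))))
  stripes <- tibble(voxel_id = meta$voxel_id,
                    compartment = factor(meta$compartment,
                                         levels = compartment_levels))
  tr_js <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth <- ground_truth(
    base_amplitude = unlist(tr_js$base_amplitude),
    stripe_selectivity = lapply(tr_js$stripe_selectivity, unlist),
    area_selectivity = lapply(tr_js$area_selectivity, unlist),
    texture_ecc_floor = tr_js$texture_ecc_floor,
    depth_profile = lapply(tr_js$depth_profile, unlist),
    texture_depth_areas = tr_js$texture_depth_areas,
    laminar_gain = unlist(tr_js$laminar_gain),
    vein_bias = tr_js$vein_bias,
    vein_columns = tr_js$vein_columns,
    shared_variability = as_tibble(tr_js$shared_variability),
    amp_jitter_sd = tr_js$amp_jitter_sd,
    subject_sd = tr_js$subject_sd,
    noise_sd = tr_js$noise_sd,
    noise_fwhm_mm = tr_js$noise_fwhm_mm,
    seed = tr_js$seed)
  g <- patch_grid_indices(patch)
  files <- sort(list.files(dir, pattern = "^run_\\d+\\.nii", full.names = TRUE))
  runs <- lapply(files, function(f) {
    arr <- as.array(RNifti::readNifti(f))
    idx <- cbind(g$iu, g$iv, g$ik)
    vapply(seq_len(dim(arr)[4]), function(t) arr[cbind(idx, t)],
           numeric(nrow(patch)))
  })
  structure(list(runs = runs, design = design, patch = patch,
                 stripes = stripes, truth = truth,
                 contrast = des_js$contrast,
                 conditions = des_js$conditions, planted = NULL),
            class = "bold_dataset")
}
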