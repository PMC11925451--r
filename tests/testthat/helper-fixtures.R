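# Shared fixtures. Heavy cohort-level computations are cached per test run so
# several test files can assert against the same study without recomputing.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

# Small geometry for fast module tests: 240 columns per area, 6 runs.
tiny_config <- function(n_runs = 6, n_subjects = 1, seed = 0) {
  cfg <- default_config(n_subjects = n_subjects, n_runs = n_runs, seed = seed,
                        patch = patch_config(nu = 24, nv = 10))
  cfg$analysis$n_tail <- 20
  cfg
}

tiny_subject <- function() {
  cached("tiny_subject", simulate_subject(tiny_config(), 1))
}

tiny_fits <- function() {
  cached("tiny_fits", {
    sim <- tiny_subject()
    lapply(sim$datasets, fit_dataset_glm)
  })
}

# The full default study (10 subjects, all stages): backs the recovery
# assertions about stripe segmentation, laminar profiles and connectivity.
default_study <- function() {
  cached("default_study", {
    run_study(default_config(), connectivity = TRUE, reliability = TRUE,
              reliability_subjects = 1, reliability_iter = 2000)
  })
}

# A one-contrast (texture) mini cohort for connectivity calibration tests:
# simulates only the texture experiment per subject at small scale.
texture_cohort_connectivity <- function(w, n_subjects, seed, n_runs = 4,
                                        n_tail = 20) {
  cfg <- tiny_config(n_runs = n_runs, seed = seed)
  cfg$truth$shared_variability$w <- w
  res <- list()
  for (s in seq_len(n_subjects)) {
    seed_s <- laminarfmri:::derive_seed(cfg$seed, s)
    patch <- make_cortical_patch(cfg$patch)
    phase <- laminarfmri:::with_seed(laminarfmri:::derive_seed(seed_s, 3),
                                     runif(1, 0, cfg$stripe$cycle_mm))
    stripes <- make_stripe_map(patch, cfg$stripe$cycle_mm, cfg$stripe$duty,
                               phase)
    des <- make_block_design(contrast_conditions()$texture,
                             n_runs = cfg$design$n_runs,
                             blocks_per_condition = cfg$design$blocks_per_condition,
                             fixation_s = cfg$design$fixation_s)
    ds <- simulate_bold(patch, stripes, des, cfg$truth, "texture",
                        seed = laminarfmri:::derive_seed(seed_s, 3))
    fit <- fit_dataset_glm(ds)
    pm <- pathway_matrix(list(texture = fit), patch,
                         top_frac = cfg$analysis$top_frac, n_tail = n_tail,
                         cost = cfg$analysis$svm_cost)
    pm$subject <- s
    res[[s]] <- pm
  }
  dplyr::bind_rows(res)
}
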