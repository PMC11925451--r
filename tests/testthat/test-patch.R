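test_that("depth samples sit at bin midpoints on a flat cortex", {
  patch <- make_cortical_patch(patch_config(
    nu = 4, nv = 3, n_depth = 3, curvature = list(type = "flat")))
  expect_setequal(round(unique(patch$depth), 10), round(c(1, 3, 5) / 6, 10))
  expect_true(all(patch$A_inner == patch$A_outer))
  bins <- table(patch$area, laminarfmri:::cut_depth_bin(patch$depth))
  expect_true(all(bins > 0))
})

test_that("eccentricity maps linearly over its range on either axis", {
  for (ax in c("u", "v")) {
    patch <- make_cortical_patch(patch_config(nu = 10, nv = 8, ecc_axis = ax))
    expect_equal(min(patch$ecc), 0)
    expect_equal(max(patch$ecc), 18)
  }
})

test_that("curved columns get equi-volume depths via the closed form", {
  patch <- make_cortical_patch(patch_config(
    nu = 6, nv = 6, curvature = list(type = "sinusoidal", amplitude = 0.4,
                                     period_mm = 7)))
  expect_true(any(patch$A_inner != patch$A_outer))
  # stored depth is the volume fraction of the geometric sample position
  expect_equal(patch$depth,
               equivolume_alpha(patch$rho, patch$A_inner, patch$A_outer))
  # inverse consistency with the equi-volume closed form
  expect_equal(equivolume_depth(patch$depth, patch$A_inner, patch$A_outer),
               patch$rho, tolerance = 1e-12)
})

test_that("invalid patch configs are rejected", {
  expect_error(make_cortical_patch(patch_config(nu = 0)), "positive")
  expect_error(make_cortical_patch(list(curvature = list(type = "weird"))),
               "curvature")
})

test_that("stripe bands tile the cycle according to the duty fractions", {
  patch <- make_cortical_patch(patch_config(nu = 16, nv = 4))
  sm <- make_stripe_map(patch, cycle_mm = 8,
                        duty = c(0.25, 0.25, 0.25, 0.25), phase = 0)
  v2 <- patch$area == "V2"
  expect_true(all(sm$compartment[v2 & patch$u %in% c(0, 1)] == "thin"))
  expect_true(all(sm$compartment[v2 & patch$u %in% c(4, 5)] == "thick"))
  expect_true(all(sm$compartment[!v2] == "none"))
  # bands are constant along v
  comp_by_col <- tapply(as.character(sm$compartment[v2]), patch$u[v2],
                        function(x) length(unique(x)))
  expect_true(all(comp_by_col == 1))
})

test_that("stripe map is periodic in the phase and validates duty", {
  patch <- make_cortical_patch(patch_config(nu = 16, nv = 4))
  a <- make_stripe_map(patch, cycle_mm = 8, phase = 0)
  b <- make_stripe_map(patch, cycle_mm = 8, phase = 8)
  expect_equal(a$compartment, b$compartment)
  expect_error(make_stripe_map(patch, duty = c(0.3, 0.3, 0.3, 0.2)), "sum")
})

test_that("block designs tile the TR grid and counterbalance conditions", {
  expect_error(
    make_block_design(c("Chr", "Ach"), 1, 5, fixation_s = 16, TR_s = 2.4),
    "whole number of TRs")
  d <- make_block_design(c("Chr", "Ach"), 2, 5, fixation_s = 16.8, TR_s = 2.4)
  expect_equal(d$n_timepoints, 114L)
  expect_equal(nrow(d$onsets[d$onsets$run == 1, ]), 10L)
  counts <- table(d$onsets$run, d$onsets$condition)
  expect_true(all(counts == 5))
  # conditions alternate within a run, start rotates across runs
  r1 <- d$onsets$condition[d$onsets$run == 1]
  expect_true(all(r1[-1] != r1[-10]))
  expect_false(d$onsets$condition[1] ==
                 d$onsets$condition[d$onsets$run == 2][1])
  one <- make_block_design("A", 1, 1, fixation_s = 16.8, TR_s = 2.4,
                           tol_tr = 0.5)
  expect_equal(one$onsets$onset_s, 16.8)
})

test_that("planted stripe periodicity shows up in the spatial spectrum", {
  cfg <- tiny_config()
  patch <- make_cortical_patch(cfg$patch)   # nu = 24
  sm <- make_stripe_map(patch, cycle_mm = 8, phase = 0)
  amp <- planted_amplitudes(patch, sm, cfg$truth, "color",
                            sel_scatter = rep(0, nrow(patch)))
  v2 <- patch$area == "V2" & patch$k == 2
  diffmap <- tapply((amp[, 1] - amp[, 2])[v2], list(patch$u[v2], patch$v[v2]),
                    mean)
  spec <- rowMeans(apply(diffmap, 2, function(col) Mod(fft(col))^2))
  # 24 mm of u at an 8 mm cycle: power peaks at 3 cycles per window
  expect_equal(unname(which.max(spec[2:12])), 3L)
})

test_that("the generator is deterministic and validates inputs", {
  cfg <- tiny_config(n_runs = 1)
  a <- simulate_subject(cfg, 1)
  b <- simulate_subject(cfg, 1)
  expect_identical(a$datasets$color$runs, b$datasets$color$runs)
  patch <- make_cortical_patch(patch_config(nu = 4, nv = 3))
  sm <- make_stripe_map(patch)
  des <- make_block_design(c("Chr", "Ach"), 1, 5, fixation_s = 16.8)
  expect_error(simulate_bold(patch[1:10, ], sm, des, ground_truth(), "color"),
               "voxel counts")
})

test_that("noise has zero mean and the planted noiseless limit is exact", {
  cfg <- tiny_config(n_runs = 1)
  cfg$truth$base_amplitude[] <- 0
  sim <- simulate_bold(make_cortical_patch(cfg$patch),
                       make_stripe_map(make_cortical_patch(cfg$patch)),
                       make_block_design(c("Chr", "Ach"), 1, 5,
                                         fixation_s = 16.8),
                       cfg$truth, "color", seed = 4)
  x <- sim$runs[[1]]
  se <- sd(x) / sqrt(length(x) / 20)   # conservative: spatial smoothing
  expect_lt(abs(mean(x)), 3 * se)
  # marginal sd matches the configured noise level
  expect_equal(sd(x), cfg$truth$noise_sd, tolerance = 0.05)
})

test_that("block-level latents have unit variance across many blocks", {
  cfg <- tiny_config()
  cfg$patch <- patch_config(nu = 2, nv = 2)
  des <- make_block_design(c("T", "N"), 1, 260, fixation_s = 16.8)
  patch <- make_cortical_patch(cfg$patch)
  ds <- simulate_bold(patch, make_stripe_map(patch), des, cfg$truth,
                      "texture", seed = 9, drop_noise = TRUE)
  s <- as.vector(ds$planted$latents)
  expect_equal(length(s), 520L)
  expect_lt(abs(var(s) - 1), 3 * sqrt(2 / (length(s) - 1)))
})
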