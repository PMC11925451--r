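test_that("selectivity index arithmetic, antisymmetry and guards", {
  expect_equal(selectivity_index(1.5, 0.5), 0.5)
  expect_equal(selectivity_index(0.5, 1.5), -0.5)
  b <- runif(10, 0.1, 3)
  expect_equal(selectivity_index(b, b), rep(0, 10))
  a2 <- runif(10, 0.1, 2)
  expect_equal(selectivity_index(b, a2), -selectivity_index(a2, b))
  expect_true(is.na(selectivity_index(1, -1)))
  expect_true(all(abs(selectivity_index(b, a2)) <= 1))
})

test_that("profiles aggregate as SI of mean betas, not mean of SI", {
  # two-voxel hand case where the two orders disagree
  patch <- make_cortical_patch(patch_config(nu = 1, nv = 1, n_depth = 2,
                                            curvature = list(type = "flat")))
  fit <- list(betas = cbind(Chr = c(1, 3), Ach = c(0.5, 1)))
  one <- patch[patch$area == "V1", ]
  one$depth <- c(0.5, 0.5)
  prof <- laminarfmri:::roi_profile(fit, one, factor(c("m", "m")), "bin")
  expect_equal(prof$si, (2 - 0.75) / (2 + 0.75))         # 0.4545...
  expect_false(isTRUE(all.equal(prof$si, mean(c(1 / 3, 0.5)))))
})

test_that("laminar and eccentricity profiles recover planted structure", {
  sim <- tiny_subject()
  fits <- tiny_fits()
  lam <- laminar_profile(fits$color, sim$patch, "V2")
  expect_equal(as.character(lam$bin), c("deep", "middle", "superficial"))
  # compare against the planted gain-weighted ROI selectivity
  ds <- sim$datasets$color
  g <- ds$planted$gain
  a <- ds$planted$amplitudes
  mult <- ds$planted$mult
  cond <- ds$design$onsets$condition
  bins <- laminarfmri:::cut_depth_bin(sim$patch$depth)
  reg <- as.integer(ds$planted$region)
  for (b in levels(bins)) {
    i <- which(sim$patch$area == "V2" & bins == b)
    # expectation including the realized block-amplitude multipliers
    mA <- mean(mult[reg[i[1]], cond == "Chr"])
    mB <- mean(mult[reg[i[1]], cond == "Ach"])
    si_pl <- selectivity_index(mean(g[i] * a[i, 1]) * mA,
                               mean(g[i] * a[i, 2]) * mB)
    expect_lt(abs(lam$si[lam$bin == b] - si_pl), 0.02)
  }
  ecc <- eccentricity_profile(fits$texture, sim$patch, "V2")
  expect_equal(as.character(ecc$ecc_bin),
               c("central", "parafoveal", "peripheral"))
  expect_true(all(diff(ecc$si) > 0))    # planted eccentricity ramp
  # boundary rule: a voxel at exactly 3 degrees falls in the parafoveal bin
  probe <- sim$patch[1:3, ]
  probe$ecc <- c(1, 3, 7)
  probe$area <- factor("V2", levels = levels(sim$patch$area))
  pr <- eccentricity_profile(list(betas = fits$texture$betas), probe, "V2",
                             bin_edges = c(0, 3, 6, 18),
                             labels = c("c", "p", "f"))
  expect_equal(pr$n_vox, c(1L, 1L, 1L))
  expect_equal(pr$beta_a[pr$ecc_bin == "p"],
               unname(fits$texture$betas[probe$voxel_id[2], 1]))
  expect_error(eccentricity_profile(fits$texture, sim$patch, "V2",
                                    bin_edges = c(0, 6, 6.2, 18)),
               "empty")
})

test_that("stripe segmentation is antisymmetric and shift invariant", {
  sim <- tiny_subject()
  fits <- tiny_fits()
  dmap <- differential_map(fits$color, fits$disparity, sim$patch)
  est <- segment_stripes(dmap, sim$patch, z = 0.8)
  flipped <- dmap
  flipped$value <- -flipped$value
  est_f <- segment_stripes(flipped, sim$patch, z = 0.8)
  thin <- est$voxel_id[est$compartment == "thin"]
  thick <- est$voxel_id[est$compartment == "thick"]
  expect_setequal(thin, est_f$voxel_id[est_f$compartment == "thick"])
  expect_setequal(thick, est_f$voxel_id[est_f$compartment == "thin"])
  shifted <- dmap
  shifted$value <- shifted$value + 5
  expect_equal(segment_stripes(shifted, sim$patch, z = 0.8)$compartment,
               est$compartment)
  flat <- dmap
  flat$value <- rep(0, nrow(dmap)) + rnorm(nrow(dmap), sd = 1e-9)
  expect_warning(segment_stripes(flat, sim$patch, z = 10), "suprathreshold")
})

test_that("segmentation recovers the planted stripes with high Dice", {
  sim <- tiny_subject()
  fits <- tiny_fits()
  dmap <- differential_map(fits$color, fits$disparity, sim$patch)
  est <- segment_stripes(dmap, sim$patch, z = 0.8)
  d <- stripe_dice(est, sim$stripes)
  expect_true(all(d$dice > 0.85))
  # noiseless limit: near-perfect recovery in band interiors
  cfg <- tiny_config(n_runs = 2)
  cfg$truth$noise_sd <- 0
  cfg$truth$voxel_sel_sd <- 0
  cfg$truth$amp_jitter_sd <- 0
  sim0 <- simulate_subject(cfg, 1)
  f0 <- lapply(sim0$datasets[c("color", "disparity")], fit_dataset_glm,
               block_wise = FALSE)
  est0 <- segment_stripes(differential_map(f0$color, f0$disparity,
                                           sim0$patch),
                          sim0$patch, z = 1, smooth_fwhm_mm = 0)
  d0 <- stripe_dice(est0, sim0$stripes)
  expect_true(all(d0$dice >= 0.9))
})

test_that("compartment profiles order selectivity as planted", {
  sim <- tiny_subject()
  fits <- tiny_fits()
  dmap <- differential_map(fits$color, fits$disparity, sim$patch)
  est <- segment_stripes(dmap, sim$patch, z = 0.8)
  cp_c <- compartment_profile(fits$color, sim$patch, est)
  expect_equal(as.character(cp_c$compartment[which.max(cp_c$si)]), "thin")
  cp_d <- compartment_profile(fits$disparity, sim$patch, est)
  expect_equal(as.character(cp_d$compartment[which.max(cp_d$si)]), "thick")
  # stripe definition is independent of the texture contrast being profiled
  cp_t <- compartment_profile(fits$texture, sim$patch, est)
  expect_lt(diff(range(cp_t$si)), 0.05)
})

test_that("compartment mean SI ordering is stable across thresholds", {
  sim <- tiny_subject()
  fits <- tiny_fits()
  dmap <- differential_map(fits$color, fits$disparity, sim$patch)
  evaluated <- 0
  for (z in c(0.5, 1, 1.5, 2)) {
    est <- segment_stripes(dmap, sim$patch, z = z)
    cp_c <- tryCatch(compartment_profile(fits$color, sim$patch, est),
                     error = function(e) NULL)
    # at very high thresholds a small map may leave a compartment empty
    if (is.null(cp_c)) next
    cp_d <- compartment_profile(fits$disparity, sim$patch, est)
    expect_equal(as.character(cp_c$compartment[which.max(cp_c$si)]), "thin",
                 label = paste("color at z =", z))
    expect_equal(as.character(cp_d$compartment[which.max(cp_d$si)]), "thick",
                 label = paste("disparity at z =", z))
    evaluated <- evaluated + 1
  }
  expect_gte(evaluated, 3)
})
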