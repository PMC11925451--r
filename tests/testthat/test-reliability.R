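make_null_object <- function(samples) {
  structure(list(samples = samples, n_iter = length(samples), seed = 0),
            class = "null_distribution")
}

test_that("pattern correlation basics and guards", {
  m <- tibble::tibble(column_id = 1:50, value = rnorm(50))
  m2 <- m
  m2$value <- -m$value
  expect_equal(pattern_correlation(m, m), 1)
  expect_equal(pattern_correlation(m, m2), -1)
  ind <- m
  ind$value <- rnorm(50)
  expect_lt(abs(pattern_correlation(m, ind)), 3 / sqrt(50))
  flat <- m
  flat$value <- rep(1, 50)
  expect_error(pattern_correlation(m, flat), "zero variance")
  expect_error(pattern_correlation(m[1:2, ], m[1:2, ]), ">= 3")
})

test_that("FWE p uses the add-one one-sided rule", {
  null <- make_null_object(seq(-0.5, 0.5, length.out = 1000))
  expect_equal(fwe_corrected_p(0.6, null), 1 / 1001)
  expect_equal(fwe_corrected_p(median(null$samples), null), 0.5,
               tolerance = 0.01)
  expect_gt(fwe_corrected_p(-1, null), 0.999)
  # the alpha-critical value is exceeded by the nominal fraction of nulls
  expect_equal(mean(null$samples > critical_value(null, 0.05)), 0.05,
               tolerance = 0.002)
})

test_that("residual ACF estimation recovers the generator smoothness", {
  cfg <- tiny_config()
  patch <- make_cortical_patch(cfg$patch)
  # pure smoothed-noise "residuals" straight from the noise model
  noise <- laminarfmri:::with_seed(5, do.call(rbind, lapply(1:4, function(a) {
    laminarfmri:::smooth_area_noise(24, 10, 3, 80, 1.5, 2, 1)
  })))
  acf <- estimate_acf(noise, patch, max_timepoints = 80)
  sigma <- laminarfmri:::fwhm_to_sigma(2)
  expect_gt(acf$a, 0.8)                       # Gaussian component dominates
  expect_equal(acf$b, sigma * sqrt(2), tolerance = 0.15)
  expect_false(acf$degenerate)
  expect_equal(acf$curve$acf[acf$curve$dist == 0], 1)
  # white-noise residuals flag a degenerate fit
  white <- matrix(rnorm(nrow(patch) * 60), ncol = 60)
  wa <- tryCatch(estimate_acf(white, patch, max_timepoints = 60),
                 acf_fit_error = function(e) e)
  if (inherits(wa, "acf_model")) {
    expect_true(wa$degenerate)
  } else {
    expect_s3_class(wa$curve, "tbl_df")      # error carries the curve
  }
})

test_that("null correlations are centred and widen with ACF scale", {
  acf1 <- structure(list(a = 1, b = 1, c = 1, spacing_mm = 1),
                    class = "acf_model")
  # a smooth reference map (drawn from the b = 2 null model): with a smooth
  # reference, wider null ACFs mean fewer effective degrees of freedom
  acf_ref <- acf1
  acf_ref$b <- 2
  ref_field <- laminarfmri:::with_seed(3,
    laminarfmri:::make_null_sampler(acf_ref, 40, 30, 1)(1))
  ref <- tidyr::expand_grid(v = 1:30, u = 1:40) %>%
    dplyr::mutate(column_id = dplyr::row_number(),
                  value = as.vector(ref_field))
  crits <- sapply(c(1, 2, 4), function(b) {
    acf <- acf1
    acf$b <- b
    null <- simulate_null_correlations(acf, ref, n_iter = 2000, seed = 7)
    expect_lt(abs(mean(null$samples)),
              3 * sd(null$samples) / sqrt(null$n_iter))
    critical_value(null, 0.05)
  })
  expect_true(all(diff(crits) > 0))
})

test_that("planted shared structure is detected; unrelated maps are not", {
  cfg <- tiny_config(n_runs = 4)
  sim <- simulate_subject(cfg, 1)
  rel <- reliability_analysis(sim, cfg, n_iter = 500)
  expect_true(all(rel$r > rel$critical))
  expect_true(all(rel$p < 0.01))
  # a second subject's map (different stripes and tuning) is unrelated
  sim2 <- simulate_subject(cfg, 2)
  f1 <- fit_dataset_glm(sim$datasets$color, block_wise = FALSE)
  f2 <- fit_dataset_glm(sim2$datasets$color, block_wise = FALSE)
  acf <- estimate_acf(f1$residuals, sim$patch)
  tr <- test_retest(session_map(f1, sim$patch), session_map(f2, sim2$patch),
                    acf, n_iter = 500, seed = 11)
  expect_gt(tr$p, 0.05)
})

test_that("the FWE procedure is calibrated for independent sessions", {
  acf <- structure(list(a = 1, b = 1.2, c = 1, spacing_mm = 1),
                   class = "acf_model")
  cal <- reliability_calibration(acf, 30, 24, n_repeats = 400, n_iter = 400,
                                 n_pools = 8, seed = 13)
  ci <- 2.576 * sqrt(0.05 * 0.95 / 400)
  expect_gt(cal$rate, 0.05 - ci)
  expect_lt(cal$rate, 0.05 + ci)
})
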