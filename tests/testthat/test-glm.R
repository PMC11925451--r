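test_that("canonical block response has the gamma peak, causality and plateau", {
  expect_equal(laminarfmri:::hrf_gamma(5), 1)
  r <- canonical_block_response(24, 0.5)
  times <- attr(r, "times")
  expect_equal(r[times == 0], 0)
  plateau <- r[times >= 20 & times <= 24]
  expect_equal(max(abs(plateau - 1)), 0, tolerance = 1e-3)
  expect_error(canonical_block_response(0, 2.4), "block_duration_s")
})

test_that("design matrices have the documented regressor layout", {
  des <- make_block_design(c("Chr", "Ach"), 1, 5, fixation_s = 16.8)
  X1 <- build_design_matrix(des, 1, "per_condition", drift_order = 1)
  expect_equal(ncol(X1$matrix), 4L)       # 2 conditions + intercept + drift
  Xb <- build_design_matrix(des, 1, "per_block", drift_order = 2)
  expect_equal(length(Xb$condition_columns), 10L)
  X0 <- build_design_matrix(des, 1, "per_condition", drift_order = 0)
  expect_equal(X0$regressor_names, c("Chr", "Ach", "intercept"))
  bad <- des
  bad$onsets$onset_s[2] <- bad$onsets$onset_s[1] + 1
  expect_error(build_design_matrix(bad, 1), "overlapping")
})

test_that("OLS solves a hand-checkable single-regressor problem", {
  X <- structure(list(
    matrix = cbind(x = c(1, 1, 1)), regressor_names = "x",
    condition_columns = c(x = 1L), mode = "per_condition",
    block_info = NULL, drift_order = 0), class = "design_matrix")
  fit <- fit_glm(matrix(c(1, 2, 3), nrow = 1), X)
  expect_equal(unname(fit$betas[1, 1]), 2)
})

test_that("rank-deficient designs are rejected with the offending column", {
  X <- structure(list(
    matrix = cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8)),
    regressor_names = c("a", "b"), condition_columns = c(a = 1L, b = 2L),
    mode = "per_condition", block_info = NULL, drift_order = 0),
    class = "design_matrix")
  expect_error(fit_glm(matrix(rnorm(4), 1), X), "collinear.*b")
})

test_that("fit_glm matches lm() coefficient-by-coefficient", {
  set.seed(11)
  des <- make_block_design(c("Chr", "Ach"), 1, 5, fixation_s = 16.8)
  X <- build_design_matrix(des, 1, "per_condition", drift_order = 2)
  y <- matrix(rnorm(3 * des$n_timepoints), nrow = 3)
  fit <- fit_glm(y, X)
  ref <- lm(t(y) ~ X$matrix - 1)
  expect_equal(unname(fit$betas), unname(t(coef(ref))[, 1:2]),
               tolerance = 1e-10)
  sm <- summary(lm(y[1, ] ~ X$matrix - 1))
  expect_equal(unname(fit$t[1, ]), unname(sm$coefficients[1:2, "t value"]),
               tolerance = 1e-8)
  # partial F for one regressor equals its squared t
  df <- as.data.frame(X$matrix)
  names(df) <- paste0("x", seq_along(df))
  df$y <- y[1, ]
  m_full <- lm(y ~ . - 1, data = df)
  m_red <- lm(y ~ . - 1 - x1, data = df)
  expect_equal(unname(fit$t[1, 1]^2), anova(m_red, m_full)$F[2],
               tolerance = 1e-8)
})

test_that("noiseless simulated data recover planted betas exactly", {
  cfg <- tiny_config(n_runs = 2)
  cfg$truth$amp_jitter_sd <- 0
  cfg$truth$noise_sd <- 0
  sim <- simulate_subject(cfg, 1)
  ds <- sim$datasets$color
  fit <- fit_dataset_glm(ds, drift_order = 2, block_wise = TRUE)
  planted <- ds$planted$amplitudes * ds$planted$gain
  expect_equal(unname(fit$betas), unname(planted), tolerance = 1e-10)
  X <- build_design_matrix(ds$design, 1, "per_condition", 2)
  expect_lt(max(abs(t(X$matrix) %*% t(fit$residuals))),
            1e-8 * max(abs(ds$runs[[1]])))
  # per-condition betas equal the mean of that condition's per-block betas
  Xb <- build_design_matrix(ds$design, 1, "per_block", drift_order = 0)
  bfit <- fit_glm(ds$runs[[1]], Xb)
  for (cn in ds$conditions) {
    cols <- which(Xb$block_info$condition == cn)
    expect_equal(unname(rowMeans(bfit$betas[, cols])),
                 unname(planted[, cn]), tolerance = 1e-8)
  }
})

test_that("pure-noise betas are unbiased", {
  set.seed(21)
  des <- make_block_design(c("Chr", "Ach"), 1, 5, fixation_s = 16.8)
  X <- build_design_matrix(des, 1, "per_condition", 2)
  y <- matrix(rnorm(1000 * des$n_timepoints), nrow = 1000)
  fit <- fit_glm(y, X)
  se <- sd(fit$betas[, 1]) / sqrt(1000)
  expect_lt(abs(mean(fit$betas[, 1])), 3 * se)
})

test_that("dataset fits concatenate block patterns across runs in order", {
  fit <- tiny_fits()$color
  des <- tiny_subject()$datasets$color$design
  expect_equal(ncol(fit$block_t), des$n_runs * 10L)
  expect_equal(fit$block_info$run,
               rep(seq_len(des$n_runs), each = 10L))
  expect_equal(fit$dof, des$n_timepoints - 5L)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(fit$betas) * 2)
  expect_equal(glance(fit)$n_blocks, ncol(fit$block_t))
})
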