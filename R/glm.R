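# Block-design GLM: canonical block response, design matrices, OLS fits with
# per-condition betas and per-block t patterns.

# Single-gamma impulse response h(t) = (t/p)^q exp(q - q t/p), peak h(p) = 1.
hrf_gamma <- function(t, p = 5, q = 4) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / p)^q * exp(q - q * t[pos] / p)
  out
}

# Cumulative impulse response normalized to 1 at infinity. h is proportional
# to a gamma density with shape q+1 and rate q/p, so the running integral is
# an incomplete gamma function in closed form.
hrf_gamma_cum <- function(t, p = 5, q = 4) {
  stats::pgamma(pmax(t, 0), shape = q + 1, rate = q / p)
}

#' Canonical block response regressor
#'
#' A boxcar of `block_duration_s` seconds convolved with a single-gamma
#' hemodynamic impulse response (peak at `p` = 5 s, shape `q` = 4), normalized
#' so the plateau of a sustained block equals 1. The convolution is evaluated
#' in closed form via the incomplete gamma function, so values are exact at
#' any sample times.
#'
#' @param block_duration_s block duration in seconds (> 0).
#' @param TR_s sampling interval in seconds.
#' @param duration_s total length of the returned regressor; defaults to the
#'   block plus 32 s of tail.
#' @param p,q impulse-response peak time (s) and shape parameter.
#' @return numeric vector of regressor values at frame times
#'   `0, TR_s, 2 TR_s, ...` (stored in the `"times"` attribute).
#' @examples
#' r <- canonical_block_response(24, 2.4)
#' max(r) # plateau ~ 1
#' @export
canonical_block_response <- function(block_duration_s, TR_s,
                                     duration_s = block_duration_s + 32,
                                     p = 5, q = 4) {
  check_number(block_duration_s, "block_duration_s", lower = 1e-9)
  check_number(TR_s, "TR_s", lower = 1e-9)
  times <- seq(0, duration_s, by = TR_s)
  vals <- hrf_gamma_cum(times, p, q) - hrf_gamma_cum(times - block_duration_s, p, q)
  structure(vals, times = times)
}

# Legendre polynomials P_0..P_order on x in [-1, 1] (Bonnet recurrence).
legendre_basis <- function(n_timepoints, order) {
  x <- seq(-1, 1, length.out = n_timepoints)
  P <- matrix(0, n_timepoints, order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2) {
    for (k in 2:order) {
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
    }
  }
  P
}

#' Build a run-wise GLM design matrix
#'
#' One canonical-block-response regressor per condition (`per_condition`
#' mode) or per stimulus block (`per_block` mode, used for block-wise t-score
#' patterns), plus an intercept and Legendre polynomial drift regressors.
#'
#' @param design a [make_block_design()] object.
#' @param run_index which run's onsets to use.
#' @param mode `"per_condition"` or `"per_block"`.
#' @param drift_order highest Legendre polynomial order for slow drift
#'   (default 2; 0 keeps the intercept only).
#' @param p,q impulse-response parameters, see [canonical_block_response()].
#' @return a `design_matrix` list: `matrix` (timepoint x regressor),
#'   `regressor_names`, `condition_columns` (named indices of the stimulus
#'   columns), `mode`, and for `per_block` mode a `block_info` tibble.
#' @export
build_design_matrix <- function(design, run_index = 1,
                                mode = c("per_condition", "per_block"),
                                drift_order = 2, p = 5, q = 4) {
  mode <- match.arg(mode)
  if (drift_order < 0) stop_input("`drift_order` must be >= 0")
  ons <- design$onsets[design$onsets$run == run_index, ]
  if (nrow(ons) == 0) stop_input("no onsets for run ", run_index)
  if (any(diff(sort(ons$onset_s)) < design$block_duration_s - 1e-9)) {
    stop_input("overlapping blocks in run ", run_index)
  }
  nT <- design$n_timepoints
  t_frames <- (seq_len(nT) - 1) * design$TR_s
  block_reg <- function(onset) {
    hrf_gamma_cum(t_frames - onset, p, q) -
      hrf_gamma_cum(t_frames - onset - design$block_duration_s, p, q)
  }
  B <- vapply(ons$onset_s, block_reg, numeric(nT))
  if (mode == "per_condition") {
    conds <- design$conditions
    S <- vapply(conds, function(cn) {
      rowSums(B[, ons$condition == cn, drop = FALSE])
    }, numeric(nT))
    stim_names <- conds
    block_info <- NULL
  } else {
    S <- B
    stim_names <- sprintf("block_%02d", ons$block)
    block_info <- tibble(run = ons$run, block = ons$block,
                         condition = ons$condition)
  }
  drift <- legendre_basis(nT, drift_order)
  drift_names <- c("intercept", if (drift_order >= 1)
    paste0("drift_", seq_len(drift_order)))
  X <- cbind(S, drift)
  colnames(X) <- c(stim_names, drift_names)
  structure(list(matrix = X, regressor_names = colnames(X),
                 condition_columns = setNames(seq_along(stim_names), stim_names),
                 mode = mode, drift_order = drift_order,
                 block_info = block_info, run_index = run_index),
            class = "design_matrix")
}

#' Fit an ordinary-least-squares GLM to one run
#'
#' Voxel-wise OLS: `beta = (X'X)^-1 X'y`, with t statistics
#' `t_j = beta_j / (s sqrt((X'X)^-1_jj))` where `s^2 = RSS / dof`. Stimulus
#' regressors are unit-plateau block responses, so betas are in the data's
#' percent-signal-change units.
#'
#' @param run_data voxel x timepoint matrix (percent signal change).
#' @param X a `design_matrix` from [build_design_matrix()].
#' @return a `bold_glm` list: `betas` and `t` (voxel x stimulus-regressor
#'   matrices), `residuals` (voxel x timepoint), `dof`, plus the design
#'   metadata. In `per_block` mode the `t` matrix holds the per-block
#'   activation patterns.
#' @export
fit_glm <- function(run_data, X) {
  M <- X$matrix
  if (ncol(run_data) != nrow(M)) {
    stop_input(sprintf("run_data has %d timepoints but the design has %d",
                       ncol(run_data), nrow(M)))
  }
  qrX <- qr(M)
  if (qrX$rank < ncol(M)) {
    bad <- colnames(M)[qrX$pivot[(qrX$rank + 1):ncol(M)]]
    stop_input("design matrix is rank deficient; collinear column(s): ",
               paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qrX, t(run_data))            # regressor x voxel
  fitted <- M %*% coefs
  res <- t(run_data) - fitted                   # timepoint x voxel
  dof <- nrow(M) - qrX$rank
  sigma2 <- colSums(res^2) / dof
  XtXinv_diag <- diag(chol2inv(qr.R(qrX)))[order(qrX$pivot)]
  stim <- X$condition_columns
  betas <- t(coefs[stim, , drop = FALSE])
  se <- sqrt(outer(sigma2, XtXinv_diag[stim]))
  tmat <- betas / se
  tmat[sigma2 <= 0, ] <- NA_real_
  colnames(betas) <- colnames(tmat) <- names(stim)
  structure(list(betas = betas, t = tmat, residuals = t(res), dof = dof,
                 mode = X$mode, block_info = X$block_info,
                 regressor_names = X$regressor_names),
            class = "bold_glm")
}

#' Fit GLMs across all runs of a dataset
#'
#' Per-condition betas are estimated run-wise and averaged across runs;
#' block-wise activation patterns (t scores, one regressor per block within a
#' single run model) are concatenated across runs in block order. Residuals of
#' the first run's per-condition model are kept for spatial-autocorrelation
#' estimation.
#'
#' @param dataset a `bold_dataset` from [simulate_bold()] or [read_bold_dataset()].
#' @param drift_order Legendre drift order per run.
#' @param block_wise also fit the per-block models (default TRUE).
#' @return a `dataset_glm` list: `betas` (voxel x condition), `block_t`
#'   (voxel x block), `block_info` tibble, `residuals` (first run), `dof`,
#'   `conditions`.
#' @export
fit_dataset_glm <- function(dataset, drift_order = 2, block_wise = TRUE) {
  des <- dataset$design
  beta_sum <- NULL
  block_t <- list()
  block_info <- list()
  residuals <- NULL
  dof <- NA_integer_
  for (r in seq_len(des$n_runs)) {
    Xc <- build_design_matrix(des, r, "per_condition", drift_order)
    fit <- fit_glm(dataset$runs[[r]], Xc)
    beta_sum <- if (is.null(beta_sum)) fit$betas else beta_sum + fit$betas
    if (r == 1) {
      residuals <- fit$residuals
      dof <- fit$dof
    }
    if (block_wise) {
      Xb <- build_design_matrix(des, r, "per_block", drift_order)
      bfit <- fit_glm(dataset$runs[[r]], Xb)
      block_t[[r]] <- bfit$t
      block_info[[r]] <- bfit$block_info
    }
  }
  structure(list(
    betas = beta_sum / des$n_runs,
    conditions = des$conditions,
    block_t = if (block_wise) do.call(cbind, block_t),
    block_info = if (block_wise) dplyr::bind_rows(block_info),
    residuals = residuals, dof = dof, drift_order = drift_order),
    class = "dataset_glm")
}
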