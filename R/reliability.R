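# Inter-session columnar pattern reliability: Pearson pattern correlation
# with a Monte-Carlo family-wise-error null of spatially autocorrelated maps.

#' Column-level condition-difference map for one session
#'
#' The session's columnar activation pattern: the difference of the two
#' condition betas (e.g. chromatic minus achromatic), averaged across the
#' depth samples of each column of an area.
#'
#' @param fit a `dataset_glm`.
#' @param patch the `cortical_patch`.
#' @param area area label (default `"V2"`).
#' @return tibble with `column_id`, `u`, `v`, `value`.
#' @export
session_map <- function(fit, patch, area = "V2") {
  roi <- patch[patch$area == area, ]
  d <- fit$betas[roi$voxel_id, 1] - fit$betas[roi$voxel_id, 2]
  tibble(column_id = roi$column_id, u = roi$u, v = roi$v, value = d) %>%
    group_by(column_id, u, v) %>%
    summarise(value = mean(value), .groups = "drop")
}

#' Pearson pattern correlation between two maps
#'
#' @param map1,map2 tibbles with `column_id` and `value` (joined on
#'   `column_id`).
#' @return Pearson correlation over the shared columns.
#' @export
pattern_correlation <- function(map1, map2) {
  j <- dplyr::inner_join(map1, map2, by = "column_id",
                         suffix = c("_1", "_2"))
  if (nrow(j) < 3) stop_input("need >= 3 shared columns")
  if (any(!is.finite(j$value_1)) || any(!is.finite(j$value_2))) {
    stop_input("non-finite map values")
  }
  if (sd(j$value_1) == 0 || sd(j$value_2) == 0) {
    stop_input("zero variance in a map: correlation undefined")
  }
  cor(j$value_1, j$value_2)
}

acf_mixture <- function(d, a, b, cc) {
  a * exp(-d^2 / (2 * b^2)) + (1 - a) * exp(-d / cc)
}

#' Estimate the spatial autocorrelation of GLM residuals
#'
#' Computes the empirical spatial autocorrelation of residual timeseries on
#' the `(u, v)` grid of an area (2D sample autocorrelation per depth slice,
#' averaged, collapsed radially) and fits the mixture model
#' `ACF(r) = a exp(-r^2 / (2 b^2)) + (1 - a) exp(-r / c)` by least squares.
#'
#' @param residuals voxel x timepoint matrix of GLM residuals.
#' @param patch the `cortical_patch` the residuals live on.
#' @param area area whose grid to use (default `"V2"`).
#' @param max_lag_mm largest spatial lag entering the fit.
#' @param max_timepoints number of (evenly spaced) timepoints to average.
#' @return an `acf_model` list: `a`, `b`, `c`, `curve` (tibble `dist`,
#'   `acf`), `degenerate` (TRUE when no spatial correlation beyond lag 0 was
#'   detected). A failed fit raises an error carrying the empirical curve.
#' @export
estimate_acf <- function(residuals, patch, area = "V2", max_lag_mm = 10,
                         max_timepoints = 50) {
  if (ncol(residuals) < 2) stop_input("need >= 2 timepoints")
  geom <- patch_geometry(patch)
  roi <- patch[patch$area == area, ]
  spacing <- geom$spacing_mm
  nu <- geom$nu
  nv <- geom$nv
  tp <- unique(round(seq(1, ncol(residuals), length.out = max_timepoints)))
  # mean 2D autocovariance over depth slices and timepoints (zero-padded FFT)
  P <- 2 * nu
  Q <- 2 * nv
  acc <- matrix(0, P, Q)
  nsl <- 0
  ones <- matrix(0, P, Q)
  ones[1:nu, 1:nv] <- 1
  cnt <- Re(fft_2d(Mod(fft_2d(ones))^2, inverse = TRUE)) / (P * Q)
  for (k in seq_len(geom$n_depth)) {
    rows <- roi$voxel_id[roi$k == k]
    for (t in tp) {
      x <- matrix(residuals[rows, t], nu, nv)
      x <- x - mean(x)
      pad <- matrix(0, P, Q)
      pad[1:nu, 1:nv] <- x
      acc <- acc + Re(fft_2d(Mod(fft_2d(pad))^2, inverse = TRUE)) / (P * Q)
      nsl <- nsl + 1
    }
  }
  covimg <- acc / nsl / pmax(cnt, 1)
  du <- c(0:(nu - 1), -(nu:1))[1:P] * spacing
  dv <- c(0:(nv - 1), -(nv:1))[1:Q] * spacing
  dist <- sqrt(outer(du^2, dv^2, "+"))
  keep <- dist <= max_lag_mm
  curve <- tibble(dist = round(dist[keep] / (spacing / 2)) * (spacing / 2),
                  cov = covimg[keep]) %>%
    group_by(dist) %>%
    summarise(acf = mean(cov), .groups = "drop") %>%
    mutate(acf = acf / acf[dist == 0])
  degenerate <- all(abs(curve$acf[curve$dist > 0]) < 0.05)
  # Raw Levenberg-Marquardt on the residual function: the mixture is often
  # best fit at a parameter boundary (pure-Gaussian fields push a -> 1),
  # where nls-object construction fails on the vanishing gradient.
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(a = 0.5, b = 2, cc = 2),
      lower = c(0, 1e-3, 0.05), upper = c(1, 50, 50),
      fn = function(p) {
        curve$acf - acf_mixture(curve$dist, p[1], p[2], p[3])
      },
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error") || !(fit$info %in% 1:4)) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit) else fit$message
    cond <- structure(
      class = c("acf_fit_error", "error", "condition"),
      list(message = paste0("ACF fit failed: ", msg), call = NULL,
           curve = curve))
    stop(cond)
  }
  cf <- fit$par
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 c = unname(cf["cc"]), curve = curve,
                 degenerate = degenerate, spacing_mm = spacing),
            class = "acf_model")
}

# Batched 2D FFT helpers: arr is (n1, n2) or (n1, n2, B).
fft_2d <- function(arr, inverse = FALSE) {
  d <- dim(arr)
  if (length(d) == 2) d <- c(d, 1L)
  a <- array(arr, d)
  a <- array(stats::mvfft(matrix(a, d[1]), inverse = inverse), d)
  a <- aperm(a, c(2, 1, 3))
  a <- array(stats::mvfft(matrix(a, d[2]), inverse = inverse),
             c(d[2], d[1], d[3]))
  a <- aperm(a, c(2, 1, 3))
  if (length(dim(arr)) == 2) a <- a[, , 1]
  a
}

# Sampler of smooth stationary Gaussian null fields with a given ACF:
# spectral filtering of white noise on a padded torus grid (padding past the
# ACF range so wrap-around correlation is negligible). Each complex FFT pass
# yields two independent real fields (real and imaginary parts).
make_null_sampler <- function(acf, nu, nv, spacing) {
  pad <- ceiling(4 * max(acf$b, acf$c, 1) / spacing)
  P <- stats::nextn(nu + pad, c(2, 3, 5))
  Q <- stats::nextn(nv + pad, c(2, 3, 5))
  du <- pmin(0:(P - 1), P - (0:(P - 1))) * spacing
  dv <- pmin(0:(Q - 1), Q - (0:(Q - 1))) * spacing
  dist <- sqrt(outer(du^2, dv^2, "+"))
  C <- acf_mixture(dist, acf$a, acf$b, acf$c)
  filt <- sqrt(pmax(Re(fft_2d(C)), 0))
  function(n) {
    m <- ceiling(n / 2)
    W <- array(complex(real = rnorm(P * Q * m),
                       imaginary = rnorm(P * Q * m)), c(P, Q, m))
    X <- fft_2d(fft_2d(W) * as.vector(filt), inverse = TRUE) / (P * Q)
    X <- X[1:nu, 1:nv, , drop = FALSE]
    out <- array(0, c(nu, nv, 2 * m))
    out[, , seq(1, 2 * m, by = 2)] <- Re(X)
    out[, , seq(2, 2 * m, by = 2)] <- Im(X)
    out[, , seq_len(n), drop = FALSE]
  }
}

#' Monte-Carlo null distribution of inter-session pattern correlations
#'
#' Holds the first-session reference map fixed and repeatedly simulates a
#' second-session map as a smooth Gaussian field with the fitted residual
#' ACF, correlating each simulated map with the reference over the ROI
#' columns. The resulting null distribution controls the family-wise error
#' of the observed inter-session correlation.
#'
#' @param acf an `acf_model` from [estimate_acf()].
#' @param reference the session-1 map (tibble `column_id`, `u`, `v`,
#'   `value`); its columns define the ROI.
#' @param n_iter number of simulated maps (>= 100).
#' @param seed RNG seed.
#' @param batch simulated maps per FFT batch.
#' @return a `null_distribution` list: `samples`, `n_iter`, `seed`.
#' @export
simulate_null_correlations <- function(acf, reference, n_iter = 10000,
                                       seed = 1, batch = 250) {
  if (n_iter < 100) stop_input("`n_iter` must be >= 100")
  uu <- sort(unique(reference$u))
  vv <- sort(unique(reference$v))
  nu <- length(uu)
  nv <- length(vv)
  cell <- cbind(match(reference$u, uu), match(reference$v, vv))
  flat <- cell[, 1] + (cell[, 2] - 1) * nu
  ref <- reference$value - mean(reference$value)
  ref_ss <- sqrt(sum(ref^2))
  sampler <- make_null_sampler(acf, nu, nv, acf$spacing_mm)
  samples <- numeric(n_iter)
  done <- 0
  with_seed(derive_seed(seed, 17), {
    while (done < n_iter) {
      b <- min(batch, n_iter - done)
      X <- sampler(b)
      vals <- matrix(X, nu * nv, b)[flat, , drop = FALSE]
      vals <- sweep(vals, 2, colMeans(vals))
      samples[done + seq_len(b)] <-
        as.vector(crossprod(vals, ref)) /
        (sqrt(colSums(vals^2)) * ref_ss)
      done <- done + b
    }
  })
  structure(list(samples = samples, n_iter = n_iter, seed = seed),
            class = "null_distribution")
}

#' Critical value of a null distribution
#' @param null a `null_distribution`.
#' @param alpha one-sided significance level.
#' @return the `1 - alpha` quantile of the null samples.
#' @export
critical_value <- function(null, alpha = 0.05) {
  unname(quantile(null$samples, 1 - alpha, type = 1))
}

#' FWE-corrected p value for an observed pattern correlation
#'
#' One-sided (positive reliability is the hypothesis), with add-one
#' smoothing: `p = (1 + #(null >= observed)) / (1 + n_iter)`.
#'
#' @param observed_r observed inter-session correlation.
#' @param null a `null_distribution`.
#' @return p value.
#' @export
fwe_corrected_p <- function(observed_r, null) {
  if (length(null$samples) == 0) stop_input("empty null distribution")
  (1 + sum(null$samples >= observed_r)) / (1 + null$n_iter)
}

#' Test-retest reliability of a columnar map pair
#'
#' Convenience wrapper: observed pattern correlation, Monte-Carlo null from
#' the session-1 residual ACF, critical value and FWE-corrected p.
#'
#' @param map1,map2 session maps from [session_map()].
#' @param acf an `acf_model` estimated from session 1 residuals.
#' @param n_iter Monte-Carlo iterations.
#' @param alpha significance level for the critical value.
#' @param seed RNG seed.
#' @return list with `r`, `critical`, `p`, `null`.
#' @export
test_retest <- function(map1, map2, acf, n_iter = 10000, alpha = 0.05,
                        seed = 1) {
  r <- pattern_correlation(map1, map2)
  null <- simulate_null_correlations(acf, map1, n_iter = n_iter, seed = seed)
  list(r = r, critical = critical_value(null, alpha),
       p = fwe_corrected_p(r, null), null = null)
}

#' Type-I calibration of the FWE-corrected reliability test
#'
#' Repeatedly draws truly independent "session" map pairs from the fitted
#' ACF's null model, computes the FWE-corrected p of each pair against a
#' Monte-Carlo null of `n_iter` correlations, and returns the rate of
#' `p < alpha`. For efficiency the repeats are grouped into `n_pools` groups
#' sharing one null sample each; conditionally on a pool the p value of an
#' independent pair is exactly uniform, so the hit rate remains calibrated.
#'
#' @param acf an `acf_model`.
#' @param nu,nv grid dimensions of the simulated maps.
#' @param n_repeats number of independent session pairs.
#' @param n_iter null correlations per repeat.
#' @param n_pools number of independent null pools.
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return list with `rate`, `hits`, `n_repeats`.
#' @export
reliability_calibration <- function(acf, nu, nv, n_repeats = 1000,
                                    n_iter = 1000, n_pools = 10,
                                    alpha = 0.05, seed = 1) {
  sampler <- make_null_sampler(acf, nu, nv, acf$spacing_mm)
  per_pool <- ceiling(n_repeats / n_pools)
  hits <- 0
  done <- 0
  corr_cols <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    M / rep(sqrt(colSums(M^2)), each = nrow(M))
  }
  with_seed(derive_seed(seed, 23), {
    for (pool in seq_len(n_pools)) {
      b <- min(per_pool, n_repeats - done)
      if (b <= 0) break
      null_maps <- corr_cols(matrix(sampler(n_iter), nu * nv, n_iter))
      refs <- corr_cols(matrix(sampler(b), nu * nv, b))
      obs <- corr_cols(matrix(sampler(b), nu * nv, b))
      r_obs <- colSums(refs * obs)
      r_null <- crossprod(null_maps, refs)        # n_iter x b
      exceed <- colSums(r_null >= rep(r_obs, each = n_iter))
      p <- (1 + exceed) / (1 + n_iter)
      hits <- hits + sum(p < alpha)
      done <- done + b
    }
  })
  list(rate = hits / done, hits = hits, n_repeats = done)
}
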