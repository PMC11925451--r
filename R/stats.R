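# Group statistics: repeated-measures ANOVA, paired t, bootstrap stripe null,
# Fisher z, Benjamini-Hochberg FDR.

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject decomposition for a complete subject x condition
#' table: `F = MS_condition / MS_(condition x subject)` with `k - 1` and
#' `(k - 1)(n - 1)` degrees of freedom. Degenerate tables (zero interaction
#' mean square) are flagged rather than returning an infinite F.
#'
#' @param data numeric matrix or data frame, subjects in rows, conditions in
#'   columns; no missing cells.
#' @return an `rm_anova` list: `F`, `df_effect`, `df_error`, `p`,
#'   `degenerate`.
#' @examples
#' m <- cbind(a = c(1, 2, 3, 2), b = c(2, 2, 4, 3), c = c(2, 3, 5, 3))
#' rm_anova_oneway(m)$F
#' @export
rm_anova_oneway <- function(data) {
  m <- as.matrix(data)
  if (anyNA(m)) stop_input("missing cells are not supported (no imputation)")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) stop_input("need >= 2 subjects and >= 2 conditions")
  grand <- mean(m)
  cond_means <- colMeans(m)
  subj_means <- rowMeans(m)
  ss_cond <- n * sum((cond_means - grand)^2)
  resid <- m - outer(subj_means, rep(1, k)) -
    outer(rep(1, n), cond_means) + grand
  ss_err <- sum(resid^2)
  df_effect <- k - 1
  df_error <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df_effect
  ms_err <- ss_err / df_error
  degenerate <- ms_err <= 1e-12 * ms_cond
  Fval <- if (degenerate && ms_cond > 0) Inf else if (ms_err == 0) 0
    else ms_cond / ms_err
  p <- if (is.infinite(Fval)) 0 else pf(Fval, df_effect, df_error,
                                        lower.tail = FALSE)
  structure(list(F = Fval, df_effect = df_effect, df_error = df_error,
                 p = p, degenerate = degenerate),
            class = "rm_anova")
}

#' Paired t test
#'
#' Standard two-sided paired t; errors on zero-variance differences.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop_input("`x` and `y` must be paired vectors of equal length >= 2")
  }
  d <- x - y
  if (sd(d) == 0) stop_input("zero-variance differences: paired t undefined")
  res <- t.test(x, y, paired = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Bootstrap null for stripe-compartment differences
#'
#' Resamples subjects with replacement, computes per-compartment mean
#' selectivity and all pairwise differences; two-sided p values test each
#' pairwise difference against zero with add-one smoothing.
#'
#' @param si subject x compartment matrix (or data frame) of selectivity
#'   indices.
#' @param n_iter bootstrap iterations.
#' @param seed RNG seed.
#' @return a `bootstrap_null` list: `samples` (n_iter x pair matrix of
#'   difference samples), `p` (named per pair), `n_iter`, `seed`.
#' @export
bootstrap_compartment_null <- function(si, n_iter = 10000, seed = 1) {
  m <- as.matrix(si)
  n <- nrow(m)
  if (n < 2) stop_input("need >= 2 subjects")
  k <- ncol(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(k))
  pairs <- utils::combn(colnames(m), 2)
  idx <- with_seed(derive_seed(seed, 3),
                   matrix(sample.int(n, n * n_iter, replace = TRUE), n_iter, n))
  means <- vapply(seq_len(k), function(j) {
    rowMeans(matrix(m[idx, j], n_iter, n))
  }, numeric(n_iter))
  diffs <- vapply(seq_len(ncol(pairs)), function(q) {
    means[, match(pairs[1, q], colnames(m))] -
      means[, match(pairs[2, q], colnames(m))]
  }, numeric(n_iter))
  colnames(diffs) <- paste(pairs[1, ], pairs[2, ], sep = "-")
  p <- apply(diffs, 2, function(d) {
    lo <- (1 + sum(d <= 0)) / (1 + n_iter)
    hi <- (1 + sum(d >= 0)) / (1 + n_iter)
    min(1, 2 * min(lo, hi))
  })
  structure(list(samples = diffs, p = p, n_iter = n_iter, seed = seed),
            class = "bootstrap_null")
}

#' Fisher z transform and its inverse
#'
#' `z = atanh(r)`; errors for `|r| >= 1`.
#'
#' @param r correlation value(s), `|r| < 1`.
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop_input("`r` must satisfy |r| < 1")
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher z value(s).
#' @export
fisher_z_inverse <- function(z) tanh(z)

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity
#' (delegates to [stats::p.adjust()]); validates the input range.
#'
#' @param p p values in `[0, 1]`.
#' @return q values, same order as `p`.
#' @export
fdr_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_input("p values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.3f, p = %.4g%s\n",
              x$df_effect, x$df_error, x$F, x$p,
              if (x$degenerate) " [degenerate: zero interaction MS]" else ""))
  invisible(x)
}
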