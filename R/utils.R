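# Internal helpers shared across modules.

#' Derive a reproducible child seed from a base seed
#'
#' Hash-style combination that stays within the 32-bit integer range, so a
#' single user-facing seed can deterministically drive independent random
#' streams (one per run, per subject, per purpose).
#'
#' @param seed base integer seed.
#' @param ... integer offsets identifying the sub-stream.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  s <- as.numeric(seed) %% 2147483629
  for (off in c(...)) {
    s <- (s * 7919 + as.numeric(off) + 1) %% 2147483629
  }
  as.integer(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_input <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_input(sprintf("`%s` must be a single finite number in [%s, %s]",
                       name, format(lower), format(upper)))
  }
  invisible(x)
}

# Half-open cut: [0, 0.33) deep, [0.33, 0.67) middle, [0.67, 1] superficial.
depth_bin_levels <- c("deep", "middle", "superficial")

cut_depth_bin <- function(depth) {
  out <- ifelse(depth < 0.33, "deep", ifelse(depth < 0.67, "middle", "superficial"))
  factor(out, levels = depth_bin_levels)
}

compartment_levels <- c("thin", "thick", "pale", "none")
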