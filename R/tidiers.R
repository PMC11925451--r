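# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.dataset_glm <- function(x, ...) {
  tibble(voxel_id = rep(seq_len(nrow(x$betas)), ncol(x$betas)),
         condition = rep(colnames(x$betas), each = nrow(x$betas)),
         beta = as.vector(x$betas))
}

#' @export
glance.dataset_glm <- function(x, ...) {
  tibble(n_voxels = nrow(x$betas), conditions = ncol(x$betas),
         n_blocks = if (is.null(x$block_t)) NA_integer_ else ncol(x$block_t),
         dof = x$dof, drift_order = x$drift_order)
}

#' @export
tidy.rm_anova <- function(x, ...) {
  tibble(statistic = x$F, df = x$df_effect, df_error = x$df_error,
         p.value = x$p, degenerate = x$degenerate)
}

#' @export
tidy.bootstrap_null <- function(x, ...) {
  tibble(pair = names(x$p), p.value = unname(x$p),
         mean_diff = colMeans(x$samples))
}

#' @export
tidy.null_distribution <- function(x, ...) {
  tibble(n_iter = x$n_iter, mean = mean(x$samples),
         critical_05 = critical_value(x, 0.05))
}

#' @export
glance.laminar_study <- function(x, ...) {
  tibble(n_subjects = x$config$n_subjects,
         mean_dice = mean(x$dice$dice),
         n_pathways = if (is.null(x$group_connectivity)) 0L
                      else nrow(x$group_connectivity),
         n_significant_pathways = if (is.null(x$group_connectivity)) 0L
                      else sum(x$group_connectivity$q < 0.05))
}
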