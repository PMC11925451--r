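# ggplot2 views of the main result types.

#' Laminar selectivity profiles
#'
#' Mean selectivity index (+/- 1 SEM across subjects) per depth bin, faceted
#' by contrast and area.
#'
#' @param study a `laminar_study` (or its `laminar` tibble).
#' @return a ggplot object.
#' @export
plot_laminar_profiles <- function(study) {
  tab <- if (inherits(study, "laminar_study")) study$laminar else study
  sm <- tab %>%
    group_by(contrast, area, bin) %>%
    summarise(mean_si = mean(si), sem = sd(si) / sqrt(dplyr::n()),
              .groups = "drop")
  ggplot2::ggplot(sm, ggplot2::aes(x = bin, y = mean_si, group = contrast)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = mean_si - sem,
                                          ymax = mean_si + sem)) +
    ggplot2::facet_grid(contrast ~ area) +
    ggplot2::labs(x = "cortical depth bin", y = "selectivity index") +
    ggplot2::theme_minimal()
}

#' Stripe-compartment selectivity profile
#' @inheritParams plot_laminar_profiles
#' @return a ggplot object.
#' @export
plot_compartment_profiles <- function(study) {
  tab <- if (inherits(study, "laminar_study")) study$compartment else study
  sm <- tab %>%
    group_by(contrast, compartment) %>%
    summarise(mean_si = mean(si), sem = sd(si) / sqrt(dplyr::n()),
              .groups = "drop")
  ggplot2::ggplot(sm, ggplot2::aes(x = compartment, y = mean_si)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_si - sem,
                                        ymax = mean_si + sem), width = 0.2) +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::labs(x = "stripe compartment", y = "selectivity index") +
    ggplot2::theme_minimal()
}

#' Pathway connectivity matrix
#'
#' Group-mean informational connectivity per pathway and contrast, starred
#' where the FDR-corrected q falls below `alpha`.
#'
#' @param group_connectivity the `group_connectivity` tibble of a study.
#' @param alpha significance threshold on q.
#' @return a ggplot object.
#' @export
plot_connectivity_matrix <- function(group_connectivity, alpha = 0.05) {
  d <- group_connectivity %>%
    mutate(lab = sprintf("%.2f%s", mean_r, ifelse(q < alpha, " *", "")))
  ggplot2::ggplot(d, ggplot2::aes(x = contrast, y = pathway,
                                  fill = mean_r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = lab), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean r") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.null_distribution <- function(object, observed = NULL,
                                       alpha = 0.05, ...) {
  d <- tibble(r = object$samples)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = r)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(xintercept = critical_value(object, alpha),
                        linetype = 2) +
    ggplot2::labs(x = "null pattern correlation", y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "red")
  }
  p
}

#' @export
autoplot.acf_model <- function(object, ...) {
  grid <- tibble(dist = seq(0, max(object$curve$dist), length.out = 200))
  grid$fit <- acf_mixture(grid$dist, object$a, object$b, object$c)
  ggplot2::ggplot(object$curve, ggplot2::aes(x = dist, y = acf)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = fit), colour = "blue") +
    ggplot2::labs(x = "distance (mm)", y = "residual spatial ACF") +
    ggplot2::theme_minimal()
}
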