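# Orchestration: per-subject analysis and the multi-subject study with
# group-level statistics, mirroring the structure of a columnar/laminar
# 7T experiment (stripe profiles, depth profiles, eccentricity profile,
# test-retest reliability, layer-specific connectivity).

#' Pial-vein mask from fitted GLMs
#'
#' Ranks each area's columns by the mean all-conditions-vs-baseline response
#' (averaged over the session's experiments and the column's depth samples)
#' and excludes the top fraction per area.
#'
#' @param fits named list of `dataset_glm` fits.
#' @param patch the `cortical_patch`.
#' @param fraction excluded fraction per area.
#' @return a vein mask tibble (`column_id`, `excluded`) covering all columns.
#' @export
vein_mask_from_fits <- function(fits, patch, fraction = 0.05) {
  sig <- rowMeans(do.call(cbind, lapply(fits, function(f) f$betas[, 1:2])))
  col_sig <- tibble(column_id = patch$column_id,
                    area = patch$area, signal = sig) %>%
    group_by(column_id, area) %>%
    summarise(mean_signal = mean(signal), .groups = "drop")
  dplyr::bind_rows(lapply(split(col_sig, col_sig$area), function(d) {
    if (nrow(d) == 0) return(NULL)
    remove_pial_veins(d[, c("column_id", "mean_signal")], fraction)
  }))
}

#' Analyze one simulated subject
#'
#' Runs the full single-subject pipeline: GLM fits per experiment, vein
#' exclusion, stripe segmentation from the color-minus-disparity differential
#' map (with Dice overlap against the planted map), stripe-compartment /
#' laminar / eccentricity selectivity profiles, and the layer-specific
#' connectivity pathway matrix.
#'
#' @param sim a [simulate_subject()] result.
#' @param analysis analysis parameter list (see `default_config()$analysis`).
#' @param connectivity compute the decoding-based pathway matrix (slowest
#'   stage; can be disabled).
#' @return list of tibbles: `laminar`, `eccentricity`, `compartment`,
#'   `dice`, `connectivity`, plus `fits`, `vein_mask`, `stripes_est`.
#' @export
analyze_subject <- function(sim, analysis = default_config()$analysis,
                            connectivity = TRUE) {
  patch <- sim$patch
  fits <- lapply(sim$datasets, fit_dataset_glm,
                 drift_order = analysis$drift_order)
  vein <- vein_mask_from_fits(fits, patch, analysis$vein_fraction)

  areas <- levels(patch$area)
  laminar <- dplyr::bind_rows(lapply(names(fits), function(ct) {
    dplyr::bind_rows(lapply(areas, function(a) {
      laminar_profile(fits[[ct]], patch, a, vein_mask = vein)
    })) %>% mutate(contrast = ct)
  }))
  ecc <- eccentricity_profile(fits$texture, patch, "V2", vein_mask = vein) %>%
    mutate(contrast = "texture")

  dmap <- differential_map(fits$color, fits$disparity, patch)
  stripes_est <- segment_stripes(dmap, patch, z = analysis$z_threshold)
  dice <- stripe_dice(stripes_est, sim$stripes)
  compartment <- dplyr::bind_rows(lapply(names(fits), function(ct) {
    compartment_profile(fits[[ct]], patch, stripes_est, vein_mask = vein) %>%
      mutate(contrast = ct)
  }))

  conn <- NULL
  if (connectivity) {
    conn <- pathway_matrix(fits, patch, vein_mask = vein,
                           hierarchy = areas,
                           top_frac = analysis$top_frac,
                           n_tail = analysis$n_tail,
                           cost = analysis$svm_cost,
                           corr_mode = analysis$corr_mode,
                           evidence = if (identical(analysis$evidence,
                                                    "signed")) "signed"
                                      else "residual")
  }
  list(laminar = laminar, eccentricity = ecc, compartment = compartment,
       dice = dice, connectivity = conn, fits = fits, vein_mask = vein,
       stripes_est = stripes_est)
}

#' Test-retest reliability analysis for one subject
#'
#' Simulates a second scan session (same subject: same patch, stripes, vein
#' columns and selectivity factors; independent noise and block-level
#' variability), fits both sessions, estimates the residual spatial ACF from
#' session 1, and tests the inter-session columnar pattern correlation for
#' color and disparity against the Monte-Carlo FWE null.
#'
#' @param sim a [simulate_subject()] result (session 1).
#' @param config the study configuration.
#' @param n_iter Monte-Carlo iterations for the null.
#' @param contrasts which columnar contrasts to test.
#' @return tibble with `contrast`, `r`, `critical`, `p`.
#' @export
reliability_analysis <- function(sim, config, n_iter = 10000,
                                 contrasts = c("color", "disparity")) {
  res <- lapply(contrasts, function(ct) {
    ds1 <- sim$datasets[[ct]]
    ds2 <- simulate_bold(sim$patch, sim$stripes, ds1$design, config$truth,
                         contrast = ct,
                         seed = derive_seed(sim$seed, 500 + match(ct, contrasts)),
                         area_factor = sim$area_factor[[ct]],
                         vein_columns = sim$vein_columns,
                         sel_scatter = sim$sel_scatter[[ct]])
    fit1 <- fit_dataset_glm(ds1, drift_order = config$analysis$drift_order,
                            block_wise = FALSE)
    fit2 <- fit_dataset_glm(ds2, drift_order = config$analysis$drift_order,
                            block_wise = FALSE)
    acf <- estimate_acf(fit1$residuals, sim$patch)
    tr <- test_retest(session_map(fit1, sim$patch),
                      session_map(fit2, sim$patch),
                      acf, n_iter = n_iter,
                      seed = derive_seed(sim$seed, 600 + match(ct, contrasts)))
    tibble(contrast = ct, r = tr$r, critical = tr$critical, p = tr$p)
  })
  dplyr::bind_rows(res)
}

#' Run the full multi-subject study
#'
#' Simulates and analyzes `n_subjects` subjects, then computes the group
#' statistics: repeated-measures ANOVA and post hoc paired t tests on the
#' laminar profiles, compartment ANOVA + bootstrap stripe null, eccentricity
#' ANOVA + paired t tests, FDR-corrected group inference on the connectivity
#' pathway matrix, and (for the first `reliability_subjects` subjects)
#' test-retest reliability of the columnar maps.
#'
#' @param config a [default_config()] list.
#' @param connectivity,reliability enable the corresponding (slower) stages.
#' @param reliability_subjects number of subjects given a second session.
#' @param reliability_iter Monte-Carlo iterations for the reliability null.
#' @param progress print per-subject progress lines.
#' @return a `laminar_study` list of tidy tibbles: per-subject `laminar`,
#'   `eccentricity`, `compartment`, `dice`, `connectivity`, `reliability`;
#'   group-level `group_laminar`, `group_compartment`,
#'   `group_compartment_boot`, `group_eccentricity`, `group_connectivity`.
#' @export
run_study <- function(config = default_config(), connectivity = TRUE,
                      reliability = TRUE, reliability_subjects = 1,
                      reliability_iter = 2000, progress = FALSE) {
  subj <- vector("list", config$n_subjects)
  rel <- list()
  for (s in seq_len(config$n_subjects)) {
    if (progress) message("subject ", s, "/", config$n_subjects)
    sim <- simulate_subject(config, s)
    res <- analyze_subject(sim, config$analysis, connectivity = connectivity)
    if (reliability && s <= reliability_subjects) {
      rel[[s]] <- reliability_analysis(sim, config,
                                       n_iter = reliability_iter) %>%
        mutate(subject = s)
    }
    res$fits <- NULL        # free per-subject volumes before the next subject
    res$vein_mask <- NULL
    res$stripes_est <- NULL
    subj[[s]] <- lapply(res, function(x) {
      if (is.null(x)) NULL else mutate(x, subject = s)
    })
  }
  tables <- list(
    laminar = dplyr::bind_rows(lapply(subj, `[[`, "laminar")),
    eccentricity = dplyr::bind_rows(lapply(subj, `[[`, "eccentricity")),
    compartment = dplyr::bind_rows(lapply(subj, `[[`, "compartment")),
    dice = dplyr::bind_rows(lapply(subj, `[[`, "dice")),
    connectivity = dplyr::bind_rows(lapply(subj, `[[`, "connectivity")),
    reliability = dplyr::bind_rows(rel))

  out <- c(tables, list(
    group_laminar = group_profile_tests(tables$laminar, "bin"),
    group_compartment = group_profile_tests(tables$compartment, "compartment"),
    group_compartment_boot = compartment_bootstrap_tests(
      tables$compartment, seed = config$seed),
    group_eccentricity = group_profile_tests(tables$eccentricity, "ecc_bin"),
    group_connectivity = if (nrow(tables$connectivity) > 0) {
      group_inference(tables$connectivity %>%
                        select(contrast, lower, upper, direction, pathway,
                               subject, r, z))
    },
    config = config))
  structure(out, class = "laminar_study")
}

# Repeated-measures ANOVA (+ all pairwise paired t tests) per contrast/area
# cell of a subject x level selectivity table.
group_profile_tests <- function(tab, level_col) {
  if (is.null(tab) || nrow(tab) == 0) return(NULL)
  cells <- if ("area" %in% names(tab)) {
    split(tab, list(tab$contrast, tab$area), drop = TRUE)
  } else {
    split(tab, tab$contrast, drop = TRUE)
  }
  dplyr::bind_rows(lapply(cells, function(d) {
    wide <- d %>%
      select(subject, all_of(level_col), si) %>%
      tidyr::pivot_wider(names_from = all_of(level_col), values_from = si) %>%
      arrange(subject)
    m <- as.matrix(wide[, -1])
    an <- rm_anova_oneway(m)
    lv <- colnames(m)
    pt_rows <- utils::combn(lv, 2, simplify = FALSE)
    pts <- dplyr::bind_rows(lapply(pt_rows, function(pp) {
      res <- paired_t(m[, pp[1]], m[, pp[2]])
      tibble(comparison = paste(pp[1], "vs", pp[2]),
             t = res$t, df = res$df, p_t = res$p)
    }))
    base <- tibble(contrast = d$contrast[1],
                   area = if ("area" %in% names(d)) as.character(d$area[1])
                          else NA_character_,
                   F = an$F, df_effect = an$df_effect,
                   df_error = an$df_error, p_anova = an$p)
    dplyr::bind_cols(base[rep(1, nrow(pts)), ], pts)
  }))
}

# Bootstrap stripe-difference null per contrast on the compartment SI table.
compartment_bootstrap_tests <- function(tab, n_iter = 10000, seed = 1) {
  if (is.null(tab) || nrow(tab) == 0) return(NULL)
  dplyr::bind_rows(lapply(split(tab, tab$contrast), function(d) {
    wide <- d %>%
      select(subject, compartment, si) %>%
      tidyr::pivot_wider(names_from = compartment, values_from = si) %>%
      arrange(subject)
    bn <- bootstrap_compartment_null(as.matrix(wide[, -1]), n_iter = n_iter,
                                     seed = seed)
    tibble(contrast = d$contrast[1], pair = names(bn$p), p_boot = unname(bn$p))
  }))
}

#' @export
print.laminar_study <- function(x, ...) {
  cat("<laminar_study> ", x$config$n_subjects, " subject(s)\n", sep = "")
  dm <- tapply(x$dice$dice, x$dice$compartment, mean)
  cat("  mean stripe Dice: ",
      paste(sprintf("%s %.2f", names(dm), dm), collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$group_connectivity)) {
    sig <- x$group_connectivity %>% filter(q < 0.05)
    cat("  FDR-significant pathways: ", nrow(sig), "\n", sep = "")
  }
  invisible(x)
}
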