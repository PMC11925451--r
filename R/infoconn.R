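# Layer-specific informational connectivity: two-stage feature selection,
# leave-one-run-out linear max-margin decoding distances, pathway-paired
# block-wise correlation, and group inference.

#' Two-stage feature selection for decoding
#'
#' Stage 1 keeps the top `top_frac` most visually responsive voxels (by the
#' t distribution of activation vs baseline); stage 2 keeps the `n_tail` most
#' positive and `n_tail` most negative voxels of the condition-contrast t
#' distribution within that pool. Both statistics must be computed from
#' training runs only. Ties are broken towards the smaller voxel id, so the
#' selection is deterministic.
#'
#' @param visual_t per-voxel activation-vs-baseline t values.
#' @param differential_t per-voxel condition-contrast t values.
#' @param voxel_ids voxel ids (defaults to `seq_along(visual_t)`).
#' @param top_frac fraction kept in stage 1.
#' @param n_tail voxels kept from each tail in stage 2.
#' @return a `feature_set` list: `selected` (sorted voxel ids), `pos`, `neg`,
#'   `pool` (stage-1 ids), `top_frac`, `n_tail`.
#' @export
select_features <- function(visual_t, differential_t, voxel_ids = NULL,
                            top_frac = 0.2, n_tail = 200) {
  n <- length(visual_t)
  if (is.null(voxel_ids)) voxel_ids <- seq_len(n)
  if (length(differential_t) != n || length(voxel_ids) != n) {
    stop_input("`visual_t`, `differential_t` and `voxel_ids` lengths differ")
  }
  n_pool <- ceiling(top_frac * n)
  if (n_pool < 2 * n_tail) {
    stop_input(sprintf(
      "feature pool too small: stage 1 keeps %d voxels but 2 x n_tail = %d are required",
      n_pool, 2 * n_tail))
  }
  ord1 <- order(-visual_t, voxel_ids)
  pool <- sort(voxel_ids[ord1[seq_len(n_pool)]])
  dt <- differential_t[match(pool, voxel_ids)]
  pos <- pool[order(-dt, pool)][seq_len(n_tail)]
  neg <- pool[order(dt, pool)][seq_len(n_tail)]
  structure(list(selected = sort(c(pos, neg)), pos = sort(pos),
                 neg = sort(neg), pool = pool,
                 top_frac = top_frac, n_tail = n_tail),
            class = "feature_set")
}

#' L2 normalization
#'
#' Scales a pattern to unit Euclidean norm; errors on the zero vector.
#'
#' @param pattern numeric vector.
#' @return the pattern divided by its Euclidean norm.
#' @examples
#' l2_normalize(c(3, 4))
#' @export
l2_normalize <- function(pattern) {
  nrm <- sqrt(sum(pattern^2))
  if (nrm == 0) stop_input("cannot L2-normalize a zero vector")
  pattern / nrm
}

# Column-wise one-sample and two-sample t statistics over blocks.
row_t_onesample <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  s <- sqrt((rowSums(x^2) - n * m^2) / (n - 1))
  m / (s / sqrt(n))
}

row_t_twosample <- function(xa, xb) {
  na <- ncol(xa)
  nb <- ncol(xb)
  ma <- rowMeans(xa)
  mb <- rowMeans(xb)
  va <- (rowSums(xa^2) - na * ma^2) / (na - 1)
  vb <- (rowSums(xb^2) - nb * mb^2) / (nb - 1)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  (ma - mb) / (sp * sqrt(1 / na + 1 / nb))
}

#' Leave-one-run-out decoding distances
#'
#' For each cross-validation fold (one run held out): feature selection on
#' the training runs only, L2 normalization of each block pattern, a linear
#' max-margin classifier (soft margin, cost `cost`) trained on the training
#' blocks, and geometric signed distances to the decision boundary
#' `(w x + b) / |w|` for the held-out blocks. Positive distances indicate
#' classification as the first condition.
#'
#' @param patterns voxel x block matrix of block-wise t-score patterns for
#'   one region-layer.
#' @param block_info tibble with `run`, `block`, `condition` matching the
#'   pattern columns.
#' @param conditions the condition pair, first = positive class.
#' @param top_frac,n_tail feature-selection parameters, see
#'   [select_features()].
#' @param cost soft-margin regularization constant.
#' @param voxel_ids optional voxel ids for the pattern rows.
#' @return a `distance_series` tibble: `fold`, `run`, `block`, `condition`,
#'   `distance`, with the per-fold `feature_set`s in the `"features"`
#'   attribute.
#' @export
decode_distances <- function(patterns, block_info, conditions,
                             top_frac = 0.2, n_tail = 200, cost = 1,
                             voxel_ids = NULL) {
  runs <- unique(block_info$run)
  if (length(runs) < 2) stop_input("need >= 2 runs for leave-one-run-out")
  if (is.null(voxel_ids)) voxel_ids <- seq_len(nrow(patterns))
  out <- vector("list", length(runs))
  feats <- vector("list", length(runs))
  for (f in seq_along(runs)) {
    test <- block_info$run == runs[f]
    tr_info <- block_info[!test, ]
    if (length(unique(tr_info$condition)) < 2) {
      stop_input("training folds must contain both conditions")
    }
    tr <- patterns[, !test, drop = FALSE]
    vt <- row_t_onesample(tr)
    dt <- row_t_twosample(tr[, tr_info$condition == conditions[1], drop = FALSE],
                          tr[, tr_info$condition == conditions[2], drop = FALSE])
    fs <- select_features(vt, dt, voxel_ids, top_frac = top_frac,
                          n_tail = n_tail)
    sel <- match(fs$selected, voxel_ids)
    Xtr <- apply(tr[sel, , drop = FALSE], 2, l2_normalize)
    Xte <- apply(patterns[sel, test, drop = FALSE], 2, l2_normalize)
    ytr <- factor(tr_info$condition, levels = conditions)
    model <- e1071::svm(x = t(Xtr), y = ytr, kernel = "linear", cost = cost,
                        scale = FALSE)
    w <- as.vector(t(model$coefs) %*% model$SV)
    b <- -model$rho
    # orient so positive distance = first condition
    dtr <- as.vector(t(Xtr) %*% w) + b
    if (mean(dtr[ytr == conditions[1]]) < mean(dtr[ytr == conditions[2]])) {
      w <- -w
      b <- -b
    }
    d <- (as.vector(t(Xte) %*% w) + b) / sqrt(sum(w^2))
    out[[f]] <- tibble(fold = f, run = runs[f],
                       block = block_info$block[test],
                       condition = block_info$condition[test],
                       distance = d)
    feats[[f]] <- fs
  }
  res <- dplyr::bind_rows(out)
  attr(res, "features") <- feats
  class(res) <- c("distance_series", class(res))
  res
}

#' Held-out decoding accuracy of a distance series
#' @param distances a `distance_series`.
#' @param conditions the condition pair (first = positive class).
#' @return fraction of held-out blocks whose distance sign matches the label.
#' @export
decode_accuracy <- function(distances, conditions) {
  mean((distances$distance > 0) == (distances$condition == conditions[1]))
}

#' Informational connectivity between two distance series
#'
#' Pearson correlation of the block-by-block decoding-distance timeseries of
#' two region-layers, computed per cross-validation fold on the held-out
#' blocks and averaged across folds. With the default
#' `evidence = "residual"`, each series is first residualized on its mean
#' evidence per (block position x condition) cell across runs, so the
#' correlation measures shared block-level fluctuations of stimulus
#' information rather than the stimulus sequence and the deterministic
#' position profile both regions inherit from the common design;
#' `evidence = "signed"` correlates the raw signed distances.
#' `corr_mode = "concatenated"` pools the residualized distances across folds
#' into a single correlation instead of averaging per-fold values.
#'
#' @param series_a,series_b `distance_series` objects with matching folds and
#'   blocks.
#' @param evidence `"residual"` or `"signed"`.
#' @param corr_mode `"per_fold"` (default) or `"concatenated"`.
#' @return mean Pearson correlation (scalar).
#' @export
informational_connectivity <- function(series_a, series_b,
                                       evidence = c("residual", "signed"),
                                       corr_mode = c("per_fold", "concatenated")) {
  evidence <- match.arg(evidence)
  corr_mode <- match.arg(corr_mode)
  j <- dplyr::inner_join(
    as_tibble(series_a), as_tibble(series_b),
    by = c("fold", "run", "block"), suffix = c("_a", "_b"))
  if (nrow(j) != nrow(series_a) || !all(j$condition_a == j$condition_b)) {
    stop_input("distance series have mismatched folds, blocks or labels")
  }
  if (evidence == "residual") {
    # Remove each series' design-locked mean: the average evidence of every
    # (block position x condition) cell across runs. Block position carries a
    # deterministic estimation-efficiency profile (run-edge blocks yield
    # higher-SNR patterns) that is shared between any two regions and would
    # otherwise inflate every pathway correlation.
    cell <- paste(j$block, j$condition_a)
    j$distance_a <- j$distance_a - stats::ave(j$distance_a, cell)
    j$distance_b <- j$distance_b - stats::ave(j$distance_b, cell)
  }
  folds <- split(j, j$fold)
  vals <- c()
  xs <- c()
  ys <- c()
  for (fd in folds) {
    if (nrow(fd) < 3) {
      warning("fold with < 3 blocks skipped")
      next
    }
    x <- fd$distance_a
    y <- fd$distance_b
    if (corr_mode == "per_fold") {
      if (sd(x) == 0 || sd(y) == 0) next
      vals <- c(vals, cor(x, y))
    } else {
      xs <- c(xs, x)
      ys <- c(ys, y)
    }
  }
  if (corr_mode == "concatenated") {
    if (length(xs) == 0) stop_input("all folds skipped")
    return(cor(xs, ys))
  }
  if (length(vals) == 0) stop_input("all folds skipped")
  mean(vals)
}

# Adjacent pairs of the visual hierarchy V1 < V2 < {V3ab, V4}: each higher
# area is paired with the highest area below it.
hierarchy_pairs <- function(hierarchy = c("V1", "V2", "V3ab", "V4")) {
  if (length(hierarchy) < 2) return(tibble(lower = character(), upper = character()))
  lower <- c("V2" = "V1", "V3ab" = "V2", "V4" = "V2")
  keep <- hierarchy[hierarchy %in% names(lower)]
  tibble(lower = unname(lower[keep]), upper = keep) %>%
    filter(lower %in% hierarchy)
}

#' Layer-specific pathway connectivity for one subject
#'
#' For every adjacent area pair of the hierarchy and every contrast, computes
#' the feedforward pathway (superficial layer of the lower area with the
#' middle layer of the higher area) and the feedback pathway (deep layer with
#' deep layer) informational connectivity from leave-one-run-out decoding
#' distances.
#'
#' @param fits named list of `dataset_glm` fits, one per contrast.
#' @param patch the `cortical_patch`.
#' @param vein_mask optional vein mask applied before decoding.
#' @param hierarchy ordered area labels.
#' @param top_frac,n_tail,cost decoding parameters.
#' @param evidence,corr_mode see [informational_connectivity()].
#' @return tibble with `contrast`, `lower`, `upper`, `direction`, `pathway`,
#'   `r`, `z`.
#' @export
pathway_matrix <- function(fits, patch, vein_mask = NULL,
                           hierarchy = c("V1", "V2", "V3ab", "V4"),
                           top_frac = 0.2, n_tail = 200, cost = 1,
                           evidence = "residual", corr_mode = "per_fold") {
  pairs <- hierarchy_pairs(hierarchy)
  if (nrow(pairs) == 0) {
    return(tibble(contrast = character(), lower = character(),
                  upper = character(), direction = character(),
                  pathway = character(), r = numeric(), z = numeric()))
  }
  roi <- apply_vein_mask(patch, vein_mask)
  bins <- cut_depth_bin(roi$depth)
  need <- unique(dplyr::bind_rows(
    tibble(area = pairs$lower, bin = "superficial"),
    tibble(area = pairs$upper, bin = "middle"),
    tibble(area = pairs$lower, bin = "deep"),
    tibble(area = pairs$upper, bin = "deep")))
  res <- list()
  for (ct in names(fits)) {
    fit <- fits[[ct]]
    conds <- contrast_conditions()[[ct]]
    dist_cache <- list()
    get_dist <- function(a, b) {
      key <- paste(a, b)
      if (is.null(dist_cache[[key]])) {
        ids <- roi$voxel_id[roi$area == a & bins == b]
        if (length(ids) == 0) {
          stop_input("no voxels for region-layer ", a, " ", b)
        }
        dist_cache[[key]] <<- decode_distances(
          fit$block_t[ids, , drop = FALSE], fit$block_info, conds,
          top_frac = top_frac, n_tail = n_tail, cost = cost,
          voxel_ids = ids)
      }
      dist_cache[[key]]
    }
    for (i in seq_len(nrow(pairs))) {
      lo <- pairs$lower[i]
      hi <- pairs$upper[i]
      ff <- informational_connectivity(get_dist(lo, "superficial"),
                                       get_dist(hi, "middle"),
                                       evidence = evidence,
                                       corr_mode = corr_mode)
      fb <- informational_connectivity(get_dist(lo, "deep"),
                                       get_dist(hi, "deep"),
                                       evidence = evidence,
                                       corr_mode = corr_mode)
      res[[length(res) + 1]] <- tibble(
        contrast = ct, lower = lo, upper = hi,
        direction = c("feedforward", "feedback"),
        pathway = c(sprintf("%s superficial -> %s middle", lo, hi),
                    sprintf("%s deep <-> %s deep", lo, hi)),
        r = c(ff, fb))
    }
  }
  dplyr::bind_rows(res) %>% mutate(z = fisher_z(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)))
}

#' Group inference on pathway connectivity
#'
#' One-sample t test of the Fisher-z connectivity values against zero for
#' every pathway x contrast cell, with Benjamini-Hochberg FDR correction
#' across the whole family of tested cells.
#'
#' @param df tibble with one row per subject x cell, containing `z` and the
#'   cell identifiers (all columns except `subject`, `r`, `z` group cells).
#' @return tibble with one row per cell: `n`, `mean_r`, `t`, `df`, `p`, `q`,
#'   `degenerate`.
#' @export
group_inference <- function(df) {
  cell_cols <- setdiff(names(df), c("subject", "r", "z"))
  out <- df %>%
    group_by(across(all_of(cell_cols))) %>%
    summarise(n = dplyr::n(),
              mean_r = if ("r" %in% names(df)) mean(r) else tanh(mean(z)),
              mean_z = mean(z), sd_z = sd(z), .groups = "drop")
  if (any(out$n < 3)) stop_input("need >= 3 subjects per cell")
  if (any(out$sd_z == 0 & out$mean_z != 0)) {
    stop_input("zero variance with nonzero mean: t undefined")
  }
  out <- out %>%
    mutate(degenerate = sd_z == 0,
           t = ifelse(degenerate, 0, mean_z / (sd_z / sqrt(n))),
           df = n - 1,
           p = ifelse(degenerate, 1, 2 * pt(-abs(t), df)),
           q = fdr_bh(p)) %>%
    select(-mean_z, -sd_z)
  out
}
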