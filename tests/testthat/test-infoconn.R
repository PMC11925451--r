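test_that("two-stage feature selection: sizes, rank rules, tie-breaks", {
  set.seed(71)
  vt <- rnorm(4000)
  dt <- rnorm(4000)
  fs <- select_features(vt, dt)
  expect_equal(length(fs$pool), 800L)
  expect_equal(length(fs$selected), 400L)
  expect_equal(length(intersect(fs$pos, fs$neg)), 0L)
  # all-positive differential: the low tail is the least positive
  dp <- abs(dt) + 0.01
  fs2 <- select_features(vt, dp, n_tail = 100)
  low <- dp[match(fs2$neg, seq_along(dp))]
  others <- dp[match(setdiff(fs2$pool, fs2$neg), seq_along(dp))]
  expect_lt(max(low), min(others) + 1e-12)
  # ties resolve towards smaller voxel ids
  fst <- select_features(rep(1, 100), rep(0, 100), top_frac = 0.5,
                         n_tail = 10)
  expect_equal(fst$pool, 1:50)
  expect_equal(fst$pos, 1:10)
  expect_error(select_features(rnorm(50), rnorm(50), n_tail = 10),
               "pool too small")
})

test_that("L2 normalization: arithmetic, idempotence, scale invariance", {
  expect_equal(l2_normalize(c(3, 4)), c(0.6, 0.8))
  u <- l2_normalize(rnorm(10))
  expect_equal(l2_normalize(u), u)
  x <- rnorm(10)
  expect_equal(l2_normalize(10 * x), l2_normalize(x))
  expect_error(l2_normalize(rep(0, 5)), "zero vector")
})

toy_patterns <- function(n_vox = 12, n_runs = 3, sep = 1, seed = 1) {
  set.seed(seed)
  bi <- tibble::tibble(run = rep(seq_len(n_runs), each = 8),
                       block = rep(1:8, n_runs),
                       condition = rep(c("A", "B"), 4 * n_runs))
  pat <- matrix(rnorm(n_vox * nrow(bi)), n_vox) +
    outer(rep(c(1, -1), each = n_vox / 2),
          ifelse(bi$condition == "A", sep, -sep))
  list(patterns = pat, block_info = bi)
}

test_that("decoding distances separate a linearly separable toy problem", {
  toy <- toy_patterns(sep = 3)
  d <- decode_distances(toy$patterns, toy$block_info, c("A", "B"),
                        top_frac = 1, n_tail = 3)
  expect_equal(decode_accuracy(d, c("A", "B")), 1)
  expect_true(all(d$distance[d$condition == "A"] > 0))
  expect_error(decode_distances(toy$patterns, toy$block_info[1:8, ],
                                c("A", "B")), ">= 2 runs")
})

test_that("duplicating every voxel leaves distances essentially unchanged", {
  toy <- toy_patterns()
  d1 <- decode_distances(toy$patterns, toy$block_info, c("A", "B"),
                         top_frac = 1, n_tail = 3)
  d2 <- decode_distances(rbind(toy$patterns, toy$patterns), toy$block_info,
                         c("A", "B"), top_frac = 1, n_tail = 6)
  expect_equal(d1$distance, d2$distance, tolerance = 0.02)
})

test_that("label shuffling drives held-out accuracy to chance", {
  toy <- toy_patterns(n_vox = 40, n_runs = 4, sep = 1)
  accs <- sapply(1:25, function(i) {
    bi <- toy$block_info
    set.seed(100 + i)
    bi$condition <- unlist(tapply(bi$condition, bi$run, sample))
    decode_accuracy(decode_distances(toy$patterns, bi, c("A", "B"),
                                     top_frac = 0.5, n_tail = 5),
                    c("A", "B"))
  })
  expect_lt(abs(mean(accs) - 0.5), 3 * sd(accs) / sqrt(length(accs)) + 0.02)
})

test_that("informational connectivity: identity, null, symmetry, guards", {
  toy <- toy_patterns(n_vox = 30, n_runs = 4, sep = 1.5, seed = 5)
  d <- decode_distances(toy$patterns, toy$block_info, c("A", "B"),
                        top_frac = 1, n_tail = 5)
  expect_equal(informational_connectivity(d, d), 1)
  set.seed(6)
  toy2 <- toy_patterns(n_vox = 30, n_runs = 4, sep = 1.5, seed = 77)
  d2 <- decode_distances(toy2$patterns, toy2$block_info, c("A", "B"),
                         top_frac = 1, n_tail = 5)
  r12 <- informational_connectivity(d, d2)
  expect_equal(r12, informational_connectivity(d2, d))
  expect_lt(abs(r12), 3 / sqrt(16))
  # signed mode correlates the raw distances (label-driven, near 1 here)
  expect_gt(informational_connectivity(d, d2, evidence = "signed"), 0.5)
  # concatenated mode pools folds into one correlation
  rc <- informational_connectivity(d, d2, corr_mode = "concatenated")
  expect_true(is.numeric(rc) && abs(rc) <= 1)
  bad <- d2[-1, ]
  expect_error(informational_connectivity(d, bad), "mismatched")
})

test_that("pathway layer pairings follow the feedforward/feedback convention", {
  pairs <- laminarfmri:::hierarchy_pairs(c("V1", "V2", "V3ab", "V4"))
  expect_equal(pairs$lower, c("V1", "V2", "V2"))
  expect_equal(pairs$upper, c("V2", "V3ab", "V4"))
  expect_equal(nrow(laminarfmri:::hierarchy_pairs("V1")), 0L)
  sim <- tiny_subject()
  fits <- tiny_fits()
  pm <- pathway_matrix(fits["texture"], sim$patch, n_tail = 20)
  expect_equal(nrow(pm), 6L)
  expect_true("V1 superficial -> V2 middle" %in%
                pm$pathway[pm$direction == "feedforward"])
  expect_true("V2 deep <-> V4 deep" %in%
                pm$pathway[pm$direction == "feedback"])
  expect_equal(pm$z, atanh(pm$r), tolerance = 1e-10)
})

test_that("group inference: hand t, FDR family, degenerate z", {
  df <- tibble::tibble(
    pathway = rep(c("p1", "p2"), each = 5),
    subject = rep(1:5, 2),
    z = c(0.5, 0.6, 0.7, 0.5, 0.6, rep(0, 5)))
  res <- group_inference(df)
  expect_equal(res$t[res$pathway == "p1"], 15.50115, tolerance = 1e-4)
  expect_equal(res$df[res$pathway == "p1"], 4)
  expect_equal(res$t[res$pathway == "p2"], 0)
  expect_true(res$degenerate[res$pathway == "p2"])
  expect_equal(res$q, fdr_bh(res$p))
  expect_equal(atanh(0.66), 0.7928136, tolerance = 1e-6)
  expect_error(group_inference(df[df$subject < 3, ]), ">= 3 subjects")
})

test_that("feature selection guards against train/test leakage", {
  sim <- tiny_subject()
  fit <- tiny_fits()$texture
  patch <- sim$patch
  bins <- laminarfmri:::cut_depth_bin(patch$depth)
  ids <- patch$voxel_id[patch$area == "V2" & bins == "deep"]
  pat <- fit$block_t[ids, ]
  bi <- fit$block_info
  test_run <- bi$run == 1
  tr <- pat[, !test_run]
  cond_tr <- bi$condition[!test_run]
  vt_train <- laminarfmri:::row_t_onesample(tr)
  dt_train <- laminarfmri:::row_t_twosample(tr[, cond_tr == "T"],
                                            tr[, cond_tr == "N"])
  vt_all <- laminarfmri:::row_t_onesample(pat)
  dt_all <- laminarfmri:::row_t_twosample(pat[, bi$condition == "T"],
                                          pat[, bi$condition == "N"])
  fs_train <- select_features(vt_train, dt_train, ids, n_tail = 20)
  fs_all <- select_features(vt_all, dt_all, ids, n_tail = 20)
  expect_false(setequal(fs_train$selected, fs_all$selected))
})
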