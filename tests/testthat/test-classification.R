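# one small generated dataset reused across decoding tests
decoding_fixture <- function(n_subjects = 2, n_voxels = 80, sigma = 0.2,
                             ts_noise = 4, seed = 23L, alpha = 0.5) {
  cfg <- scenario_config(n_subjects = n_subjects, n_voxels = n_voxels,
                         roi_names = "EBA", sigma_noise = sigma,
                         alpha_true = alpha, seed = seed)
  ds <- generate_condition_patterns(cfg)
  ts <- generate_timeseries(ds, paper_design(), noise_sd = ts_noise,
                            seed = seed + 1L)
  ts <- discard_initial_volumes(ts)
  extract_condition_volumes(ts)
}

test_that("z-scoring normalises every voxel within run", {
  vps <- decoding_fixture(n_subjects = 1, n_voxels = 30)
  z <- zscore_patterns(vps)
  m <- z$data$S01$run2$EBA
  expect_true(all(abs(colMeans(m)) < 1e-10))
  pop_sd <- sqrt(colMeans(sweep(m, 2, colMeans(m))^2))
  expect_true(all(abs(pop_sd - 1) < 1e-10))
  expect_true(isTRUE(z$zscored))
})

test_that("constant voxels are zeroed with a warning and a toy pair maps to +/-1", {
  vps <- decoding_fixture(n_subjects = 1, n_voxels = 10)
  vps$data$S01$run1$EBA[, 3] <- 7
  expect_warning(z <- zscore_patterns(vps), "zero-variance")
  expect_true(all(z$data$S01$run1$EBA[, 3] == 0))
  # two-volume voxel {1, 3} standardises to {-1, +1} under the population SD
  x <- c(1, 3)
  pop_sd <- sqrt(mean((x - mean(x))^2))
  expect_equal((x - mean(x)) / pop_sd, c(-1, 1))
})

test_that("voxelwise ANOVA agrees with oneway.test", {
  set.seed(3)
  X <- matrix(rnorm(90 * 5), 90, 5)
  labels <- rep(letters[1:9], each = 10)
  res <- voxelwise_anova(X, labels)
  for (j in 1:5) {
    ref <- stats::oneway.test(X[, j] ~ factor(labels), var.equal = TRUE)
    expect_equal(res$F[j], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p[j], ref$p.value, tolerance = 1e-10)
  }
})

test_that("feature selection retains ~5% of null voxels and all at threshold 1", {
  set.seed(9)
  n_vox <- 2000
  X <- matrix(rnorm(540 * n_vox), 540, n_vox)
  labels <- rep(conditions_table()$condition, each = 60)
  res <- voxelwise_anova(X, labels)
  frac <- mean(res$p < 0.05)
  ci_half <- 2.576 * sqrt(0.05 * 0.95 / n_vox)
  expect_lt(abs(frac - 0.05), ci_half)
  expect_true(all(res$p < 1 + 1e-15))
  expect_equal(mean(res$p < 1), 1)

  # voxels with large condition effects are retained
  effect <- outer(as.integer(factor(labels)), rep(1, 50)) / 3
  Xeff <- matrix(rnorm(540 * 50), 540, 50) + effect
  expect_true(all(voxelwise_anova(Xeff, labels)$p < 0.05))
})

test_that("empty masks raise an explicit error", {
  vps <- decoding_fixture(n_subjects = 1, n_voxels = 10, ts_noise = 60,
                          sigma = 3)
  z <- zscore_patterns(vps)
  expect_error(anova_feature_select(z, "S01", "EBA", p_threshold = 1e-12),
               "no voxels")
})

test_that("training sets have the design-implied exemplar counts", {
  vps <- zscore_patterns(decoding_fixture(n_subjects = 1, n_voxels = 20))
  tr <- build_training_patterns(vps, "S01", "EBA", "face")
  expect_equal(nrow(tr$X), 180)                 # 3 runs x 20 volumes x 3 emotions
  expect_true(all(table(tr$y) == 60))           # 60 exemplars per emotion
  te <- build_test_patterns(vps, "S01", "EBA")
  expect_equal(nrow(te$X), 180)                 # run 4: 3 x 60 person volumes
  expect_true(all(table(te$y) == 60))
  # block-wise aggregation: 18 blocks in run 4
  teb <- build_test_patterns(vps, "S01", "EBA", aggregate = "block")
  expect_equal(nrow(teb$X), 18)
  expect_true(all(table(teb$y) == 6))
})

test_that("mean training equals weighted-mean training at alpha 0.5", {
  vps <- zscore_patterns(decoding_fixture(n_subjects = 1, n_voxels = 20))
  atab <- data.frame(subject = "S01", roi = "EBA",
                     emotion = emotion_levels(), alpha_hat = 0.5)
  a <- build_training_patterns(vps, "S01", "EBA", "mean")
  b <- build_training_patterns(vps, "S01", "EBA", "weighted_mean",
                               alpha_table = atab)
  expect_equal(a$X, b$X)
  expect_identical(a$y, b$y)
  expect_error(build_training_patterns(vps, "S01", "EBA", "weighted_mean"),
               "alpha_table")
  expect_error(build_training_patterns(vps, "S01", "EBA", "banana"))
})

test_that("well-separated part-based data decodes person emotions above 0.9", {
  vps <- zscore_patterns(decoding_fixture(n_subjects = 1, n_voxels = 150,
                                          sigma = 0.1, ts_noise = 1))
  mask <- anova_feature_select(vps, "S01", "EBA")
  tr <- build_training_patterns(vps, "S01", "EBA", "mean")
  te <- build_test_patterns(vps, "S01", "EBA")
  acc <- decode_person_emotions(tr, te, mask)
  expect_gte(acc, 0.9)
  # determinism: duplicated test set gives the same accuracy
  te2 <- list(X = rbind(te$X, te$X), y = rep(te$y, 2))
  expect_equal(decode_person_emotions(tr, te2, mask), acc)
  # single-class training is rejected
  tr1 <- list(X = tr$X[tr$y == "fear", ], y = droplevels(tr$y[tr$y == "fear"]))
  expect_error(decode_person_emotions(tr1, te, mask), "single class")
})

test_that("permuted training labels decode at chance", {
  vps <- zscore_patterns(decoding_fixture(n_subjects = 1, n_voxels = 60))
  mask <- anova_feature_select(vps, "S01", "EBA")
  tr <- build_training_patterns(vps, "S01", "EBA", "mean")
  te <- build_test_patterns(vps, "S01", "EBA")
  null_acc <- permutation_null_accuracy(tr, te, mask, n_perm = 100, seed = 3L)
  expect_lt(abs(mean(null_acc) - 1 / 3), 0.03)
})

test_that("the feature mask is independent of run-4 content", {
  vps <- zscore_patterns(decoding_fixture(n_subjects = 1, n_voxels = 40))
  mask1 <- anova_feature_select(vps, "S01", "EBA")
  vps$data$S01$run4$EBA <- matrix(rnorm(length(vps$data$S01$run4$EBA)),
                                  nrow = nrow(vps$data$S01$run4$EBA))
  mask2 <- anova_feature_select(vps, "S01", "EBA")
  expect_identical(mask1, mask2)
})

test_that("synthetic-pattern training beats single-part training on part-based data", {
  one_seed <- function(seed) {
    cfg <- scenario_config(n_subjects = 20, n_voxels = 80, roi_names = "EBA",
                           sigma_noise = 0.4, seed = seed)
    ds <- generate_condition_patterns(cfg)
    ts <- discard_initial_volumes(
      generate_timeseries(ds, design_spec(), noise_sd = 8, seed = seed + 1L))
    vps <- extract_condition_volumes(ts)
    wt <- weight_table(ds, rois = "EBA")
    ctab <- classification_table(vps, alpha_table = wt)
    vapply(split(ctab$accuracy, ctab$type), mean, numeric(1))
  }
  accs <- vapply(1:50, function(i) one_seed(9000L + i), numeric(4))
  part_max <- pmax(accs["face", ], accs["body", ])
  expect_true(all(accs["mean", ] >= part_max))
  expect_true(all(accs["weighted_mean", ] >= part_max))
})

test_that("group testing against chance applies BH over all ROI x type cells", {
  set.seed(61)
  grid <- expand.grid(subject = sprintf("S%02d", 1:10), roi = default_rois(),
                      type = c("face", "body", "mean", "weighted_mean"),
                      stringsAsFactors = FALSE)
  grid$accuracy <- pmin(pmax(1 / 3 + rnorm(nrow(grid), sd = 0.05), 0), 1)
  res <- group_test_and_fdr(grid)
  expect_equal(nrow(res), 28)
  expect_equal(res$p_fdr, stats::p.adjust(res$p, method = "BH"))
  # BH never decreases a p-value and is monotone in the raw p-values
  expect_true(all(res$p_fdr >= res$p - 1e-15))
  ord <- order(res$p)
  expect_true(all(diff(res$p_fdr[ord]) >= -1e-15))
  expect_error(group_test_and_fdr(grid[-1, ]), "missing cells")
})

test_that("BH arithmetic: equal raw p values stay unchanged, single test is identity", {
  p <- rep(0.01, 28)
  expect_true(all(stats::p.adjust(p, "BH") == 0.01))
  expect_true(all(stats::p.adjust(p, "BH") < 0.05))
  grid <- data.frame(subject = rep(sprintf("S%02d", 1:8), 1), roi = "EBA",
                     type = "mean",
                     accuracy = seq(0.4, 0.75, length.out = 8))
  res <- group_test_and_fdr(grid)
  expect_equal(res$p_fdr, res$p)
})
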