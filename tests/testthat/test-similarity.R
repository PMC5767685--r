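test_that("synthetic mean is the elementwise average", {
  expect_equal(synthetic_mean(c(1, 3, 5), c(3, 1, 1)), c(2, 2, 3))
  v <- rnorm(10)
  expect_equal(synthetic_mean(v, v), v)
  expect_error(synthetic_mean(1:3, 1:4), "length")
  # consistency with the weighted combination at alpha = 0.5
  set.seed(1)
  f <- rnorm(100); b <- rnorm(100)
  expect_identical(synthetic_mean(f, b), weighted_mean(f, b, 0.5))
})

test_that("fisher z matches the closed form and clips at the boundary", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_true(is.finite(fisher_z(1)))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_equal(fisher_z(-1), -atanh(1 - 1e-7))
  expect_error(fisher_z(1.01), "outside")
  # strictly increasing on a grid spanning the domain
  r <- seq(-0.999, 0.999, length.out = 201)
  expect_true(all(diff(fisher_z(r)) > 0))
})

test_that("cross-run correlation handles identical, orthogonal and collinear patterns", {
  # identical noiseless patterns across runs: reliability at the clip maximum
  ds_same <- manual_pattern_dataset(function(s, r, cn) {
    set.seed(match(cn, conditions_table()$condition))
    rnorm(50)
  }, n_voxels = 50)
  res <- cross_run_correlation(ds_same, "EBA", "happiness", "face", "face")
  expect_equal(res$z, atanh(1 - 1e-7))
  expect_equal(res$n_pairs, 3)

  # centred orthogonal run patterns: r exactly 0
  basis <- rbind(c(1, -1, 0, 0, 0, 0),
                 c(0, 0, 1, -1, 0, 0),
                 c(0, 0, 0, 0, 1, -1))
  ds_orth <- manual_pattern_dataset(function(s, r, cn) basis[r, ],
                                    n_voxels = 6)
  res0 <- cross_run_correlation(ds_orth, "EBA", "anger", "face", "face")
  expect_equal(res0$z, 0)

  # exact collinearity across categories and runs -> clipped z
  ds_col <- manual_pattern_dataset(function(s, r, cn) {
    base <- c(1, 2, 3, 4)
    if (grepl("^person", cn)) 2 * base else base
  }, n_voxels = 4)
  resc <- cross_run_correlation(ds_col, "EBA", "fear", "face", "person")
  expect_equal(resc$r, 1)
  expect_equal(resc$z, atanh(1 - 1e-7))
  expect_equal(resc$n_pairs, 6)
})

test_that("zero-variance patterns are skipped with a warning", {
  ds <- manual_pattern_dataset(function(s, r, cn) {
    if (r == 1 && cn == "face_fear") rep(1, 6) else rnorm(6)
  }, n_voxels = 6)
  w <- capture_warnings(
    res <- cross_run_correlation(ds, "EBA", "fear", "face", "body"))
  expect_match(w, "zero-variance", all = TRUE)
  expect_length(w, 2)
  expect_equal(res$n_pairs, 4)
})

test_that("RSMs are symmetric and category-permutation equivariant", {
  ds <- generate_condition_patterns(small_config(n_voxels = 120, seed = 3L))
  m <- build_rsm(ds, "EBA", "happiness", subject = "S01")
  expect_equal(m, t(m))
  expect_identical(rownames(m), category_levels())
  # equivariance: the matrix entry only depends on the unordered pair
  z_fb <- cross_run_correlation(ds, "EBA", "happiness", "face", "body",
                                subject = "S01")$z
  z_bf <- cross_run_correlation(ds, "EBA", "happiness", "body", "face",
                                subject = "S01")$z
  expect_equal(z_fb, z_bf)
  expect_equal(m["face", "body"], z_fb)
})

test_that("group-average RSM is the elementwise subject mean", {
  m <- matrix(rnorm(16), 4, 4)
  m <- m + t(m)
  dimnames(m) <- list(category_levels(), category_levels())
  expect_equal(group_average_rsm(list(m)), m)
  expect_equal(group_average_rsm(list(m, -m)),
               matrix(0, 4, 4, dimnames = dimnames(m)))
  expect_error(group_average_rsm(list(m, NULL, m)), "missing")
})

test_that("part-based data puts person-synthetic above person-face and person-body", {
  # gamma = 1, alpha = 0.5, sigma at the r ~ 0.8 calibration
  cfg <- scenario_config(n_subjects = 20, n_voxels = 300, roi_names = "EBA",
                         sigma_noise = 0.4, seed = 41L)
  ds <- generate_condition_patterns(cfg)
  wins <- 0
  for (s in ds$subjects) {
    ps <- cross_run_correlation(ds, "EBA", "happiness", "person", "synthetic",
                                subject = s)$z
    pf <- cross_run_correlation(ds, "EBA", "happiness", "person", "face",
                                subject = s)$z
    pb <- cross_run_correlation(ds, "EBA", "happiness", "person", "body",
                                subject = s)$z
    if (ps > pf && ps > pb) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("category-emotion ANOVA agrees with aov and rejects imbalance", {
  set.seed(5)
  subj <- sprintf("S%02d", 1:12)
  tab <- expand.grid(subject = subj, emotion = emotion_levels(),
                     cat_b = c("face", "synthetic"), stringsAsFactors = FALSE)
  tab$cat_a <- "person"
  tab$z <- rnorm(nrow(tab), sd = 0.3) +
    ifelse(tab$cat_b == "synthetic", 0.5, 0)
  res <- category_emotion_anova(tab, "person_face_vs_synthetic")
  expect_identical(res$effect, c("Category", "Emotion", "Category:Emotion"))
  # cross-check all three F values against a direct aov fit
  d <- tab
  d$category <- paste0("person_", d$cat_b)
  fit <- summary(stats::aov(z ~ category * emotion +
                              Error(factor(subject) / (category * emotion)),
                            data = d))
  f_cat <- fit$`Error: factor(subject):category`[[1]]$`F value`[1]
  expect_equal(res$F[res$effect == "Category"], f_cat, tolerance = 1e-10)
  expect_lt(res$p[res$effect == "Category"], 0.01)

  expect_error(category_emotion_anova(tab[-1, ], "person_face_vs_synthetic"),
               "unbalanced")
})

test_that("a constant table yields an explicit degenerate ANOVA result", {
  subj <- sprintf("S%02d", 1:6)
  tab <- expand.grid(subject = subj, emotion = emotion_levels(),
                     cat_b = c("face", "synthetic"), stringsAsFactors = FALSE)
  tab$cat_a <- "person"
  tab$z <- 1
  expect_warning(res <- category_emotion_anova(tab, "person_face_vs_synthetic"),
                 "undefined")
  expect_true(all(is.na(res$F)))
})

test_that("the Category null test is calibrated near the nominal 5% level", {
  n_rep <- 400
  subj <- sprintf("S%02d", 1:10)
  grid <- expand.grid(subject = subj, emotion = emotion_levels(),
                      cat_b = c("face", "synthetic"), stringsAsFactors = FALSE)
  grid$cat_a <- "person"
  set.seed(77)
  rejections <- 0
  for (i in seq_len(n_rep)) {
    grid$z <- rnorm(nrow(grid))
    res <- category_emotion_anova(grid, "person_face_vs_synthetic")
    if (res$p[res$effect == "Category"] < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_rep
  expect_lt(abs(rate - 0.05), 0.03)
})
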