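# brute-force oracle: recompute the 101 correlations with a plain loop
brute_force_curve <- function(f, b, p) {
  vapply(seq(0, 1, by = 0.01), function(a) {
    w <- a * f + (1 - a) * b
    atanh(min(max(stats::cor(w, p), -(1 - 1e-7)), 1 - 1e-7))
  }, numeric(1))
}

brute_force_argmax <- function(f, b, p) {
  z <- brute_force_curve(f, b, p)
  seq(0, 1, by = 0.01)[which.max(z)]
}

test_that("weighted mean endpoints, consistency and hand arithmetic", {
  f <- rnorm(20); b <- rnorm(20)
  expect_identical(weighted_mean(f, b, 0), b)
  expect_identical(weighted_mean(f, b, 1), f)
  expect_equal(weighted_mean(c(2, 0), c(0, 2), 0.25), c(0.5, 1.5))
  expect_error(weighted_mean(f, b, 1.1), "\\[0, 1\\]")
  expect_error(weighted_mean(f, b, -0.1), "\\[0, 1\\]")
})

test_that("run averaging is the elementwise mean and checks run presence", {
  v <- rnorm(8)
  ds <- manual_pattern_dataset(function(s, r, cn) {
    if (cn != "face_anger") return(rnorm(8))
    switch(r, v, -v, rep(0, 8))
  }, n_voxels = 8)
  expect_equal(average_across_runs(ds, "S01", "EBA", "face_anger"),
               rep(0, 8))
  ds2 <- manual_pattern_dataset(function(s, r, cn) v, n_voxels = 8)
  expect_equal(average_across_runs(ds2, "S01", "EBA", "body_fear"), v)
  expect_error(average_across_runs(ds2, "S01", "EBA", "body_fear", runs = 1:5),
               "not present")
  # noiseless generated data: run average equals the template
  cfg <- small_config(sigma_noise = 0)
  dsg <- generate_condition_patterns(cfg)
  expect_equal(average_across_runs(dsg, "S01", "EBA", "person_fear"),
               unname(dsg$templates$EBA["S01", "person_fear", ]))
})

test_that("a noiseless convex construction peaks at the generating alpha", {
  set.seed(8)
  f <- rnorm(200); b <- rnorm(200)
  p <- 0.3 * f + 0.7 * b
  curve <- weight_curve(f, b, p)
  expect_equal(nrow(curve), 101)
  opt <- optimal_alpha(curve)
  expect_equal(opt$alpha_hat, 0.30)
  expect_equal(opt$beta_hat, 0.70)
  expect_equal(opt$z_max, atanh(1 - 1e-7))
})

test_that("face = body gives a constant curve with a full tie", {
  v <- rnorm(50)
  p <- v + rnorm(50, sd = 0.1)
  curve <- weight_curve(v, v, p)
  expect_true(all(abs(curve$z - curve$z[1]) < 1e-12))
  opt <- optimal_alpha(curve)
  expect_equal(opt$alpha_hat, 0)
  expect_equal(opt$tie_count, 101)
})

test_that("tie-breaking picks the smallest grid alpha", {
  curve <- structure(data.frame(alpha = seq(0, 1, by = 0.01),
                                r = 0.1, z = 0.1, flagged = FALSE),
                     class = c("weight_curve", "data.frame"))
  curve$z[curve$alpha %in% c(0.30, 0.31)] <- 0.9
  curve$r[curve$alpha %in% c(0.30, 0.31)] <- tanh(0.9)
  opt <- optimal_alpha(curve)
  expect_equal(opt$alpha_hat, 0.30)
  expect_equal(opt$tie_count, 2)

  # constructed strictly concave curve peaking at 0.42
  curve2 <- curve
  curve2$z <- -(curve2$alpha - 0.42)^2
  expect_equal(optimal_alpha(curve2)$alpha_hat, 0.42)
})

test_that("zero-variance weighted patterns are flagged and excluded", {
  f <- c(1, -1, 2, -2)
  b <- -f
  p <- c(1, 2, 3, 4)
  curve <- weight_curve(f, b, p)   # alpha = 0.5 collapses to the zero vector
  expect_true(curve$flagged[curve$alpha == 0.5])
  opt <- optimal_alpha(curve)
  expect_true(opt$alpha_hat != 0.5)
  expect_true(is.finite(opt$z_max))
  all_flagged <- curve
  all_flagged$flagged <- TRUE
  expect_error(optimal_alpha(all_flagged), "flagged")
})

test_that("the grid argmax matches exhaustive brute force on random instances", {
  set.seed(100)
  for (i in 1:100) {
    f <- rnorm(40); b <- rnorm(40)
    p <- runif(1) * f + runif(1) * b + rnorm(40, sd = 0.5)
    curve <- weight_curve(f, b, p)
    expect_equal(curve$z, brute_force_curve(f, b, p), tolerance = 1e-12)
    expect_identical(optimal_alpha(curve)$alpha_hat, brute_force_argmax(f, b, p))
  }
})

test_that("the weight curve is invariant to positive rescaling", {
  set.seed(12)
  f <- rnorm(60); b <- rnorm(60); p <- 0.4 * f + 0.6 * b + rnorm(60, sd = 0.3)
  base <- weight_curve(f, b, p)
  for (k in c(0.01, 3, 250)) {
    scaled <- weight_curve(k * f, k * b, k * p)
    expect_equal(scaled$z, base$z, tolerance = 1e-10)
  }
})

test_that("one-sample test against 0.5 matches the closed form", {
  res <- test_alpha_vs_half(rep(0.5, 6))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  w <- c(0.4, 0.45, 0.35, 0.5, 0.4)
  res2 <- test_alpha_vs_half(w)
  # hand computation: mean 0.42, sd sqrt(0.00325), t = -0.08/(sd/sqrt(5))
  expect_equal(res2$t, -3.137858, tolerance = 1e-5)
  expect_equal(res2$df, 4)
  expect_equal(res2$p, 2 * stats::pt(-3.137858, 4), tolerance = 1e-5)

  expect_warning(res3 <- test_alpha_vs_half(rep(0.4, 5)), "zero variance")
  expect_true(res3$degenerate)
  expect_error(test_alpha_vs_half(0.5), "at least 2")
})

test_that("weight recovery is accurate at the calibrated noise level", {
  cfg <- scenario_config(n_subjects = 12, n_voxels = 600, roi_names = "EBA",
                         alpha_true = c(happiness = 0.35, anger = 0.5,
                                        fear = 0.65),
                         sigma_noise = 0.4, seed = 19L)
  ds <- generate_condition_patterns(cfg)
  wt <- weight_table(ds)
  for (e in emotion_levels()) {
    m <- mean(wt$alpha_hat[wt$emotion == e])
    expect_lt(abs(m - cfg$alpha_true[[e]]), 0.05)
  }
})

test_that("emotion-by-ROI ANOVA detects an injected emotion offset", {
  make_wtab <- function(offset = 0, seed = 1) {
    set.seed(seed)
    grid <- expand.grid(subject = sprintf("S%02d", 1:12),
                        roi = c("OFA", "EBA", "STS", "FG"),
                        emotion = emotion_levels(), stringsAsFactors = FALSE)
    grid$beta_hat <- 0.5 + rnorm(nrow(grid), sd = 0.08) +
      ifelse(grid$emotion == "fear", offset, 0)
    grid
  }
  null_res <- emotion_roi_anova(make_wtab(0))
  expect_identical(null_res$anova$effect, c("Emotion", "ROI", "Emotion:ROI"))
  eff_res <- emotion_roi_anova(make_wtab(0.1))
  expect_lt(eff_res$anova$p[eff_res$anova$effect == "Emotion"], 0.01)
  # paired comparisons pool subject x ROI cells: df = 12*4 - 1
  expect_true(all(eff_res$emotion_pairs$df == 47))
  expect_true(all(eff_res$roi_pairs$df == 35))

  single <- make_wtab(0)
  single <- single[single$roi == "EBA", ]
  expect_error(emotion_roi_anova(single), "2 levels")
})

test_that("the emotion-by-ROI null ANOVA is calibrated near 5%", {
  grid <- expand.grid(subject = sprintf("S%02d", 1:10),
                      roi = c("OFA", "EBA", "STS", "FG"),
                      emotion = emotion_levels(), stringsAsFactors = FALSE)
  set.seed(55)
  n_rep <- 300
  rej_emotion <- 0
  rej_roi <- 0
  for (i in seq_len(n_rep)) {
    grid$beta_hat <- rnorm(nrow(grid))
    an <- rm_anova_within(grid, "emotion", "roi", value = "beta_hat")
    if (an$p[1] < 0.05) rej_emotion <- rej_emotion + 1
    if (an$p[2] < 0.05) rej_roi <- rej_roi + 1
  }
  expect_lt(abs(rej_emotion / n_rep - 0.05), 0.035)
  expect_lt(abs(rej_roi / n_rep - 0.05), 0.035)
})
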