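#' z-score condition volumes per voxel per run
#'
#' Standardises every voxel's values to zero mean and unit (population) SD
#' over the volumes of each run. Zero-variance voxels are set to 0 with a
#' warning.
#'
#' @param vps A `volume_pattern_set` from [extract_condition_volumes()].
#' @return The z-scored `volume_pattern_set`.
#' @export
zscore_patterns <- function(vps) {
  stopifnot(inherits(vps, "volume_pattern_set"))
  n_flat <- 0L
  for (s in names(vps$data)) {
    for (rn in names(vps$data[[s]])) {
      for (roi in names(vps$data[[s]][[rn]])) {
        m <- vps$data[[s]][[rn]][[roi]]
        if (nrow(m) < 2) stop("need >= 2 volumes per run", call. = FALSE)
        mu <- colMeans(m)
        sd <- sqrt(colMeans(sweep(m, 2, mu)^2))
        flat <- sd == 0
        n_flat <- n_flat + sum(flat)
        sd[flat] <- 1
        z <- sweep(sweep(m, 2, mu), 2, sd, "/")
        z[, flat] <- 0
        vps$data[[s]][[rn]][[roi]] <- z
      }
    }
  }
  if (n_flat > 0) {
    warning(n_flat, " zero-variance voxel-run(s) set to 0")
  }
  vps$zscored <- TRUE
  vps
}

#' One-way ANOVA F statistics per voxel
#'
#' Vectorised one-way ANOVA of each column of `X` across the groups in
#' `labels`.
#'
#' @param X Sample x voxel matrix.
#' @param labels Group label per row.
#' @return List with vectors `F`, `p`, and degrees of freedom `df1`, `df2`.
#' @export
voxelwise_anova <- function(X, labels) {
  labels <- factor(labels)
  k <- nlevels(labels)
  if (k < 2) stop("need >= 2 groups for ANOVA", call. = FALSE)
  n <- nrow(X)
  grand <- colMeans(X)
  ssb <- numeric(ncol(X))
  for (g in levels(labels)) {
    rows <- labels == g
    ssb <- ssb + sum(rows) * (colMeans(X[rows, , drop = FALSE]) - grand)^2
  }
  sst <- colSums(sweep(X, 2, grand)^2)
  ssw <- sst - ssb
  df1 <- k - 1
  df2 <- n - k
  F <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  list(F = F, p = p, df1 = df1, df2 = df2)
}

#' ANOVA feature selection on the training runs
#'
#' Selects voxels whose one-way ANOVA across all condition labels of the
#' training runs (all nine conditions of runs 1-3) is significant at
#' `p_threshold`. The mask is derived from training data only.
#'
#' @param vps A (z-scored) `volume_pattern_set`.
#' @param subject,roi Cell selectors.
#' @param p_threshold Selection threshold (default 0.05).
#' @param train_runs Training runs (default 1:3).
#' @return Logical voxel mask. Raises an error if no voxel survives.
#' @export
anova_feature_select <- function(vps, subject, roi, p_threshold = 0.05,
                                 train_runs = 1:3) {
  run_names <- paste0("run", train_runs)
  X <- do.call(rbind, lapply(run_names, function(rn)
    vps$data[[subject]][[rn]][[roi]]))
  labels <- unlist(lapply(run_names, function(rn) vps$labels[[rn]]))
  res <- voxelwise_anova(X, labels)
  mask <- is.finite(res$F) & res$p < p_threshold
  if (!any(mask)) {
    stop(sprintf("feature selection left no voxels (subject %s, ROI %s)",
                 subject, roi), call. = FALSE)
  }
  mask
}

lookup_alpha <- function(alpha_table, subject, roi, emotion) {
  row <- alpha_table$subject == subject & alpha_table$roi == roi &
    alpha_table$emotion == emotion
  if (sum(row) != 1) {
    stop(sprintf("missing optimal weight for subject %s, ROI %s, emotion %s",
                 subject, roi, emotion), call. = FALSE)
  }
  alpha_table$alpha_hat[row]
}

#' Build a labeled training set of one pattern type
#'
#' Assembles per-emotion training exemplars from the training runs. For
#' `face` and `body` the exemplars are that body type's condition volumes.
#' For `mean` and `weighted_mean` the k-th face volume and k-th body volume
#' of the same run and emotion (in acquisition order) are combined
#' volume-wise as `alpha * face + (1 - alpha) * body`, with `alpha = 0.5`
#' for `mean` and the subject's optimal face weight for `weighted_mean`.
#'
#' @param vps A (z-scored) `volume_pattern_set`.
#' @param subject,roi Cell selectors.
#' @param type One of `"face"`, `"body"`, `"mean"`, `"weighted_mean"`.
#' @param alpha_table For `weighted_mean`: data.frame with columns
#'   `subject`, `roi`, `emotion`, `alpha_hat` (a [weight_table()] result).
#' @param train_runs Training runs (default 1:3).
#' @return List with `X` (exemplar x voxel) and `y` (emotion factor).
#' @export
build_training_patterns <- function(vps, subject, roi,
                                    type = c("face", "body", "mean",
                                             "weighted_mean"),
                                    alpha_table = NULL, train_runs = 1:3) {
  type <- match.arg(type)
  if (type == "weighted_mean" && is.null(alpha_table)) {
    stop("weighted_mean training requires `alpha_table` with optimal weights",
         call. = FALSE)
  }
  run_names <- paste0("run", train_runs)
  conds <- conditions_table()
  Xs <- list()
  ys <- list()
  k <- 0
  for (rn in run_names) {
    m <- vps$data[[subject]][[rn]][[roi]]
    lab <- vps$labels[[rn]]
    for (e in emotion_levels()) {
      if (type %in% c("face", "body")) {
        rows <- lab == condition_name(type, e)
        ex <- m[rows, , drop = FALSE]
      } else {
        f <- m[lab == condition_name("face", e), , drop = FALSE]
        b <- m[lab == condition_name("body", e), , drop = FALSE]
        if (nrow(f) != nrow(b)) {
          stop("face and body volume counts differ; cannot pair volume-wise",
               call. = FALSE)
        }
        a <- if (type == "mean") 0.5 else
          lookup_alpha(alpha_table, subject, roi, e)
        ex <- a * f + (1 - a) * b
      }
      k <- k + 1
      Xs[[k]] <- ex
      ys[[k]] <- rep(e, nrow(ex))
    }
  }
  list(X = do.call(rbind, Xs),
       y = factor(unlist(ys), levels = emotion_levels()))
}

#' Run-4 whole-person test set
#'
#' Test exemplars: the whole-person condition volumes of run 4, labeled by
#' emotion, either volume-wise or averaged within block.
#'
#' @param vps A (z-scored) `volume_pattern_set`.
#' @param subject,roi Cell selectors.
#' @param aggregate `"volume"` (default) or `"block"` (average the volumes
#'   of each stimulus block into one exemplar).
#' @return List with `X` and `y` as in [build_training_patterns()].
#' @export
build_test_patterns <- function(vps, subject, roi,
                                aggregate = c("volume", "block")) {
  aggregate <- match.arg(aggregate)
  rn <- "run4"
  if (!rn %in% names(vps$data[[subject]])) {
    stop("run 4 not present; no independent test run", call. = FALSE)
  }
  m <- vps$data[[subject]][[rn]][[roi]]
  lab <- vps$labels[[rn]]
  emo <- sub("^person_", "", lab)
  if (aggregate == "block") {
    blk <- vps$blocks[[rn]]
    groups <- split(seq_along(lab), blk)
    X <- t(vapply(groups, function(i) colMeans(m[i, , drop = FALSE]),
                  numeric(ncol(m))))
    y <- vapply(groups, function(i) emo[i[1]], character(1))
    return(list(X = X, y = factor(y, levels = emotion_levels())))
  }
  list(X = m, y = factor(emo, levels = emotion_levels()))
}

#' Decode whole-person emotions with a linear SVM
#'
#' Trains a linear support-vector classifier (one-vs-one, cost 1, no
#' rescaling: inputs are already z-scored) on the masked training set and
#' returns the proportion of run-4 whole-person exemplars classified
#' correctly.
#'
#' @param train List with `X`, `y` from [build_training_patterns()].
#' @param test List with `X`, `y` from [build_test_patterns()].
#' @param mask Logical voxel mask from [anova_feature_select()].
#' @param cost SVM regularisation constant.
#' @return Proportion correct in `[0, 1]`.
#' @export
decode_person_emotions <- function(train, test, mask = NULL, cost = 1) {
  if (nlevels(droplevels(train$y)) < 2) {
    stop("training set contains a single class", call. = FALSE)
  }
  Xtr <- train$X
  Xte <- test$X
  if (!is.null(mask)) {
    if (!any(mask)) stop("empty feature mask", call. = FALSE)
    Xtr <- Xtr[, mask, drop = FALSE]
    Xte <- Xte[, mask, drop = FALSE]
  }
  fit <- e1071::svm(x = Xtr, y = train$y, kernel = "linear", cost = cost,
                    scale = FALSE)
  pred <- stats::predict(fit, Xte)
  mean(pred == test$y)
}

#' Permutation null for the decoder
#'
#' Retrains the classifier with permuted training labels.
#'
#' @inheritParams decode_person_emotions
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Numeric vector of null accuracies.
#' @export
permutation_null_accuracy <- function(train, test, mask = NULL, cost = 1,
                                      n_perm = 100, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n_perm), function(i) {
    shuffled <- list(X = train$X, y = sample(train$y))
    decode_person_emotions(shuffled, test, mask = mask, cost = cost)
  }, numeric(1))
}

#' Classification accuracies for all subjects, ROIs and training types
#'
#' Full decoding analysis: z-scores the volumes, selects features on the
#' training runs per subject and ROI, trains the four pattern-type
#' classifiers, and tests each on the run-4 whole-person volumes.
#'
#' @param vps A `volume_pattern_set` (raw; z-scoring is applied here).
#' @param alpha_table Optimal-weight table for `weighted_mean` (may be
#'   `NULL` to skip that type).
#' @param rois ROIs to analyse (default all).
#' @param types Training types to run.
#' @param p_threshold Feature-selection threshold.
#' @param cost SVM regularisation constant.
#' @param aggregate Test-exemplar aggregation (see [build_test_patterns()]).
#' @return data.frame with columns `subject`, `roi`, `type`, `accuracy`.
#' @export
classification_table <- function(vps, alpha_table = NULL, rois = vps$rois,
                                 types = c("face", "body", "mean",
                                           "weighted_mean"),
                                 p_threshold = 0.05, cost = 1,
                                 aggregate = "volume") {
  if (is.null(alpha_table)) types <- setdiff(types, "weighted_mean")
  vps <- zscore_patterns(vps)
  rows <- list()
  k <- 0
  for (roi in rois) {
    for (s in vps$subjects) {
      mask <- anova_feature_select(vps, s, roi, p_threshold = p_threshold)
      test <- build_test_patterns(vps, s, roi, aggregate = aggregate)
      for (ty in types) {
        train <- build_training_patterns(vps, s, roi, ty,
                                         alpha_table = alpha_table)
        acc <- decode_person_emotions(train, test, mask = mask, cost = cost)
        k <- k + 1
        rows[[k]] <- data.frame(subject = s, roi = roi, type = ty,
                                accuracy = acc, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Group test against chance with FDR correction
#'
#' One-sample t-test of each ROI x training-type accuracy distribution
#' against chance (1/3 for three balanced classes), with Benjamini-
#' Hochberg false-discovery-rate adjustment across all tests (7 ROIs x 4
#' types = 28 comparisons in the full design).
#'
#' @param acc A [classification_table()] result.
#' @param chance Chance accuracy (default 1/3).
#' @param q FDR significance level.
#' @param method Adjustment method passed to [stats::p.adjust()].
#' @return data.frame with one row per ROI x type: `roi`, `type`,
#'   `mean_accuracy`, `t`, `df`, `p`, `p_fdr`, `significant`.
#' @export
group_test_and_fdr <- function(acc, chance = chance_level(), q = 0.05,
                               method = "BH") {
  counts <- table(acc$roi, acc$type)
  if (any(counts != counts[1])) {
    stop("missing cells: every ROI x type needs the same subjects",
         call. = FALSE)
  }
  if (counts[1] < 2) stop("need >= 2 subjects", call. = FALSE)
  cells <- unique(acc[, c("roi", "type")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    a <- acc$accuracy[acc$roi == cells$roi[i] & acc$type == cells$type[i]]
    if (stats::sd(a) == 0) {
      t <- if (a[1] == chance) 0 else NA_real_
      p <- if (a[1] == chance) 1 else NA_real_
      return(data.frame(roi = cells$roi[i], type = cells$type[i],
                        mean_accuracy = mean(a), t = t,
                        df = length(a) - 1, p = p, stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(a, mu = chance)
    data.frame(roi = cells$roi[i], type = cells$type[i],
               mean_accuracy = mean(a), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  out$p_fdr <- stats::p.adjust(out$p, method = method)
  out$significant <- !is.na(out$p_fdr) & out$p_fdr < q
  out
}
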