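#' Convex weighted combination of face and body patterns
#'
#' `alpha * face + (1 - alpha) * body`, the synthetic weighted mean pattern
#' with total part weight constrained to 1 (face weight `alpha`, body
#' weight `1 - alpha`).
#'
#' @param face,body Numeric voxel vectors of equal length.
#' @param alpha Face weight in `[0, 1]`.
#' @export
weighted_mean <- function(face, body, alpha) {
  if (length(face) != length(body)) {
    stop("face and body patterns differ in length", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  alpha * face + (1 - alpha) * body
}

#' Face-weight grid
#' @return The 101-point grid 0.00, 0.01, ..., 1.00.
#' @export
alpha_grid <- function() seq(0, 1, by = 0.01)

#' Correlation profile over the face-weight grid
#'
#' For each grid value of the face weight `alpha`, correlates the weighted
#' combination `alpha * face + (1 - alpha) * body` with the (run-averaged)
#' whole-person pattern, and Fisher-z transforms the correlation. Grid
#' points at which the weighted pattern has zero variance are flagged and
#' excluded from later argmax computation.
#'
#' @param face_avg,body_avg,person_avg Run-averaged voxel patterns.
#' @return A `weight_curve`: data.frame columns `alpha`, `r`, `z`,
#'   `flagged`.
#' @export
weight_curve <- function(face_avg, body_avg, person_avg) {
  if (length(face_avg) != length(body_avg) ||
      length(face_avg) != length(person_avg)) {
    stop("patterns differ in length", call. = FALSE)
  }
  if (stats::sd(person_avg) == 0) {
    stop("person pattern has zero variance", call. = FALSE)
  }
  alphas <- alpha_grid()
  W <- outer(face_avg, alphas) + outer(body_avg, 1 - alphas)
  sds <- apply(W, 2, stats::sd)
  flagged <- sds == 0
  r <- rep(NA_real_, length(alphas))
  r[!flagged] <- as.numeric(stats::cor(W[, !flagged, drop = FALSE], person_avg))
  structure(data.frame(alpha = alphas, r = r,
                       z = ifelse(flagged, NA_real_, fisher_z(r)),
                       flagged = flagged),
            class = c("weight_curve", "data.frame"))
}

#' Optimal face weight of a weight curve
#'
#' Smallest grid `alpha` attaining the maximum correlation; the number of
#' grid points tied at the maximum is reported. Ties are detected within an
#' absolute tolerance of 1e-12 on z, so analytically constant curves whose
#' grid values differ only by floating-point rounding count as full ties.
#' Since the Fisher z transform is strictly increasing the argmax over z
#' equals the argmax over r.
#'
#' @param curve A [weight_curve()].
#' @return List with `alpha_hat`, `beta_hat = 1 - alpha_hat`, `z_max`,
#'   `r_max`, `tie_count`.
#' @export
optimal_alpha <- function(curve) {
  ok <- !curve$flagged & is.finite(curve$z)
  if (!any(ok)) stop("all grid points flagged; no optimum", call. = FALSE)
  z_max <- max(curve$z[ok])
  at_max <- which(ok & curve$z >= z_max - 1e-12)
  list(alpha_hat = curve$alpha[at_max[1]],
       beta_hat = 1 - curve$alpha[at_max[1]],
       z_max = z_max,
       r_max = curve$r[at_max[1]],
       tie_count = length(at_max))
}

#' Weight optimisation across a pattern dataset
#'
#' Runs the full optimisation per subject, ROI and emotion: average the
#' face, body and person patterns across runs 1-3, sweep the face weight
#' over the 0.01 grid, and record the optimum.
#'
#' @param ds A `pattern_dataset` (generated patterns or GLM betas).
#' @param rois ROIs to analyse (default all).
#' @param runs Runs to average (default 1:3).
#' @param keep_curves Also return the full curves (columns as
#'   [weight_curve()] plus selectors).
#' @return data.frame with columns `subject`, `roi`, `emotion`,
#'   `alpha_hat`, `beta_hat`, `z_max`, `tie_count`; if `keep_curves`, a
#'   list with `optima` and `curves`.
#' @export
weight_table <- function(ds, rois = names(ds$values), runs = 1:3,
                         keep_curves = FALSE) {
  rows <- list()
  curves <- list()
  k <- 0
  for (roi in rois) {
    for (e in emotion_levels()) {
      for (s in ds$subjects) {
        f <- average_across_runs(ds, s, roi, condition_name("face", e), runs)
        b <- average_across_runs(ds, s, roi, condition_name("body", e), runs)
        p <- average_across_runs(ds, s, roi, condition_name("person", e), runs)
        cur <- weight_curve(f, b, p)
        opt <- optimal_alpha(cur)
        k <- k + 1
        rows[[k]] <- data.frame(subject = s, roi = roi, emotion = e,
                                alpha_hat = opt$alpha_hat,
                                beta_hat = opt$beta_hat, z_max = opt$z_max,
                                tie_count = opt$tie_count,
                                stringsAsFactors = FALSE)
        if (keep_curves) {
          cur$subject <- s; cur$roi <- roi; cur$emotion <- e
          curves[[k]] <- cur
        }
      }
    }
  }
  optima <- do.call(rbind, rows)
  if (keep_curves) {
    list(optima = optima, curves = do.call(rbind, curves))
  } else {
    optima
  }
}

#' One-sample t-test of optimal weights against 0.5
#'
#' Two-sided test of whether a set of per-subject optimal weights (face or
#' body) differs from the equal-weight value 0.5.
#'
#' @param weights Numeric vector of per-subject weights.
#' @return List with `t`, `df`, `p`, `mean`, `degenerate` (`TRUE` when the
#'   weights have zero variance, in which case `t`/`p` are `NA` unless all
#'   weights equal 0.5 exactly, which gives `t = 0`, `p = 1`).
#' @export
test_alpha_vs_half <- function(weights) {
  if (length(weights) < 2) stop("need at least 2 subjects", call. = FALSE)
  if (stats::sd(weights) == 0) {
    if (weights[1] == 0.5) {
      return(list(t = 0, df = length(weights) - 1, p = 1,
                  mean = 0.5, degenerate = TRUE))
    }
    warning("zero variance in weights; t undefined")
    return(list(t = NA_real_, df = length(weights) - 1, p = NA_real_,
                mean = mean(weights), degenerate = TRUE))
  }
  tt <- stats::t.test(weights, mu = 0.5)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(weights), degenerate = FALSE)
}

#' Emotion-by-ROI ANOVA on optimal body weights
#'
#' 3 (Emotion) x k (ROI) repeated-measures ANOVA on per-subject optimal
#' body weights, with paired follow-up comparisons between emotions
#' (pooling subject x ROI observations) and between ROIs (pooling subject
#' x emotion observations), plus the same comparisons per level.
#'
#' @param wtab A [weight_table()] result (or any data.frame with columns
#'   `subject`, `roi`, `emotion`, `beta_hat`).
#' @return List with `anova` (effects table), `emotion_pairs`,
#'   `roi_pairs` (pooled paired t-tests), `emotion_pairs_by_roi`.
#' @export
emotion_roi_anova <- function(wtab) {
  need <- c("subject", "roi", "emotion", "beta_hat")
  if (!all(need %in% names(wtab))) {
    stop("weight table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(wtab$subject, wtab$roi, wtab$emotion)
  if (any(counts != 1)) {
    stop("unbalanced design: need one weight per subject x ROI x emotion",
         call. = FALSE)
  }
  an <- rm_anova_within(wtab, "emotion", "roi", value = "beta_hat")
  an$effect <- c("Emotion", "ROI", "Emotion:ROI")

  paired_t <- function(d, fac, other) {
    levs <- unique(d[[fac]])
    out <- list()
    k <- 0
    for (i in seq_along(levs)) {
      for (j in seq_along(levs)) {
        if (j <= i) next
        a <- d[d[[fac]] == levs[i], ]
        b <- d[d[[fac]] == levs[j], ]
        key <- c("subject", other)
        a <- a[do.call(order, a[key]), ]
        b <- b[do.call(order, b[key]), ]
        tt <- stats::t.test(a$beta_hat, b$beta_hat, paired = TRUE)
        k <- k + 1
        out[[k]] <- data.frame(level_a = levs[i], level_b = levs[j],
                               mean_diff = mean(a$beta_hat - b$beta_hat),
                               t = unname(tt$statistic),
                               df = unname(tt$parameter), p = tt$p.value,
                               stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  }

  by_roi <- lapply(split(wtab, wtab$roi), paired_t, fac = "emotion",
                   other = character(0))
  list(anova = an,
       emotion_pairs = paired_t(wtab, "emotion", "roi"),
       roi_pairs = paired_t(wtab, "roi", "emotion"),
       emotion_pairs_by_roi = by_roi)
}
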