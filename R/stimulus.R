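#' Video clip container
#'
#' @param frames Numeric array `time x height x width` of luminance values
#'   in `[0, 255]`.
#' @param frame_rate Frames per second (default 25, the stimulus rate).
#' @return An object of class `video_clip`.
#' @export
video_clip <- function(frames, frame_rate = 25) {
  if (!is.array(frames) || length(dim(frames)) != 3) {
    stop("frames must be a time x height x width array", call. = FALSE)
  }
  if (dim(frames)[1] < 1) stop("need at least one frame", call. = FALSE)
  if (any(frames < 0 | frames > 255)) {
    stop("luminance values must lie in [0, 255]", call. = FALSE)
  }
  structure(list(frames = frames, frame_rate = frame_rate),
            class = "video_clip")
}

#' Inter-frame movement score of a clip
#'
#' For each pair of adjacent frames, takes the absolute luminance
#' difference per pixel and averages it over the pixels whose difference
#' exceeds `threshold` (on the 0-255 scale); frame pairs with no
#' supra-threshold pixel contribute 0. The per-pair scores are then
#' averaged over the clip.
#'
#' @param clip A [video_clip()].
#' @param threshold Difference threshold (default 10).
#' @return Movement score (luminance units), `>= 0`.
#' @export
movement_score <- function(clip, threshold = 10) {
  f <- clip$frames
  n <- dim(f)[1]
  if (n < 2) stop("movement needs at least two frames", call. = FALSE)
  per_pair <- vapply(seq_len(n - 1), function(i) {
    d <- abs(f[i + 1, , ] - f[i, , ])
    supra <- d > threshold
    if (!any(supra)) 0 else mean(d[supra])
  }, numeric(1))
  mean(per_pair)
}

#' RMS contrast of a clip
#'
#' Population standard deviation of pixel luminance within each frame,
#' averaged over frames.
#'
#' @param clip A [video_clip()].
#' @return Contrast (luminance units), `>= 0`.
#' @export
rms_contrast <- function(clip) {
  f <- clip$frames
  per_frame <- vapply(seq_len(dim(f)[1]), function(i) {
    x <- f[i, , ]
    sqrt(mean((x - mean(x))^2))
  }, numeric(1))
  mean(per_frame)
}

#' Mean luminance of a clip
#'
#' Mean over all pixels and frames.
#'
#' @param clip A [video_clip()].
#' @export
mean_luminance <- function(clip) mean(clip$frames)

#' All three statistics of one clip
#'
#' @param clip A [video_clip()].
#' @param threshold Movement threshold.
#' @return data.frame with `movement`, `contrast`, `luminance`.
#' @export
clip_stats <- function(clip, threshold = 10) {
  data.frame(movement = movement_score(clip, threshold),
             contrast = rms_contrast(clip),
             luminance = mean_luminance(clip))
}

#' Compare clip statistics between stimulus groups
#'
#' Pairwise t-tests between groups (paired when group sizes match and
#' `paired = TRUE`, e.g. emotion triplets of matched scenarios) for each
#' statistic, plus a one-way ANOVA across groups.
#'
#' @param stats data.frame of per-clip statistics (one column per
#'   statistic).
#' @param groups Group label per clip.
#' @param paired Use paired t-tests (clips matched by within-group order).
#' @return List with `pairwise` (data.frame: `statistic`, `group_a`,
#'   `group_b`, `t`, `df`, `p`) and `anova` (data.frame: `statistic`, `F`,
#'   `df1`, `df2`, `p`).
#' @export
compare_groups <- function(stats, groups, paired = TRUE) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) stop("need >= 2 clips per group", call. = FALSE)
  if (paired && length(unique(table(groups))) != 1) {
    stop("paired comparison needs equal group sizes", call. = FALSE)
  }
  levs <- levels(groups)
  pw <- list()
  an <- list()
  k <- 0
  for (st in names(stats)) {
    x <- stats[[st]]
    for (i in seq_along(levs)) {
      for (j in seq_along(levs)) {
        if (j <= i) next
        a <- x[groups == levs[i]]
        b <- x[groups == levs[j]]
        tt <- if (isTRUE(all.equal(a, b))) {
          list(statistic = 0, parameter = length(a) - 1, p.value = 1)
        } else {
          stats::t.test(a, b, paired = paired)
        }
        k <- k + 1
        pw[[k]] <- data.frame(statistic = st, group_a = levs[i],
                              group_b = levs[j], t = unname(tt$statistic),
                              df = unname(tt$parameter), p = tt$p.value,
                              stringsAsFactors = FALSE)
      }
    }
    fit <- stats::oneway.test(x ~ groups, var.equal = TRUE)
    an[[st]] <- data.frame(statistic = st, F = unname(fit$statistic),
                           df1 = unname(fit$parameter[1]),
                           df2 = unname(fit$parameter[2]), p = fit$p.value,
                           stringsAsFactors = FALSE)
  }
  list(pairwise = do.call(rbind, pw), anova = do.call(rbind, an))
}
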