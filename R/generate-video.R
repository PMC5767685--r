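#' Generate a synthetic grayscale video clip
#'
#' Builds a frame stack with programmable inter-frame changes, for
#' exercising the stimulus-statistics functions without real video
#' material. Starting from a base frame (a constant value or a random
#' texture), each subsequent frame optionally applies listed single-pixel
#' steps and/or an independent random perturbation.
#'
#' @param height,width Frame dimensions (`>= 1`).
#' @param n_frames Number of frames (`>= 1`).
#' @param base Either a single luminance value in `[0, 255]` used for a
#'   constant base frame, or `"random"` for a uniform random texture.
#' @param changes `NULL` for a static clip, or a data.frame with columns
#'   `frame` (the later frame of the pair), `row`, `col`, `delta`: pixel
#'   `(row, col)` changes by `delta` from frame `frame - 1` to `frame`
#'   (and stays at the new value).
#' @param jitter_sd SD of independent Gaussian per-pixel jitter added to
#'   every frame after the first (0 = none). Values are clamped to
#'   `[0, 255]`.
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @return A [video_clip()].
#' @export
generate_video <- function(height, width, n_frames, base = 24,
                           changes = NULL, jitter_sd = 0, seed = NULL) {
  if (height < 1 || width < 1 || n_frames < 1) {
    stop("dimensions must be >= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  first <- if (identical(base, "random")) {
    matrix(stats::runif(height * width, 0, 255), height, width)
  } else {
    if (!is.numeric(base) || base < 0 || base > 255) {
      stop("base luminance must lie in [0, 255]", call. = FALSE)
    }
    matrix(base, height, width)
  }
  frames <- array(0, dim = c(n_frames, height, width))
  cur <- first
  frames[1, , ] <- cur
  for (k in seq_len(n_frames)[-1]) {
    if (jitter_sd > 0) {
      cur <- cur + matrix(stats::rnorm(height * width, sd = jitter_sd),
                          height, width)
    }
    if (!is.null(changes)) {
      step <- changes[changes$frame == k, , drop = FALSE]
      for (i in seq_len(nrow(step))) {
        cur[step$row[i], step$col[i]] <- cur[step$row[i], step$col[i]] +
          step$delta[i]
      }
    }
    cur <- pmin(pmax(cur, 0), 255)
    frames[k, , ] <- cur
  }
  if (any(frames < 0 | frames > 255)) {
    stop("luminance outside [0, 255] after applying changes", call. = FALSE)
  }
  video_clip(frames)
}

#' Generate a corpus of synthetic clips with emotion labels
#'
#' Emulates the stimulus set's structure: `n_per_emotion` clips for each of
#' the three emotions (72 clips for the default 24), all drawn from the
#' same generative distribution (random texture plus per-frame jitter), so
#' group comparisons are null by construction unless `emotion_shift`
#' offsets one group's luminance.
#'
#' @param n_per_emotion Clips per emotion.
#' @param height,width,n_frames Clip dimensions.
#' @param jitter_sd Per-frame jitter SD.
#' @param emotion_shift Named numeric vector of luminance offsets per
#'   emotion (default none).
#' @param seed Integer seed.
#' @return List with `clips` (list of [video_clip()]) and `emotion`
#'   (label per clip).
#' @export
generate_clip_corpus <- function(n_per_emotion = 24, height = 8, width = 8,
                                 n_frames = 50, jitter_sd = 4,
                                 emotion_shift = NULL, seed = 1L) {
  set.seed(seed)
  emotions <- rep(emotion_levels(), each = n_per_emotion)
  clips <- lapply(emotions, function(e) {
    shift <- if (!is.null(emotion_shift) && e %in% names(emotion_shift)) {
      emotion_shift[[e]]
    } else {
      0
    }
    base <- matrix(stats::runif(height * width, 60, 180) + shift,
                   height, width)
    frames <- array(0, dim = c(n_frames, height, width))
    cur <- base
    frames[1, , ] <- pmin(pmax(cur, 0), 255)
    for (k in seq_len(n_frames)[-1]) {
      cur <- cur + matrix(stats::rnorm(height * width, sd = jitter_sd),
                          height, width)
      cur <- pmin(pmax(cur, 0), 255)
      frames[k, , ] <- cur
    }
    video_clip(frames)
  })
  list(clips = clips, emotion = emotions)
}
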