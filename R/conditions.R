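#' Experimental condition layout
#'
#' The experiment crosses three body types (isolated face, isolated body,
#' whole person) with three emotions (happiness, anger, fear), giving nine
#' stimulus conditions. Runs 1-3 present all nine; run 4 presents only the
#' three whole-person conditions so that classifier test data stay
#' independent of the training runs.
#'
#' @return A data.frame with columns `condition`, `body_type`, `emotion`.
#' @export
conditions_table <- function() {
  body_types <- c("face", "body", "person")
  emotions <- c("happiness", "anger", "fear")
  grid <- expand.grid(body_type = body_types, emotion = emotions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$condition <- paste(grid$body_type, grid$emotion, sep = "_")
  grid[, c("condition", "body_type", "emotion")]
}

#' @rdname conditions_table
#' @export
emotion_levels <- function() c("happiness", "anger", "fear")

#' @rdname conditions_table
#' @export
body_type_levels <- function() c("face", "body", "person")

#' Similarity-analysis categories
#'
#' The four pattern categories compared in the representational similarity
#' analysis: face, body, whole person, and the synthetic mean (the
#' elementwise average of the face and body patterns).
#'
#' @export
category_levels <- function() c("face", "body", "person", "synthetic")

#' Default region-of-interest labels
#'
#' Seven face-, body- and both-selective regions. ROIs are opaque labels
#' here: each is simulated as an independent voxel set.
#'
#' @export
default_rois <- function() c("AMG", "IFG", "OFA", "EBA", "STS", "FG", "insula")

#' Chance accuracy for balanced three-class decoding
#' @export
chance_level <- function() 1 / 3

condition_name <- function(body_type, emotion) paste(body_type, emotion, sep = "_")

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}
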