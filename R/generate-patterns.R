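#' Generate per-condition voxel patterns under a representation scenario
#'
#' Draws, for every subject and ROI, a face template and a body template per
#' emotion (standard normal across voxels, with between-emotion correlation
#' `rho_emotion` induced by mixing a shared and an idiosyncratic component),
#' builds the whole-person template as
#' `gamma * (alpha * face + (1 - alpha) * body) + (1 - gamma) * u`
#' with `u` an independent person-only component, and then adds independent
#' Gaussian run-level noise of SD `sigma_noise` to each template to produce
#' per-run patterns. Runs 1 to 3 contain all nine conditions; run 4 contains
#' only the three whole-person conditions (fresh noise on the same person
#' templates).
#'
#' @param config A [scenario_config()].
#' @return A `pattern_dataset`: per ROI, a numeric array with dimensions
#'   `subject x run x condition x voxel` (non-person cells of run 4 are
#'   `NA`), plus the noiseless templates and a config snapshot.
#' @export
generate_condition_patterns <- function(config) {
  if (!inherits(config, "scenario_config")) {
    stop("`config` must be a scenario_config", call. = FALSE)
  }
  conds <- conditions_table()
  emotions <- emotion_levels()
  V <- config$n_voxels
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  runs <- paste0("run", seq_len(config$n_runs))
  rho <- config$rho_emotion

  set.seed(config$seed)
  values <- list()
  templates <- list()
  for (roi in config$roi_names) {
    arr <- array(NA_real_,
                 dim = c(length(subjects), length(runs), nrow(conds), V),
                 dimnames = list(subject = subjects, run = runs,
                                 condition = conds$condition, voxel = NULL))
    tmpl <- array(NA_real_,
                  dim = c(length(subjects), nrow(conds), V),
                  dimnames = list(subject = subjects,
                                  condition = conds$condition, voxel = NULL))
    for (s in seq_along(subjects)) {
      # shared + idiosyncratic mixing keeps each template standard normal
      # while giving between-emotion correlation rho within a body type
      shared_f <- stats::rnorm(V)
      shared_b <- stats::rnorm(V)
      face <- body <- person <- list()
      for (e in emotions) {
        face[[e]] <- sqrt(rho) * shared_f + sqrt(1 - rho) * stats::rnorm(V)
        body[[e]] <- sqrt(rho) * shared_b + sqrt(1 - rho) * stats::rnorm(V)
      }
      for (e in emotions) {
        a <- config$alpha_true[[e]]
        u <- stats::rnorm(V)
        person[[e]] <- config$gamma * (a * face[[e]] + (1 - a) * body[[e]]) +
          (1 - config$gamma) * u
      }
      for (e in emotions) {
        tmpl[s, condition_name("face", e), ] <- face[[e]]
        tmpl[s, condition_name("body", e), ] <- body[[e]]
        tmpl[s, condition_name("person", e), ] <- person[[e]]
      }
      for (r in seq_along(runs)) {
        cond_here <- if (r == 4L) {
          conds$condition[conds$body_type == "person"]
        } else {
          conds$condition
        }
        for (cn in cond_here) {
          noise <- if (config$sigma_noise > 0) {
            stats::rnorm(V, sd = config$sigma_noise)
          } else {
            0
          }
          arr[s, r, cn, ] <- tmpl[s, cn, ] + noise
        }
      }
    }
    values[[roi]] <- arr
    templates[[roi]] <- tmpl
  }

  structure(list(
    values = values,
    templates = templates,
    conditions = conds,
    subjects = subjects,
    runs = runs,
    config = config
  ), class = "pattern_dataset")
}

#' Extract one voxel pattern from a pattern dataset
#'
#' @param ds A `pattern_dataset`.
#' @param subject Subject label or index.
#' @param run Run label (`"run1"`) or index.
#' @param roi ROI label.
#' @param condition Condition label (`"face_happiness"`), or `"synthetic_<emotion>"`
#'   for the within-run face/body average.
#' @return Numeric voxel vector.
#' @export
get_pattern <- function(ds, subject, run, roi, condition) {
  stopifnot(inherits(ds, "pattern_dataset"))
  arr <- ds$values[[roi]]
  if (is.null(arr)) stop("unknown ROI: ", roi, call. = FALSE)
  if (grepl("^synthetic_", condition)) {
    e <- sub("^synthetic_", "", condition)
    return(synthetic_mean(arr[subject, run, condition_name("face", e), ],
                          arr[subject, run, condition_name("body", e), ]))
  }
  v <- arr[subject, run, condition, ]
  if (anyNA(v)) {
    stop(sprintf("condition `%s` not present in %s", condition,
                 if (is.numeric(run)) paste0("run", run) else run),
         call. = FALSE)
  }
  v
}

#' Category pattern for the similarity analysis
#'
#' Maps a similarity category (`face`, `body`, `person`, `synthetic`) and an
#' emotion to the corresponding voxel pattern of one run. The synthetic mean
#' is computed within-run from that run's face and body patterns.
#'
#' @inheritParams get_pattern
#' @param category One of [category_levels()].
#' @param emotion One of [emotion_levels()].
#' @export
get_category_pattern <- function(ds, subject, run, roi, category, emotion) {
  category <- match.arg(category, category_levels())
  emotion <- match.arg(emotion, emotion_levels())
  cond <- if (category == "synthetic") {
    paste0("synthetic_", emotion)
  } else {
    condition_name(category, emotion)
  }
  get_pattern(ds, subject, run, roi, cond)
}

#' Average a condition's pattern across runs
#'
#' Elementwise mean of a condition's voxel pattern over the given runs
#' (by default runs 1-3, the runs that contain all nine conditions).
#'
#' @inheritParams get_pattern
#' @param runs Integer run indices to average over.
#' @export
average_across_runs <- function(ds, subject, roi, condition, runs = 1:3) {
  stopifnot(inherits(ds, "pattern_dataset"))
  if (any(runs > length(ds$runs))) {
    stop("requested runs not present in dataset", call. = FALSE)
  }
  mats <- vapply(runs, function(r) get_pattern(ds, subject, r, roi, condition),
                 numeric(dim(ds$values[[roi]])[4]))
  rowMeans(mats)
}

#' @export
print.pattern_dataset <- function(x, ...) {
  d <- dim(x$values[[1]])
  cat("<pattern_dataset>", d[1], "subjects x", d[2], "runs x",
      length(x$values), "ROIs x", d[4], "voxels\n")
  cat("  scenario:", x$config$scenario, "(gamma =", x$config$gamma, ")\n")
  invisible(x)
}
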