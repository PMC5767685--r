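#' Discard initial equilibration volumes
#'
#' Removes the first `n_discard` volumes of every run (data and nuisance)
#' and advances the dataset's time offset so that block onsets, which are
#' expressed in absolute run time, stay aligned with the retained volumes.
#'
#' @param ts A `timeseries_dataset`.
#' @param n_discard Number of initial volumes to drop; defaults to the
#'   design's `n_discard`.
#' @return The trimmed `timeseries_dataset`.
#' @export
discard_initial_volumes <- function(ts, n_discard = ts$design$n_discard) {
  stopifnot(inherits(ts, "timeseries_dataset"))
  if (n_discard == 0) return(ts)
  n_vol <- nrow(ts$data[[1]][[1]][[1]])
  if (n_discard >= n_vol) {
    stop(sprintf("cannot discard %d volumes from a %d-volume run",
                 n_discard, n_vol), call. = FALSE)
  }
  keep <- (n_discard + 1):n_vol
  for (s in names(ts$data)) {
    for (rn in names(ts$data[[s]])) {
      ts$data[[s]][[rn]] <- lapply(ts$data[[s]][[rn]],
                                   function(m) m[keep, , drop = FALSE])
      ts$nuisance[[s]][[rn]] <- ts$nuisance[[s]][[rn]][keep, , drop = FALSE]
    }
  }
  ts$time_offset_s <- ts$time_offset_s + n_discard * ts$design$tr_s
  ts
}

#' Acquisition times of the retained volumes
#' @param ts A `timeseries_dataset`.
#' @return Numeric vector of volume onset times (s from run start).
#' @export
volume_times <- function(ts) {
  n_vol <- nrow(ts$data[[1]][[1]][[1]])
  ts$time_offset_s + (seq_len(n_vol) - 1) * ts$design$tr_s
}

#' Build a GLM design matrix for one run
#'
#' One HRF-convolved boxcar column per condition present in the run, the
#' nuisance regressors and their temporal derivatives (first differences,
#' padded with 0), and an intercept. With the experiment's nine conditions
#' and eight nuisance series this gives 9 + 8 + 8 + 1 = 26 columns.
#' All-zero derivative columns (constant nuisance) are dropped with a
#' warning; all-zero condition columns are flagged with a warning; rank
#' deficiency raises an error naming the collinear columns.
#'
#' @param design A [design_spec()].
#' @param nuisance Volume x regressor matrix for the run (already trimmed
#'   to the retained volumes), or `NULL` for none.
#' @param run Run label or index.
#' @param time_offset_s Seconds already discarded from the run start.
#' @return A `design_matrix`: list with `X` (volume x regressor),
#'   `condition_cols`, `labels`.
#' @export
build_design_matrix <- function(design, nuisance = NULL, run = 1,
                                time_offset_s = 0) {
  Xc_full <- condition_regressors(design, run)
  n_skip <- round(time_offset_s / design$tr_s)
  rows <- (n_skip + 1):design$n_volumes
  Xc <- Xc_full[rows, , drop = FALSE]
  if (!is.null(nuisance) && nrow(nuisance) != nrow(Xc)) {
    stop("nuisance rows do not match retained volume count", call. = FALSE)
  }
  zero_cond <- colSums(abs(Xc)) == 0
  if (any(zero_cond)) {
    warning("all-zero condition column(s): ",
            paste(colnames(Xc)[zero_cond], collapse = ", "))
  }
  parts <- list(Xc)
  if (!is.null(nuisance) && ncol(nuisance) > 0) {
    deriv <- rbind(0, diff(nuisance))
    colnames(deriv) <- paste0("d_", colnames(nuisance))
    keep_d <- colSums(abs(deriv)) > 0
    if (!all(keep_d)) {
      warning("dropping all-zero derivative column(s): ",
              paste(colnames(deriv)[!keep_d], collapse = ", "))
    }
    parts <- c(parts, list(nuisance, deriv[, keep_d, drop = FALSE]))
  }
  X <- do.call(cbind, c(parts, list(intercept = rep(1, length(rows)))))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(X = X, condition_cols = colnames(Xc), labels = colnames(X)),
            class = "design_matrix")
}

#' Ordinary-least-squares beta patterns for one data matrix
#'
#' @param Y Volume x voxel data matrix.
#' @param dm A `design_matrix` (or plain matrix whose columns are all
#'   treated as conditions).
#' @return Regressor x voxel matrix of OLS coefficients, restricted to the
#'   condition columns.
#' @export
ols_betas <- function(Y, dm) {
  if (anyNA(Y) || any(!is.finite(Y))) {
    stop("time series contains non-finite values", call. = FALSE)
  }
  if (inherits(dm, "design_matrix")) {
    X <- dm$X
    cond <- dm$condition_cols
  } else {
    X <- dm
    cond <- colnames(dm)
  }
  if (nrow(X) != nrow(Y)) stop("design and data row counts differ", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  B <- qr.coef(qrX, Y)
  rownames(B) <- colnames(X)
  B[cond, , drop = FALSE]
}

#' Estimate per-condition beta patterns across a dataset
#'
#' Fits, for every subject, run and ROI, an OLS GLM with the run's
#' condition regressors, nuisance regressors, their temporal derivatives,
#' and an intercept, and collects the condition betas into a
#' `pattern_dataset` so the similarity and weight analyses can consume
#' them directly.
#'
#' @param ts A `timeseries_dataset` (typically after
#'   [discard_initial_volumes()]).
#' @param include_nuisance Include the stored nuisance regressors and their
#'   derivatives in the model.
#' @return A `pattern_dataset` of beta patterns.
#' @export
estimate_betas <- function(ts, include_nuisance = TRUE) {
  stopifnot(inherits(ts, "timeseries_dataset"))
  conds <- conditions_table()
  V <- ncol(ts$data[[1]][[1]][[1]])
  values <- list()
  for (roi in ts$rois) {
    values[[roi]] <- array(NA_real_,
                           dim = c(length(ts$subjects), length(ts$runs),
                                   nrow(conds), V),
                           dimnames = list(subject = ts$subjects, run = ts$runs,
                                           condition = conds$condition,
                                           voxel = NULL))
  }
  for (s in ts$subjects) {
    for (r in seq_along(ts$runs)) {
      rn <- ts$runs[r]
      nuis <- if (include_nuisance) ts$nuisance[[s]][[rn]] else NULL
      dm <- build_design_matrix(ts$design, nuis, run = rn,
                                time_offset_s = ts$time_offset_s)
      for (roi in ts$rois) {
        B <- ols_betas(ts$data[[s]][[rn]][[roi]], dm)
        values[[roi]][s, r, rownames(B), ] <- B
      }
    }
  }
  structure(list(
    values = values,
    templates = NULL,
    conditions = conds,
    subjects = ts$subjects,
    runs = ts$runs,
    config = list(provenance = "glm_betas", design = ts$design)
  ), class = "pattern_dataset")
}

#' Extract condition-labeled volumes from the time series
#'
#' Labels each retained volume with the condition of the stimulus block it
#' falls in after applying a hemodynamic shift: a volume acquired at time
#' `t` belongs to a block's condition when `t` lies in
#' `[stim_onset + shift, stim_end + shift)`. Fixation and response-window
#' volumes are left unlabeled. With the main-experiment design (two 20-s
#' stimulus blocks per condition per run, TR 2 s) every condition receives
#' exactly 20 volumes per run.
#'
#' The default shift of one TR (2 s) is the largest shift under which all
#' 18 blocks, including the last, keep their full 10 stimulus volumes
#' inside the acquired run; see the methods vignette.
#'
#' @param ts A `timeseries_dataset` after discarding initial volumes.
#' @param shift_s Hemodynamic shift (s), default 2 (one TR).
#' @return A `volume_pattern_set`: `data[[subject]][[run]][[roi]]` labeled
#'   volume x voxel matrices, `labels[[run]]` condition per retained row.
#' @export
extract_condition_volumes <- function(ts, shift_s = 2) {
  stopifnot(inherits(ts, "timeseries_dataset"))
  if (shift_s < 0) stop_config("shift_s", "must be >= 0")
  times <- volume_times(ts)
  run_end <- ts$design$n_blocks * ts$design$block_duration_s
  labels <- list()
  blocks <- list()
  keep_rows <- list()
  for (rn in ts$runs) {
    bt <- block_timing(ts$design, rn)
    if (any(bt$stim_end + shift_s > run_end)) {
      stop("shift pushes stimulus blocks past the end of the run", call. = FALSE)
    }
    lab <- rep(NA_character_, length(times))
    blk <- rep(NA_integer_, length(times))
    for (i in seq_len(nrow(bt))) {
      in_block <- times >= bt$stim_onset[i] + shift_s &
        times < bt$stim_end[i] + shift_s
      if (any(!is.na(lab[in_block]))) {
        stop("internal error: volume assigned to two conditions", call. = FALSE)
      }
      lab[in_block] <- bt$condition[i]
      blk[in_block] <- bt$block[i]
    }
    keep_rows[[rn]] <- which(!is.na(lab))
    labels[[rn]] <- lab[keep_rows[[rn]]]
    blocks[[rn]] <- blk[keep_rows[[rn]]]
  }
  data <- list()
  for (s in ts$subjects) {
    data[[s]] <- list()
    for (rn in ts$runs) {
      data[[s]][[rn]] <- lapply(ts$data[[s]][[rn]],
                                function(m) m[keep_rows[[rn]], , drop = FALSE])
    }
  }
  structure(list(
    data = data,
    labels = labels,
    blocks = blocks,
    subjects = ts$subjects,
    runs = ts$runs,
    rois = ts$rois,
    design = ts$design,
    shift_s = shift_s
  ), class = "volume_pattern_set")
}

#' Volumes per condition in a volume pattern set
#' @param vps A `volume_pattern_set`.
#' @param run Run label or index.
#' @export
volumes_per_condition <- function(vps, run = 1) {
  rn <- if (is.numeric(run)) paste0("run", run) else run
  table(vps$labels[[rn]])
}
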