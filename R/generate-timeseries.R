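#' Generate block-design voxel time series from condition patterns
#'
#' Forward model for the scanner data: each voxel's time course is the sum
#' over conditions of the condition's pattern amplitude times the
#' HRF-convolved stimulus boxcar, plus a nuisance contribution (eight
#' regressors emulating six head-motion parameters and mean white-matter and
#' CSF signals) and Gaussian noise, optionally AR(1)-correlated in time.
#' The full pre-discard timeline is generated so that discarding the
#' initial equilibration volumes reproduces the experiment's bookkeeping.
#'
#' The default `noise_sd = 8` puts the correlation between a single
#' stimulus volume's pattern and its generating template near 0.5 for
#' unit-variance templates, a moderate single-volume signal-to-noise
#' regime (see the methods vignette).
#'
#' @param patterns A `pattern_dataset` giving condition amplitudes.
#' @param design A [design_spec()] whose `condition_order` covers the
#'   dataset's conditions run by run.
#' @param noise_sd White-noise SD per voxel per volume.
#' @param seed Integer seed.
#' @param nuisance_scale SD of the per-voxel nuisance loadings; 0 removes
#'   the nuisance contribution (the regressors are still returned).
#' @param ar1 AR(1) coefficient for temporal noise correlation (0 = white).
#' @return A `timeseries_dataset`: `data[[subject]][[run]][[roi]]` volume x
#'   voxel matrices, `nuisance[[subject]][[run]]` volume x 8 matrices, the
#'   design, and `time_offset_s` (0 until volumes are discarded).
#' @export
generate_timeseries <- function(patterns, design, noise_sd = 8, seed = 1L,
                                nuisance_scale = 0.5, ar1 = 0) {
  stopifnot(inherits(patterns, "pattern_dataset"), inherits(design, "design_spec"))
  if (noise_sd < 0) stop_config("noise_sd", "must be >= 0")
  runs <- patterns$runs
  for (r in seq_along(runs)) {
    order_r <- design$condition_order[[runs[r]]]
    if (is.null(order_r)) {
      stop("design has no condition order for ", runs[r], call. = FALSE)
    }
    have <- available_conditions(patterns, r)
    if (!setequal(unique(order_r), have)) {
      stop(sprintf("condition order for %s does not match dataset conditions (%s vs %s)",
                   runs[r], paste(sort(unique(order_r)), collapse = ","),
                   paste(sort(have), collapse = ",")), call. = FALSE)
    }
  }

  V <- dim(patterns$values[[1]])[4]
  n_vol <- design$n_volumes
  set.seed(seed)
  X_cond <- lapply(seq_along(runs), function(r) condition_regressors(design, r))
  names(X_cond) <- runs

  data <- list()
  nuisance <- list()
  for (s in patterns$subjects) {
    data[[s]] <- list()
    nuisance[[s]] <- list()
    for (r in seq_along(runs)) {
      rn <- runs[r]
      nuis <- simulate_nuisance(n_vol)
      Xc <- X_cond[[rn]]
      data[[s]][[rn]] <- list()
      for (roi in names(patterns$values)) {
        A <- matrix(patterns$values[[roi]][s, r, colnames(Xc), ],
                    nrow = length(colnames(Xc)), ncol = V)
        Y <- Xc %*% A
        if (nuisance_scale > 0) {
          W <- matrix(stats::rnorm(ncol(nuis) * V, sd = nuisance_scale),
                      nrow = ncol(nuis))
          Y <- Y + nuis %*% W
        }
        if (noise_sd > 0) {
          eps <- matrix(stats::rnorm(n_vol * V, sd = noise_sd), nrow = n_vol)
          if (ar1 != 0) {
            eps <- apply(eps, 2, function(e) {
              as.numeric(stats::filter(e, ar1, method = "recursive")) * sqrt(1 - ar1^2)
            })
          }
          Y <- Y + eps
        }
        data[[s]][[rn]][[roi]] <- Y
      }
      nuisance[[s]][[rn]] <- nuis
    }
  }

  structure(list(
    data = data,
    nuisance = nuisance,
    design = design,
    subjects = patterns$subjects,
    runs = runs,
    rois = names(patterns$values),
    time_offset_s = 0,
    noise_sd = noise_sd,
    ar1 = ar1
  ), class = "timeseries_dataset")
}

#' Conditions present in a run of a pattern dataset
#' @keywords internal
available_conditions <- function(patterns, run) {
  arr <- patterns$values[[1]]
  conds <- dimnames(arr)$condition
  conds[!is.na(arr[1, run, , 1])]
}

#' Simulated nuisance regressors
#'
#' Six slow random-walk series standing in for head-motion parameters and
#' two low-frequency drift series standing in for mean white-matter and CSF
#' signals, each standardised to zero mean and unit SD.
#'
#' @param n_vol Number of volumes.
#' @return `n_vol x 8` matrix with named columns.
#' @export
simulate_nuisance <- function(n_vol) {
  motion <- vapply(1:6, function(i) cumsum(stats::rnorm(n_vol, sd = 0.05)),
                   numeric(n_vol))
  t_idx <- seq_len(n_vol)
  wm <- sin(2 * pi * t_idx / (n_vol / 2)) + stats::rnorm(n_vol, sd = 0.2)
  csf <- cos(2 * pi * t_idx / (n_vol / 3)) + stats::rnorm(n_vol, sd = 0.2)
  out <- cbind(motion, wm, csf)
  colnames(out) <- c(paste0("motion", 1:6), "wm", "csf")
  scale(out)[, , drop = FALSE]
}

#' @export
print.timeseries_dataset <- function(x, ...) {
  d <- dim(x$data[[1]][[1]][[1]])
  cat("<timeseries_dataset>", length(x$subjects), "subjects x",
      length(x$runs), "runs x", length(x$rois), "ROIs;",
      d[1], "volumes x", d[2], "voxels per run\n")
  if (x$time_offset_s > 0) {
    cat("  initial", x$time_offset_s, "s discarded\n")
  }
  invisible(x)
}
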