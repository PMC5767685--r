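#' Block-design timing specification
#'
#' Timing of one run. Each block consists of a leading inter-block fixation
#' interval, a stimulus period of `trials_per_block` trials (video +
#' inter-stimulus interval), and a response window in which subjects report
#' the emotion by button press. Putting the fixation at the head of the
#' block means the initial discarded equilibration volumes fall entirely
#' within fixation, so every condition keeps its full complement of
#' stimulus volumes.
#'
#' The defaults are the main-experiment parameters: 18 blocks of 8 trials,
#' 2 s video + 0.5 s ISI, 2 s response window, 10 s fixation, TR 2 s, and 5
#' initial volumes discarded. Block duration is then 32 s and a run spans
#' 18 x 32 / 2 = 288 volumes before discarding.
#'
#' @param n_blocks Blocks per run.
#' @param trials_per_block Trials in each block's stimulus period.
#' @param trial_duration_s,isi_s,response_window_s,fixation_s Durations (s).
#' @param tr_s Repetition time (s).
#' @param n_discard Initial volumes discarded for signal equilibration.
#' @param condition_order Named list, one character vector per run
#'   (`run1`...), mapping blocks to condition labels. `NULL` uses
#'   [default_condition_order()] for 4 runs.
#' @param order_seed Seed for the default pseudo-random block order.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_blocks = 18,
                        trials_per_block = 8,
                        trial_duration_s = 2,
                        isi_s = 0.5,
                        response_window_s = 2,
                        fixation_s = 10,
                        tr_s = 2,
                        n_discard = 5,
                        condition_order = NULL,
                        order_seed = 99L) {
  durs <- c(trial_duration_s = trial_duration_s, isi_s = isi_s,
            response_window_s = response_window_s, fixation_s = fixation_s,
            tr_s = tr_s)
  for (nm in names(durs)) {
    if (!is.numeric(durs[[nm]]) || durs[[nm]] <= 0) {
      stop_config(nm, "must be > 0")
    }
  }
  if (n_blocks < 1 || trials_per_block < 1) {
    stop_config("n_blocks/trials_per_block", "must be >= 1")
  }
  if (n_discard < 0) stop_config("n_discard", "must be >= 0")
  stim_s <- trials_per_block * (trial_duration_s + isi_s)
  block_s <- fixation_s + stim_s + response_window_s
  total_s <- n_blocks * block_s
  if (abs(total_s / tr_s - round(total_s / tr_s)) > 1e-9) {
    stop_config("tr_s", "must divide the total run duration")
  }
  d <- structure(list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    trial_duration_s = trial_duration_s,
    isi_s = isi_s,
    response_window_s = response_window_s,
    fixation_s = fixation_s,
    tr_s = tr_s,
    n_discard = as.integer(n_discard),
    stim_duration_s = stim_s,
    block_duration_s = block_s,
    n_volumes = as.integer(round(total_s / tr_s)),
    condition_order = condition_order
  ), class = "design_spec")
  if (is.null(d$condition_order)) {
    d$condition_order <- default_condition_order(n_blocks, seed = order_seed)
  }
  d
}

#' Pseudo-random block-to-condition assignment
#'
#' Runs 1-3 present each of the nine conditions in `n_blocks / 9` blocks
#' each; run 4 presents only the three whole-person conditions, balanced.
#' Orders are shuffled deterministically from `seed`.
#'
#' @param n_blocks Blocks per run (must be divisible by 9 and by 3).
#' @param n_runs Number of runs.
#' @param seed Integer seed for the shuffle.
#' @return Named list of character vectors, one per run.
#' @export
default_condition_order <- function(n_blocks = 18, n_runs = 4, seed = 99L) {
  conds <- conditions_table()
  if (n_blocks %% 9 != 0) {
    stop_config("n_blocks", "must be divisible by 9 for a balanced order")
  }
  person_conds <- conds$condition[conds$body_type == "person"]
  set.seed(seed)
  out <- list()
  for (r in seq_len(n_runs)) {
    pool <- if (r == 4L) {
      rep(person_conds, n_blocks / 3)
    } else {
      rep(conds$condition, n_blocks / 9)
    }
    out[[paste0("run", r)]] <- sample(pool)
  }
  out
}

#' Block timing table for one run
#'
#' Absolute onsets (seconds from run start, 0-based) of each block's
#' fixation, stimulus and response epochs.
#'
#' @param design A [design_spec()].
#' @param run Run label or index.
#' @return data.frame with one row per block: `block`, `condition`,
#'   `fix_onset`, `stim_onset`, `stim_end`, `resp_onset`, `block_end`.
#' @export
block_timing <- function(design, run = 1) {
  run <- if (is.numeric(run)) paste0("run", run) else run
  order <- design$condition_order[[run]]
  if (is.null(order)) stop("no condition order for ", run, call. = FALSE)
  start <- (seq_along(order) - 1) * design$block_duration_s
  data.frame(
    block = seq_along(order),
    condition = order,
    fix_onset = start,
    stim_onset = start + design$fixation_s,
    stim_end = start + design$fixation_s + design$stim_duration_s,
    resp_onset = start + design$fixation_s + design$stim_duration_s,
    block_end = start + design$block_duration_s,
    stringsAsFactors = FALSE
  )
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak near 5-6 s, undershoot
#' near 16 s, peak-to-undershoot ratio 6), normalised to unit peak.
#'
#' @param t Time points (s), `>= 0`.
#' @param peak_shape,undershoot_shape,ratio Shape parameters of the two
#'   gamma densities and their amplitude ratio.
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak_shape = 6, undershoot_shape = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak_shape, rate = 1) -
    stats::dgamma(t, shape = undershoot_shape, rate = 1) / ratio
  h / max(stats::dgamma(seq(0, 32, by = 0.01), shape = peak_shape, rate = 1))
}

#' Convolve a run's condition boxcars with the HRF
#'
#' Builds one regressor per condition present in the run: a boxcar over the
#' condition's stimulus epochs convolved with [hrf_double_gamma()] on a fine
#' time grid, sampled at volume acquisition times.
#'
#' @param design A [design_spec()].
#' @param run Run label or index.
#' @param dt Fine grid step (s) for the convolution.
#' @return Matrix `n_volumes x n_conditions` with condition column names
#'   (full, pre-discard timeline).
#' @export
condition_regressors <- function(design, run = 1, dt = 0.1) {
  bt <- block_timing(design, run)
  conds <- unique(bt$condition)
  total_s <- design$n_blocks * design$block_duration_s
  fine_t <- seq(0, total_s - dt, by = dt)
  hrf <- hrf_double_gamma(seq(0, 32, by = dt))
  vol_t <- (seq_len(design$n_volumes) - 1) * design$tr_s
  vol_idx <- round(vol_t / dt) + 1
  out <- matrix(0, nrow = design$n_volumes, ncol = length(conds),
                dimnames = list(NULL, conds))
  for (cn in conds) {
    box <- numeric(length(fine_t))
    rows <- bt[bt$condition == cn, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      box[fine_t >= rows$stim_onset[i] & fine_t < rows$stim_end[i]] <- 1
    }
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(fine_t)] * dt
    out[, cn] <- conv[vol_idx]
  }
  out
}
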