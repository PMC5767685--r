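# Small fixtures shared across test files. Everything is built in code;
# sizes are kept small so the default run stays fast.

small_config <- function(...) {
  defaults <- list(n_subjects = 2, n_voxels = 60, roi_names = "EBA", seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(scenario_config, args)
}

# A pattern_dataset built directly from a filler function
# fill(subject, run, condition) -> voxel vector, so tests can construct
# exact patterns (orthogonal runs, collinear pairs, ...).
manual_pattern_dataset <- function(fill, n_subjects = 1, n_runs = 3,
                                   n_voxels = 4, roi = "EBA") {
  conds <- conditions_table()
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  runs <- paste0("run", seq_len(n_runs))
  arr <- array(NA_real_,
               dim = c(n_subjects, n_runs, nrow(conds), n_voxels),
               dimnames = list(subject = subjects, run = runs,
                               condition = conds$condition, voxel = NULL))
  for (s in seq_len(n_subjects)) {
    for (r in seq_len(n_runs)) {
      for (cn in conds$condition) {
        arr[s, r, cn, ] <- fill(s, r, cn)
      }
    }
  }
  structure(list(values = stats::setNames(list(arr), roi), templates = NULL,
                 conditions = conds, subjects = subjects, runs = runs,
                 config = list(provenance = "manual")),
            class = "pattern_dataset")
}

# A tiny design whose arithmetic is easy to hand-check:
# 9 blocks (one per condition), 2 trials of 1.5+0.5 s (4 s stimulus),
# fixation 2 s, response 2 s -> 8 s blocks, 36 volumes at TR 2.
toy_design <- function(...) {
  args <- utils::modifyList(
    list(n_blocks = 9, trials_per_block = 2, trial_duration_s = 1.5,
         isi_s = 0.5, response_window_s = 2, fixation_s = 2, tr_s = 2,
         n_discard = 0, order_seed = 42L),
    list(...))
  do.call(design_spec, args)
}

paper_design <- function(...) design_spec(...)
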