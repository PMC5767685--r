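#' Serialise a pattern dataset to a directory
#'
#' Writes one tab-separated table (`patterns.tsv`: one row per subject,
#' run, ROI and condition, voxels as columns `v1...vV`) and a JSON
#' snapshot of the generating configuration (`config.json`).
#'
#' @param ds A `pattern_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pattern_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  k <- 0
  for (roi in names(ds$values)) {
    arr <- ds$values[[roi]]
    for (s in ds$subjects) {
      for (r in seq_along(ds$runs)) {
        for (cn in dimnames(arr)$condition) {
          v <- arr[s, r, cn, ]
          if (anyNA(v)) next
          k <- k + 1
          rows[[k]] <- data.frame(subject = s, run = ds$runs[r], roi = roi,
                                  condition = cn, t(v),
                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  names(tab)[-(1:4)] <- paste0("v", seq_len(ncol(tab) - 4))
  utils::write.table(tab, file.path(dir, "patterns.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfg <- ds$config
  if (inherits(cfg, "scenario_config")) cfg <- unclass(cfg)
  cfg_ser <- lapply(cfg, function(x) if (inherits(x, "design_spec")) unclass(x) else x)
  jsonlite::write_json(cfg_ser, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a pattern dataset written by [write_pattern_dataset()]
#'
#' @param dir Directory containing `patterns.tsv` (and optionally
#'   `config.json`).
#' @return A `pattern_dataset`.
#' @export
read_pattern_dataset <- function(dir) {
  tab <- utils::read.table(file.path(dir, "patterns.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  vox_cols <- grep("^v[0-9]+$", names(tab))
  subjects <- unique(tab$subject)
  runs <- unique(tab$run)
  rois <- unique(tab$roi)
  conds <- conditions_table()
  values <- list()
  for (roi in rois) {
    arr <- array(NA_real_,
                 dim = c(length(subjects), length(runs), nrow(conds),
                         length(vox_cols)),
                 dimnames = list(subject = subjects, run = runs,
                                 condition = conds$condition, voxel = NULL))
    sub <- tab[tab$roi == roi, ]
    for (i in seq_len(nrow(sub))) {
      arr[sub$subject[i], sub$run[i], sub$condition[i], ] <-
        as.numeric(sub[i, vox_cols])
    }
    values[[roi]] <- arr
  }
  cfg_path <- file.path(dir, "config.json")
  cfg <- if (file.exists(cfg_path)) jsonlite::read_json(cfg_path) else NULL
  structure(list(values = values, templates = NULL, conditions = conds,
                 subjects = subjects, runs = runs, config = cfg),
            class = "pattern_dataset")
}
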