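#' End-to-end run configuration
#'
#' Bundles the generative scenario, the run design, and the analysis
#' switches into one serialisable object. All experiment constants (0.01
#' weight grid, p = 0.05 feature selection, 5 discarded volumes, chance
#' 1/3, BH FDR) are defaults and overridable here.
#'
#' @param scenario A [scenario_config()].
#' @param design A [design_spec()].
#' @param shift_s Hemodynamic shift for volume extraction (s).
#' @param p_select Feature-selection threshold.
#' @param fdr_method Multiple-comparison method for [stats::p.adjust()].
#' @param svm_cost SVM regularisation constant.
#' @param ts_noise_sd Time-series noise SD.
#' @param aggregate Test-exemplar aggregation, `"volume"` or `"block"`.
#' @param use_timeseries If `TRUE` the similarity and weight analyses run
#'   on GLM beta patterns estimated from generated time series (both
#'   procedures of the analysis flow); if `FALSE` they run on the
#'   generated condition patterns directly and classification is skipped.
#' @param seed Master seed; per-stage seeds are derived from it so that
#'   changing `class_seed_offset` alone leaves the other stages untouched.
#' @param class_seed_offset Offset of the classification-stage seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = scenario_config(),
                       design = design_spec(),
                       shift_s = 2,
                       p_select = 0.05,
                       fdr_method = "BH",
                       svm_cost = 1,
                       ts_noise_sd = 8,
                       aggregate = "volume",
                       use_timeseries = TRUE,
                       seed = 1L,
                       class_seed_offset = 7919L) {
  structure(list(scenario = scenario, design = design, shift_s = shift_s,
                 p_select = p_select, fdr_method = fdr_method,
                 svm_cost = svm_cost, ts_noise_sd = ts_noise_sd,
                 aggregate = aggregate, use_timeseries = use_timeseries,
                 seed = as.integer(seed),
                 class_seed_offset = as.integer(class_seed_offset)),
            class = "run_config")
}

#' Validate a run configuration
#'
#' @param config A [run_config()] (or a plain list with the same fields).
#' @return Character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  sc <- config$scenario
  if (!inherits(sc, "scenario_config")) {
    res <- tryCatch({
      do.call(scenario_config, sc)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) problems <- c(problems, res)
  }
  if (!inherits(config$design, "design_spec")) {
    problems <- c(problems, "invalid configuration: `design` is not a design_spec")
  }
  if (!is.numeric(config$shift_s) || config$shift_s < 0) {
    problems <- c(problems, "invalid configuration: `shift_s` must be >= 0")
  }
  if (!is.numeric(config$p_select) || config$p_select <= 0 ||
      config$p_select > 1) {
    problems <- c(problems, "invalid configuration: `p_select` must lie in (0, 1]")
  }
  if (inherits(sc, "scenario_config") && length(sc$roi_names) == 0) {
    problems <- c(problems, "invalid configuration: `roi_names` is empty")
  }
  problems
}

#' Run the full analysis pipeline
#'
#' Executes both analysis procedures end to end on synthetic data:
#' generate condition patterns under the configured scenario; generate
#' block-design time series; discard the initial volumes; (procedure 1)
#' estimate GLM beta patterns and run the pattern-similarity and weight
#' analyses on them; (procedure 2) extract z-scored condition volumes and
#' run the four-training-type emotion classification tested on run-4
#' whole-person volumes, with group tests against chance and FDR
#' correction. Deterministic given the config.
#'
#' @param config A [run_config()].
#' @return A `report_bundle`: list with `correlations`, `rsm_group`,
#'   `similarity_anovas`, `weights`, `weight_anova`, `classification`,
#'   `group_tests`, and `provenance`.
#' @export
run_pipeline <- function(config = run_config()) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop(paste(problems, collapse = "\n"), call. = FALSE)
  }
  sc <- config$scenario
  sc$seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed [config %s]: %s", name,
                   config_hash(config), conditionMessage(e)), call. = FALSE)
    })
  }

  patterns <- stage("simulate_patterns", generate_condition_patterns(sc))

  if (config$use_timeseries) {
    ts <- stage("simulate_timeseries",
                generate_timeseries(patterns, config$design,
                                    noise_sd = config$ts_noise_sd,
                                    seed = config$seed + 1L))
    ts <- stage("discard", discard_initial_volumes(ts))
    betas <- stage("estimate_betas", estimate_betas(ts))
    vps <- stage("extract_volumes",
                 extract_condition_volumes(ts, shift_s = config$shift_s))
    analysis_patterns <- betas
  } else {
    vps <- NULL
    analysis_patterns <- patterns
  }

  cortab <- stage("similarity", correlation_table(analysis_patterns))
  rois <- names(analysis_patterns$values)
  rsm_group <- stage("similarity", {
    out <- list()
    for (roi in rois) {
      for (e in emotion_levels()) {
        rsms <- lapply(analysis_patterns$subjects, function(s)
          build_rsm(analysis_patterns, roi, e, subject = s))
        out[[paste(roi, e, sep = ".")]] <- group_average_rsm(rsms)
      }
    }
    out
  })
  sim_anovas <- stage("similarity_anova", {
    out <- list()
    for (roi in rois) {
      sub <- cortab[cortab$roi == roi, ]
      out[[roi]] <- list(
        person_face_vs_synthetic =
          category_emotion_anova(sub, "person_face_vs_synthetic"),
        person_body_vs_synthetic =
          category_emotion_anova(sub, "person_body_vs_synthetic"))
    }
    out
  })

  wtab <- stage("weights", weight_table(analysis_patterns))
  weight_anova <- stage("weight_anova", {
    if (length(rois) >= 2) emotion_roi_anova(wtab) else NULL
  })

  if (config$use_timeseries) {
    class_tab <- stage("classification",
                       classification_table(vps, alpha_table = wtab,
                                            p_threshold = config$p_select,
                                            cost = config$svm_cost,
                                            aggregate = config$aggregate))
    group_tests <- stage("classification",
                         group_test_and_fdr(class_tab,
                                            method = config$fdr_method))
  } else {
    class_tab <- NULL
    group_tests <- NULL
  }

  structure(list(
    correlations = cortab,
    rsm_group = rsm_group,
    similarity_anovas = sim_anovas,
    weights = wtab,
    weight_anova = weight_anova,
    classification = class_tab,
    group_tests = group_tests,
    provenance = list(config_hash = config_hash(config),
                      seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("personmvpa")))
  ), class = "report_bundle")
}

#' Hash of a run configuration
#'
#' Order-stable hash of the serialised config, recorded in every report so
#' tables are traceable to the configuration that produced them.
#'
#' @param config A [run_config()].
#' @return Character scalar.
#' @export
config_hash <- function(config) {
  ser <- jsonlite::serializeJSON(rapply(unclass(config), unclass, how = "replace"))
  # small stable polynomial rolling hash; avoids a digest dependency
  bytes <- utf8ToInt(as.character(ser))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a report bundle to disk
#'
#' Tabular components as TSV, matrices and ANOVA lists as JSON, plus a
#' provenance file.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    if (!is.null(x)) {
      utils::write.table(x, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  wr(bundle$correlations, "correlations")
  wr(bundle$weights, "weights")
  wr(bundle$classification, "classification")
  wr(bundle$group_tests, "group_tests")
  jsonlite::write_json(
    list(rsm_group = bundle$rsm_group,
         similarity_anovas = bundle$similarity_anovas,
         weight_anova = bundle$weight_anova,
         provenance = bundle$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor", null = "null")
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> config", x$provenance$config_hash, "\n")
  cat("  correlations:", nrow(x$correlations), "rows;",
      "weights:", nrow(x$weights), "rows\n")
  if (!is.null(x$group_tests)) {
    cat("  classification group tests:", nrow(x$group_tests),
        "( significant:", sum(x$group_tests$significant), ")\n")
  }
  invisible(x)
}
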