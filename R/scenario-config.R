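#' Generative scenario configuration
#'
#' Parameters of the synthetic-data generator. Two scenarios are supported.
#' Under `part_based`, the whole-person voxel template of each emotion is a
#' convex combination of that emotion's face and body templates,
#' `alpha * face + (1 - alpha) * body`. Under `integrated`, a fraction
#' `1 - gamma` of the person template comes from an independent
#' person-only component, so only `gamma = 1` is fully part-based;
#' `part_based` is equivalent to `integrated` with `gamma = 1`.
#'
#' Default values reproduce the simulated study conditions: 20 subjects,
#' 4 runs, 7 regions, 600 voxels per region, and a run-level noise standard
#' deviation of 0.4, which under `gamma = 1`, `alpha = 0.5` puts the
#' expected cross-run person-synthetic Pearson correlation near 0.8 (see the
#' methods vignette for the closed-form calibration).
#'
#' @param scenario `"part_based"` or `"integrated"`.
#' @param alpha_true Named numeric vector of true face weights in `[0, 1]`,
#'   one per emotion (`happiness`, `anger`, `fear`). A single unnamed value
#'   is recycled to all three emotions.
#' @param gamma Fraction of the person template explained by the face/body
#'   combination, in `[0, 1]`. Forced to 1 when `scenario = "part_based"`.
#' @param sigma_noise Run-level voxel noise SD (response units), `>= 0`.
#' @param rho_emotion Correlation between the templates of different
#'   emotions within a body type, in `[0, 1)`.
#' @param n_voxels Voxels per ROI (`>= 2`).
#' @param n_subjects,n_runs Counts. Run 4 holds only person conditions.
#' @param roi_names Character vector of ROI labels.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("part_based", "integrated"),
                            alpha_true = 0.5,
                            gamma = 1,
                            sigma_noise = 0.4,
                            rho_emotion = 0.2,
                            n_voxels = 600,
                            n_subjects = 20,
                            n_runs = 4,
                            roi_names = default_rois(),
                            seed = 1L) {
  scenario <- match.arg(scenario)
  emotions <- emotion_levels()
  if (length(alpha_true) == 1L && is.null(names(alpha_true))) {
    alpha_true <- stats::setNames(rep(alpha_true, 3L), emotions)
  }
  if (!all(emotions %in% names(alpha_true))) {
    stop_config("alpha_true", "must be named with all three emotions")
  }
  alpha_true <- alpha_true[emotions]
  if (any(!is.finite(alpha_true)) || any(alpha_true < 0) || any(alpha_true > 1)) {
    stop_config("alpha_true", "values must lie in [0, 1]")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0 || gamma > 1) {
    stop_config("gamma", "must be a single value in [0, 1]")
  }
  if (scenario == "part_based") gamma <- 1
  if (!is.numeric(sigma_noise) || length(sigma_noise) != 1L ||
      !is.finite(sigma_noise) || sigma_noise < 0) {
    stop_config("sigma_noise", "must be a single value >= 0")
  }
  if (!is.numeric(rho_emotion) || length(rho_emotion) != 1L ||
      rho_emotion < 0 || rho_emotion >= 1) {
    stop_config("rho_emotion", "must lie in [0, 1)")
  }
  if (!is.numeric(n_voxels) || n_voxels < 2) {
    stop_config("n_voxels", "must be >= 2")
  }
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    stop_config("n_subjects", "must be >= 1")
  }
  if (!is.numeric(n_runs) || n_runs < 1 || n_runs > 4) {
    stop_config("n_runs", "must be between 1 and 4")
  }
  if (!is.character(roi_names) || length(roi_names) < 1L ||
      anyDuplicated(roi_names)) {
    stop_config("roi_names", "must be a non-empty set of unique labels")
  }
  structure(list(
    scenario = scenario,
    alpha_true = alpha_true,
    gamma = gamma,
    sigma_noise = sigma_noise,
    rho_emotion = rho_emotion,
    n_voxels = as.integer(n_voxels),
    n_subjects = as.integer(n_subjects),
    n_runs = as.integer(n_runs),
    roi_names = roi_names,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat("  scenario:   ", x$scenario, " (gamma = ", x$gamma, ")\n", sep = "")
  cat("  alpha_true: ", paste(sprintf("%s=%.2f", names(x$alpha_true), x$alpha_true),
                              collapse = ", "), "\n", sep = "")
  cat("  sigma_noise:", x$sigma_noise, " rho_emotion:", x$rho_emotion, "\n")
  cat("  dims:       ", x$n_subjects, "subjects x", x$n_runs, "runs x",
      length(x$roi_names), "ROIs x", x$n_voxels, "voxels\n")
  cat("  seed:       ", x$seed, "\n")
  invisible(x)
}
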