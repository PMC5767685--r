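# Shared settings for the analysis scripts. Sourced by 01-07.
#
# The generative defaults mirror the simulated study conditions: 20
# subjects, 4 runs, 9 conditions, seven ROIs, 600 voxels per ROI, run-level
# noise SD 0.4 (cross-run person-synthetic r ~ 0.8 under the part-based
# scenario). The time-series stages use fewer voxels and ROIs so the GLM
# and SVM steps stay desk-sized; the methods vignette discusses the sizes.

library(personmvpa)

SEED <- 2024L

scenario_part <- scenario_config(scenario = "part_based", alpha_true = 0.5,
                                 sigma_noise = 0.4, seed = SEED)
scenario_integr <- scenario_config(scenario = "integrated", gamma = 0.5,
                                   alpha_true = 0.5, sigma_noise = 0.4,
                                   seed = SEED)
# emotion-modulated part-based scenario: happy person patterns lean on the
# face, threat emotions on (closer to) equal weights
scenario_emotion <- scenario_config(
  scenario = "part_based",
  alpha_true = c(happiness = 0.6, anger = 0.5, fear = 0.45),
  sigma_noise = 0.4, seed = SEED)

main_design <- design_spec()

results_dir <- file.path("results")
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)

write_tsv <- function(x, name) {
  path <- file.path(results_dir, paste0(name, ".tsv"))
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  cat("  wrote", path, "\n")
}
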