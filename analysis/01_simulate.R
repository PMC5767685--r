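#!/usr/bin/env Rscript
# Generate the synthetic datasets under the two representation scenarios
# and record their basic structure. Under the part-based scenario the
# whole-person template is exactly alpha*face + (1-alpha)*body; under the
# integrated scenario half of the person template comes from an
# independent person-only population.

source(file.path("analysis", "00_config.R"))

cat("== 01 simulate: two scenarios at study scale ==\n")
for (nm in c("part_based", "integrated")) {
  cfg <- if (nm == "part_based") scenario_part else scenario_integr
  ds <- generate_condition_patterns(cfg)
  print(ds)

  # within-run correlation between person and its part combination,
  # noiseless templates: 1 under part-based, < 1 under integrated
  tpl <- ds$templates$EBA
  r_tpl <- mean(sapply(ds$subjects, function(s) {
    cor(tpl[s, "person_happiness", ],
        0.5 * tpl[s, "face_happiness", ] + 0.5 * tpl[s, "body_happiness", ])
  }))
  cat(sprintf("  %s: mean template cor(person, 0.5*face+0.5*body) = %.3f\n",
              nm, r_tpl))

  summary_tab <- data.frame(
    scenario = nm, gamma = cfg$gamma,
    n_subjects = cfg$n_subjects, n_rois = length(cfg$roi_names),
    n_voxels = cfg$n_voxels, sigma_noise = cfg$sigma_noise,
    template_part_cor = r_tpl)
  write_tsv(summary_tab, paste0("simulated_", nm, "_summary"))

  # full serialisation goes to scratch space (large)
  out_dir <- file.path("scratch", paste0("dataset_", nm))
  write_pattern_dataset(ds, out_dir)
  cat("  serialised dataset to", out_dir, "\n")
}

cat("Done. Part-based templates satisfy the convex identity exactly;\n")
cat("gamma = 0.5 integrated templates correlate ~0.58 with their part\n")
cat("combination (analytically 1/sqrt(3) at alpha = 0.5).\n")
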