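#!/usr/bin/env Rscript
# Pattern similarity analysis: cross-run Fisher-z correlations among face,
# body, person and synthetic-mean patterns; group-average RSMs; and the
# 2 (Category) x 3 (Emotion) within-subject ANOVAs contrasting
# person-synthetic against person-face and person-body similarity.

source(file.path("analysis", "00_config.R"))

cat("== 03 similarity: RSMs and category-emotion ANOVAs ==\n")
ps_z <- c(part_based = NA_real_, integrated = NA_real_)
for (nm in c("part_based", "integrated")) {
  cfg <- if (nm == "part_based") scenario_part else scenario_integr
  ds <- generate_condition_patterns(cfg)
  cortab <- correlation_table(ds, rois = c("EBA", "OFA", "STS"))
  write_tsv(cortab, paste0("similarity_correlations_", nm))

  rsm <- group_average_rsm(lapply(ds$subjects, function(s)
    build_rsm(ds, "EBA", "happiness", subject = s)))
  cat(sprintf("\n%s: group RSM (EBA, happiness), Fisher z:\n", nm))
  print(round(rsm, 3))

  sub <- cortab[cortab$roi == "EBA", ]
  ps_z[nm] <- mean(sub$z[sub$cat_a == "person" & sub$cat_b == "synthetic"])
  for (contrast in c("person_face_vs_synthetic", "person_body_vs_synthetic")) {
    an <- category_emotion_anova(sub, contrast)
    cat(sprintf("  %s ANOVA (EBA): Category F(%d,%d) = %.2f, p = %.2g\n",
                contrast, an$df1[1], an$df2[1], an$F[1], an$p[1]))
    an$contrast <- contrast
    an$scenario <- nm
    write_tsv(an, paste0("similarity_anova_", nm, "_", contrast))
  }
}

cat(sprintf("\nDone. Mean person-synthetic z in the EBA: %.2f part-based vs %.2f\n",
            ps_z["part_based"], ps_z["integrated"]))
cat("integrated -- the similarity signature that separates the scenarios.\n")
cat("(The Category contrasts stay significant in both because the synthetic\n")
cat("mean always shares more signal with the person pattern than either\n")
cat("part alone does.)\n")
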