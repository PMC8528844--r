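#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Builds the three synthetic data sets every later stage consumes: a 20-slide
# H-DAB panel with ground-truth nuclei spanning 5-60% Ki67 positivity (plus
# four annotated slides reserved for classifier training), a window-trial
# table at the trial's paired sample sizes (29/14/15/13) with the arm effect
# sizes (65% / 37% mean post/pre ratios on tamoxifen), and a probe-level
# expression matrix whose signature genes track each patient's Ki67 response.

library(ki67window)

out <- "results"
dir.create(file.path(out, "slides"), recursive = TRUE, showWarnings = FALSE)

panel_pf <- seq(0.05, 0.60, length.out = 20)
manifest <- data.frame(slide = sprintf("panel_%02d", seq_along(panel_pf)),
                       role = "panel", positive_fraction = panel_pf,
                       seed = 201:220)
train <- data.frame(slide = sprintf("train_%02d", 1:4), role = "train",
                    positive_fraction = c(0.1, 0.3, 0.5, 0.2), seed = 101:104)
manifest <- rbind(manifest, train)

for (i in seq_len(nrow(manifest))) {
  sl <- generate_slide(slide_spec(positive_fraction = manifest$positive_fraction[i],
                                  seed = manifest$seed[i]))
  write_slide_image(sl$image,
                    file.path(out, "slides", paste0(manifest$slide[i], ".png")))
  write_ground_truth(sl$ground_truth,
                     file.path(out, "slides", paste0(manifest$slide[i], "_truth.csv")))
}
write.csv(manifest, file.path(out, "slide_manifest.csv"), row.names = FALSE)
cat("wrote", nrow(manifest), "slides with ground truth under",
    file.path(out, "slides"), "\n")

trial <- generate_trial_table(trial_sim_spec(seed = 31))
write_trial_table(trial, file.path(out, "trial_table.tsv"))
cat("trial table:", nrow(trial), "patients;",
    sprintf("%.0f%%", 100 * mean(trial$e2_pre_censored[trial$menopause == "post"])),
    "of postmenopausal pre-treatment E2 values censored at 44 pmol/L\n")

em <- generate_expression(expression_sim_spec(seed = 41), trial)
write_expression_matrix(em, file.path(out, "expression.tsv"))
cat("expression matrix:", nrow(em$values), "probes x", ncol(em$values),
    "samples,", sprintf("%.1f%%", 100 * mean(is.na(em$values))), "missing\n")
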