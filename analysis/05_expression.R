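#!/usr/bin/env Rscript
# Stage 5 — expression-based proliferation readouts.
#
# knn-10 imputation, median probe-to-gene collapse, the empirical-Bayes
# moderated paired t-test for MKI67 within each arm, one-sided Wilcoxon
# signed-rank tests on every proliferation-signature score, the one-sided
# t-test comparing tamoxifen arms on per-patient MKI67 changes, and ANOVA
# across the postmenopausal arms.

library(ki67window)

out <- "results"
em <- read_expression_matrix(file.path(out, "expression.tsv"))
# gene sets travel as plain-text files; the bundled ones are synthetic
# placeholders over the simulated gene universe
set_files <- list.files(system.file("extdata", "gene_sets",
                                    package = "ki67window"),
                        full.names = TRUE)
sets <- lapply(set_files, read_gene_set)
names(sets) <- sub("^synthetic_", "", vapply(sets, `[[`, "", "name"))

report <- run_expression_analysis(em, k = 10, gene_sets = sets)
print(report)

jsonlite::write_json(list(
  mki67_moderated_one_sided_p = as.list(report$mki67_p),
  menopause_t_one_sided_p = report$arm_comparison$menopause_t$p_value,
  postmenopausal_anova_p = report$arm_comparison$postmenopausal_anova$p_value,
  signature_wilcoxon_p = lapply(report$signature_wilcoxon, function(arms) {
    lapply(arms, `[[`, "p_value")
  })
), file.path(out, "expression_report.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
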