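#!/usr/bin/env Rscript
# Stage 4 — window-trial paired-response statistics.
#
# Per-arm one-sided Wilcoxon signed-rank tests on log10(Ki67+1), the
# Mann-Whitney comparison of pre- versus postmenopausal tamoxifen post/pre
# ratios (all patients and responders only), Kruskal-Wallis across the
# postmenopausal arms, per-arm effect sizes, responder tabulation, and the
# inverse association between residual estradiol and Ki67 decrease among
# tamoxifen patients above the 44 pmol/L detection limit. All p-values are
# uncorrected, sidedness as labeled.

library(ki67window)

out <- "results"
trial <- read_trial_table(file.path(out, "trial_table.tsv"))
report <- run_trial_analysis(trial)
print(report)

sink(file.path(out, "trial_report.txt")); print(report); sink()
jsonlite::write_json(list(
  wilcoxon_one_sided_p = lapply(report$paired_wilcoxon, `[[`, "p_value"),
  menopause_mwu_p = report$menopause_comparison$p_value,
  menopause_mwu_responders_p = report$menopause_comparison_responders$p_value,
  postmenopausal_kruskal_p = report$postmenopausal_kruskal_wallis$p_value,
  effect_sizes = report$effect_sizes,
  e2 = report$e2,
  note = report$note
), file.path(out, "trial_report.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
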