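#!/usr/bin/env Rscript
# Stage 3 — concordance of automated scoring with ground truth.
#
# The analogue of validating an automated scorer against expert visual
# scoring on annotated hotspots: Spearman rank correlation and the
# absolute-agreement intraclass correlation ICC(2,1) with its 95% CI,
# between the automated index and the ground-truth index per ROI.

library(ki67window)

out <- "results"
scores <- read.csv(file.path(out, "roi_scores.csv"))
pairs <- paired_scores(scores$index_truth, scores$index_auto,
                       sample_id = scores$slide)

sp <- spearman_concordance(pairs)
ic <- icc_concordance(pairs)
report <- list(
  n_rois = nrow(scores),
  spearman = list(rho = sp$rho, p_value = sp$p_value, method = sp$method),
  icc = list(estimate = ic$icc, ci_low = ic$ci_low, ci_high = ic$ci_high,
             p_value = ic$p_value, form = ic$form)
)
jsonlite::write_json(report, file.path(out, "concordance.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf("automated vs truth over %d ROIs: Spearman rho = %.4f, ICC(2,1) = %.3f (95%% CI %.3f-%.3f)\n",
            nrow(scores), sp$rho, ic$icc, ic$ci_low, ic$ci_high))
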