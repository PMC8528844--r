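#!/usr/bin/env Rscript
# Stage 2 — automated Ki67 scoring of the slide panel.
#
# Trains the sliding-window patch classifier on the four annotated training
# slides (4 x 400 windows, 80/20 split) and scores a fixed 100 x 100 um ROI
# on every panel slide: probability map at 10 px stride, Gaussian nucleus
# map, contour extraction, DAB positivity, proliferation index. Writes the
# per-slide automated and ground-truth indices for the concordance stage.

library(ki67window)

out <- "results"
manifest <- read.csv(file.path(out, "slide_manifest.csv"))

train_rows <- manifest[manifest$role == "train", ]
train_slides <- lapply(seq_len(nrow(train_rows)), function(i) {
  generate_slide(slide_spec(positive_fraction = train_rows$positive_fraction[i],
                            seed = train_rows$seed[i]))
})
samp <- sample_training_patches(train_slides, per_slide = 400,
                                split_fraction = 0.8, seed = 11)
clf <- train_patch_classifier(samp$train, samp$val, seed = 2)
cat(sprintf("patch classifier: %d training / %d validation windows, held-out accuracy %.3f\n",
            clf$n_train, clf$n_val, clf$validation_accuracy))

roi <- c(60, 60, 260, 260)
panel_rows <- manifest[manifest$role == "panel", ]
scores <- do.call(rbind, lapply(seq_len(nrow(panel_rows)), function(i) {
  sl <- generate_slide(slide_spec(positive_fraction = panel_rows$positive_fraction[i],
                                  seed = panel_rows$seed[i]))
  sc <- score_roi(sl, roi, clf)
  data.frame(slide = panel_rows$slide[i],
             index_auto = sc$index,
             index_truth = ground_truth_index(sl$ground_truth, roi),
             n_total = sc$n_total, n_positive = sc$n_positive,
             area_mm2 = sc$area_mm2)
}))
write.csv(scores, file.path(out, "roi_scores.csv"), row.names = FALSE)
cat(sprintf("scored %d ROIs of %.4f mm^2; %.0f nuclei counted on average\n",
            nrow(scores), scores$area_mm2[1], mean(scores$n_total)))
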