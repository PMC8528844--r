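# Shared fixtures, built once per test run and cached.

fixture_cache <- new.env(parent = emptyenv())

# Four annotated training slides spanning low to high positivity.
fixture_training_slides <- function() {
  if (is.null(fixture_cache$slides)) {
    pf <- c(0.1, 0.3, 0.5, 0.2)
    fixture_cache$slides <- lapply(seq_along(pf), function(i) {
      generate_slide(slide_spec(positive_fraction = pf[i], seed = 100 + i))
    })
  }
  fixture_cache$slides
}

# Patch classifier trained on the fixture slides with a held-out split.
fixture_classifier <- function() {
  if (is.null(fixture_cache$clf)) {
    samp <- sample_training_patches(fixture_training_slides(),
                                    per_slide = 400, split_fraction = 0.8,
                                    seed = 11)
    fixture_cache$clf <- train_patch_classifier(samp$train, samp$val, seed = 2)
  }
  fixture_cache$clf
}

# Match detected calls to ground-truth tumor nuclei; recall / precision /
# positivity accuracy restricted to the region the probability map covers.
detection_metrics <- function(slide, calls, match_radius = 10,
                              window_px = 80, stride_px = 10) {
  img <- slide$image
  off <- (window_px - 1) / 2
  n_cells <- floor((dim(img)[1:2] - window_px) / stride_px) + 1
  hi_r <- off + (n_cells[1] - 1) * stride_px
  hi_c <- off + (n_cells[2] - 1) * stride_px
  gt <- slide$ground_truth
  tum <- gt[gt$cell_class == "tumor", , drop = FALSE]
  inb <- tum$center_row >= off & tum$center_row <= hi_r &
    tum$center_col >= off & tum$center_col <= hi_c
  ti <- tum[inb, , drop = FALSE]
  d2 <- outer(calls$center_row, ti$center_row, "-")^2 +
    outer(calls$center_col, ti$center_col, "-")^2
  ic <- calls$center_row >= off & calls$center_row <= hi_r &
    calls$center_col >= off & calls$center_col <= hi_c
  d2c <- outer(calls$center_row[ic], tum$center_row, "-")^2 +
    outer(calls$center_col[ic], tum$center_col, "-")^2
  matched <- apply(d2c, 1, min) <= match_radius^2
  nn <- apply(d2c, 1, which.min)
  list(
    recall = mean(apply(d2, 2, min) <= match_radius^2),
    precision = mean(matched),
    positivity_accuracy = mean(
      calls$positive[ic][matched] == tum$ki67_positive[nn[matched]])
  )
}

# All permutations of a vector (for brute-force rank-test oracles).
enumerate_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in enumerate_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}
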