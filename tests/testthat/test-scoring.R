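test_that("a blank image yields a near-zero map and no detections", {
  spec <- slide_spec(width_px = 160, height_px = 160, n_tumor_nuclei = 0,
                     n_stromal_nuclei = 0, seed = 2)
  blank <- generate_slide(spec)
  clf <- fixture_classifier()
  params <- scoring_params()
  pm <- compute_probability_map(blank$image, clf, params$grid, spec$background)
  expect_true(all(pm >= 0 & pm <= 1))
  expect_true(all(pm <= params$detection_threshold))
  calls <- detect_nuclei(blank, clf, params)
  expect_equal(nrow(calls), 0L)
})

test_that("a single centered nucleus peaks at the nearest anchor", {
  spec <- slide_spec(width_px = 160, height_px = 160, n_tumor_nuclei = 1,
                     n_stromal_nuclei = 0, positive_fraction = 0, seed = 23)
  sl <- generate_slide(spec)
  clf <- fixture_classifier()
  pm <- compute_probability_map(sl$image, clf, patch_grid(), spec$background)
  peak <- which(pm == max(pm), arr.ind = TRUE)[1, ]
  off <- (80 - 1) / 2
  peak_px <- (peak - 1) * 10 + off
  ctr <- unlist(sl$ground_truth[1, c("center_row", "center_col")])
  expect_lt(sqrt(sum((peak_px - ctr)^2)), 10)
})

test_that("Gaussian smoothing preserves constants and matches the kernel on a delta", {
  m <- matrix(0.4, 15, 15)
  expect_equal(smooth_to_nucleus_map(m, 1), m, tolerance = 1e-12)
  delta <- matrix(0, 15, 15); delta[8, 8] <- 1
  sm <- smooth_to_nucleus_map(delta, 1)
  k <- 3L
  w <- exp(-((-k:k)^2) / 2); w <- w / sum(w)
  expect_equal(sm[8 + (-k:k), 8 + (-k:k)], outer(w, w), tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12) # interior mass conserved
  # sigma -> 0 limit returns the input
  expect_equal(smooth_to_nucleus_map(delta, 0.01), delta)
  expect_error(smooth_to_nucleus_map(delta, 0), "sigma > 0")
})

test_that("two peaks closer than the suppression radius give one call", {
  m <- matrix(0.01, 20, 20)
  m[10, 10] <- 0.9
  m[10, 11] <- 0.8 # 10 px away at stride 10, inside min_separation 15
  attr(m, "grid") <- patch_grid(80, 10)
  attr(m, "offset_px") <- 39.5
  flat <- generate_slide(slide_spec(width_px = 280, height_px = 280,
                                    n_tumor_nuclei = 1, n_stromal_nuclei = 0,
                                    seed = 4))
  calls <- extract_nuclei(m, flat$image, scoring_params())
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$peak, 0.9) # suppression keeps the higher peak
})

test_that("detection achieves high recall and precision on well-separated nuclei", {
  sl <- generate_slide(slide_spec(width_px = 560, height_px = 560,
                                  n_tumor_nuclei = 200, n_stromal_nuclei = 20,
                                  min_separation_px = 25,
                                  positive_fraction = 0.3, seed = 77))
  calls <- detect_nuclei(sl, fixture_classifier())
  met <- detection_metrics(sl, calls)
  expect_gte(met$recall, 0.95)
  expect_gte(met$precision, 0.95)
})

test_that("per-nucleus DAB positivity is called from colour and brightness", {
  clf <- fixture_classifier()
  # pure DAB nuclei -> positive; pure hematoxylin -> negative
  pos_slide <- generate_slide(slide_spec(width_px = 280, height_px = 280,
                                         n_tumor_nuclei = 20,
                                         n_stromal_nuclei = 0,
                                         positive_fraction = 1, seed = 41))
  neg_slide <- generate_slide(slide_spec(width_px = 280, height_px = 280,
                                         n_tumor_nuclei = 20,
                                         n_stromal_nuclei = 0,
                                         positive_fraction = 0, seed = 41))
  match_gt <- function(slide, calls) {
    gt <- slide$ground_truth
    d2 <- outer(calls$center_row, gt$center_row, "-")^2 +
      outer(calls$center_col, gt$center_col, "-")^2
    calls[apply(d2, 1, min) <= 100, , drop = FALSE] # true-nucleus calls only
  }
  pos_calls <- match_gt(pos_slide, detect_nuclei(pos_slide, clf))
  neg_calls <- match_gt(neg_slide, detect_nuclei(neg_slide, clf))
  expect_gte(nrow(pos_calls), 5L)
  expect_true(all(pos_calls$positive))
  expect_false(any(neg_calls$positive))
  # accuracy against ground truth across a mixed panel
  accs <- vapply(c(51, 52, 53), function(seed) {
    sl <- generate_slide(slide_spec(positive_fraction = 0.4, seed = seed))
    detection_metrics(sl, detect_nuclei(sl, clf))$positivity_accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})

test_that("degenerate contours are flagged and excluded from counts", {
  calls <- data.frame(center_row = 50, center_col = 50, peak = 1,
                      radius_px = 0.1)
  calls$contour <- list(cbind(row = 50 + 0.1 * cos(seq(0, 2 * pi, length.out = 17)[-17]),
                              col = 50 + 0.1 * sin(seq(0, 2 * pi, length.out = 17)[-17])))
  sl <- generate_slide(slide_spec(width_px = 120, height_px = 120,
                                  n_tumor_nuclei = 0, n_stromal_nuclei = 0,
                                  seed = 1))
  out <- classify_positivity(sl$image, calls, scoring_params(n_rays = 16),
                             sl$spec$background)
  expect_false(out$valid)
  sc <- ki67window:::score_from_calls(out, c(0, 0, 120, 120), 1)
  expect_equal(sc$n_total, 0L)
  expect_false(sc$defined)
})

test_that("ROI scores flag cell-free regions and recover the true index", {
  clf <- fixture_classifier()
  blank <- generate_slide(slide_spec(width_px = 240, height_px = 240,
                                     n_tumor_nuclei = 0, n_stromal_nuclei = 0,
                                     seed = 3))
  sc <- score_roi(blank, c(40, 40, 200, 200), clf)
  expect_false(sc$defined)
  expect_true(is.na(sc$index))

  sl <- generate_slide(slide_spec(positive_fraction = 0.30, seed = 61))
  roi <- c(60, 60, 260, 260)
  sc <- score_roi(sl, roi, clf)
  expect_true(sc$defined)
  expect_equal(sc$n_positive + (sc$n_total - sc$n_positive), sc$n_total)
  expect_equal(sc$area_mm2, (200 * 0.5 / 1000)^2)
  truth <- ground_truth_index(sl$ground_truth, roi)
  expect_lt(abs(sc$index - truth), 3)
})

test_that("the scored index tracks ground truth under ROI translation", {
  clf <- fixture_classifier()
  sl <- generate_slide(slide_spec(width_px = 520, height_px = 520,
                                  n_tumor_nuclei = 290, n_stromal_nuclei = 58,
                                  positive_fraction = 0.35, seed = 71))
  for (shift in list(c(0, 0), c(15, 0), c(0, 15), c(10, 10))) {
    roi <- c(60, 60, 440, 440) + rep(shift, 2)
    sc <- score_roi(sl, roi, clf)
    truth <- ground_truth_index(sl$ground_truth, roi)
    expect_lt(abs(sc$index - truth), 3)
  }
})

test_that("a higher positive fraction never lowers the scored index", {
  clf <- fixture_classifier()
  roi <- c(60, 60, 260, 260)
  idx <- vapply(c(0.1, 0.3, 0.5), function(pf) {
    sl <- generate_slide(slide_spec(positive_fraction = pf, seed = 83))
    score_roi(sl, roi, clf)$index
  }, numeric(1))
  expect_true(all(diff(idx) >= 0))
})

test_that("scoring is deterministic across repeated runs", {
  clf <- fixture_classifier()
  sl <- generate_slide(slide_spec(positive_fraction = 0.25, seed = 91))
  s1 <- score_roi(sl, c(60, 60, 240, 240), clf)
  s2 <- score_roi(sl, c(60, 60, 240, 240), clf)
  expect_identical(s1, s2)
})

test_that("the hotspot search finds the high-positivity cluster", {
  clf <- fixture_classifier()
  # two slides pasted side by side: left 5% positive, right 55% positive
  left <- generate_slide(slide_spec(positive_fraction = 0.05, seed = 15))
  right <- generate_slide(slide_spec(positive_fraction = 0.55, seed = 16))
  img <- array(0, c(320, 640, 3))
  img[, 1:320, ] <- left$image
  img[, 321:640, ] <- right$image
  params <- scoring_params(min_cells = 20)
  hs <- find_hotspot(img, clf, roi_area_mm2 = (200 * 0.5 / 1000)^2,
                     params = params, background = left$spec$background,
                     microns_per_pixel = 0.5)
  # chosen ROI center falls in the right (high-positivity) half
  expect_gt((hs$roi[2] + hs$roi[4]) / 2, 320)
  expect_gt(hs$score$index, 30)
  # impossible cell demand errors with advice
  expect_error(
    find_hotspot(img, clf, roi_area_mm2 = (200 * 0.5 / 1000)^2,
                 params = scoring_params(min_cells = 100000),
                 background = left$spec$background, microns_per_pixel = 0.5),
    "min_cells")
})

test_that("on a uniform slide the hotspot index stays near the global index", {
  clf <- fixture_classifier()
  sl <- generate_slide(slide_spec(positive_fraction = 0.3, seed = 19))
  params <- scoring_params(min_cells = 20)
  global <- score_roi(sl, c(0, 0, 320, 320), clf, params)
  hs <- find_hotspot(sl, clf, roi_area_mm2 = (280 * 0.5 / 1000)^2,
                     params = params)
  expect_lt(abs(hs$score$index - global$index), 5)
  expect_gte(hs$score$index, global$index - 1e-9) # a maximum never falls below
})
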