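#' Parameters of the Ki67 scoring pipeline
#'
#' Bundles every tunable of the image chain. Defaults: the 80/10 sliding
#' window; Gaussian sigma of `expected_radius_px / (2 * stride_px)` grid
#' units; nucleus-probability detection threshold 0.25; greedy non-maximum
#' suppression at 15 px; contours as the 50%-of-peak level set of the total
#' stain optical density along radial rays, clipped at
#' `max_radius_factor * expected_radius_px`; DAB positivity when the mean DAB
#' amount inside the contour exceeds `dab_threshold` and the mean brightness
#' stays below `brightness_threshold` (excluding unstained bright debris).
#' The positivity thresholds were calibrated once on a held-out synthetic
#' calibration slide and frozen here.
#'
#' @param window_px,stride_px sliding-window geometry (see [patch_grid()]).
#' @param sigma_grid Gaussian sigma in grid units; `NULL` uses the default.
#' @param detection_threshold minimum nucleus-map value for a peak.
#' @param min_separation_px non-maximum-suppression radius in px.
#' @param expected_radius_px nominal nucleus radius in px.
#' @param contour_level level-set fraction of the per-nucleus peak density.
#' @param max_radius_factor contour clip radius, in units of expected radius.
#' @param n_rays radial rays per contour polygon.
#' @param dab_threshold,brightness_threshold positivity thresholds.
#' @param min_cells minimum nuclei for a valid hotspot (default 1000).
#' @param microns_per_pixel fallback resolution when the image carries none.
#' @return object of class `scoring_params`.
#' @export
scoring_params <- function(window_px = 80L, stride_px = 10L, sigma_grid = NULL,
                           detection_threshold = 0.25, min_separation_px = 15,
                           expected_radius_px = 7, contour_level = 0.5,
                           max_radius_factor = 1.8, n_rays = 16L,
                           dab_threshold = 0.2, brightness_threshold = 0.8,
                           min_cells = 1000L, microns_per_pixel = 0.5) {
  stopifnot(detection_threshold > 0, min_separation_px > 0,
            expected_radius_px > 0, contour_level > 0, contour_level < 1)
  if (is.null(sigma_grid)) sigma_grid <- expected_radius_px / (2 * stride_px)
  structure(list(
    grid = patch_grid(window_px, stride_px), sigma_grid = sigma_grid,
    detection_threshold = detection_threshold,
    min_separation_px = min_separation_px,
    expected_radius_px = expected_radius_px, contour_level = contour_level,
    max_radius_factor = max_radius_factor, n_rays = as.integer(n_rays),
    dab_threshold = dab_threshold, brightness_threshold = brightness_threshold,
    min_cells = as.integer(min_cells), microns_per_pixel = microns_per_pixel
  ), class = "scoring_params")
}

#' Nucleus probability map of an image
#'
#' Applies the sliding window over the image and evaluates the patch
#' classifier at every anchor, yielding a probability-of-nucleus-at-center
#' field on the stride-resolution grid (`floor((dim - window)/stride) + 1`
#' cells per axis). Grid cell (i, j) (0-based) maps to the source-pixel
#' window center `(i, j) * stride + (window - 1)/2`.
#'
#' @param image h x w x 3 array or list with `image`.
#' @param classifier a trained [train_patch_classifier()].
#' @param grid a [patch_grid()].
#' @param background RGB background level for stain separation.
#' @return matrix of probabilities with attributes `grid` and `offset_px`.
#' @export
compute_probability_map <- function(image, classifier, grid = patch_grid(),
                                    background = c(1, 1, 1)) {
  img <- if (is.list(image)) image$image else image
  nd <- grid_dims(grid, dim(img)[1], dim(img)[2])
  anchors <- grid_anchors(grid, dim(img)[1], dim(img)[2])
  ft <- image_feature_tables(img, background)
  p <- predict_probability(classifier, anchor_features(ft, anchors, grid$window_px))
  m <- matrix(p, nd[1], nd[2], byrow = TRUE) # anchors are row-major
  attr(m, "grid") <- grid
  attr(m, "offset_px") <- (grid$window_px - 1) / 2
  m
}

#' Gaussian smoothing of a probability map
#'
#' Separable discrete Gaussian convolution with reflecting boundaries, so a
#' constant map is unchanged and mass is conserved in the interior; the
#' result is the "nucleus map" whose local maxima are nucleus candidates.
#'
#' @param map matrix (probability map); attributes are preserved.
#' @param sigma Gaussian sigma in grid units (> 0). Values below 0.05 return
#'   the input unchanged (identity limit).
#' @return smoothed matrix.
#' @export
smooth_to_nucleus_map <- function(map, sigma) {
  stopifnot(is.numeric(sigma), sigma > 0)
  if (sigma < 0.05) return(map)
  k <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-k:k)^2) / (2 * sigma^2))
  w <- w / sum(w)
  reflect_idx <- function(i, n) {
    # reflect about the edges (1 and n) until inside
    i <- abs(i - 1) + 1
    over <- i > n
    i[over] <- 2 * n - i[over]
    # a second pass covers kernels wider than the axis
    i <- abs(i - 1) + 1
    i[i > n] <- 2 * n - i[i > n]
    i
  }
  conv1 <- function(m) { # along rows (dimension 1)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in -k:k) {
      out <- out + w[j + k + 1L] * m[reflect_idx(seq_len(n) + j, n), , drop = FALSE]
    }
    out
  }
  out <- t(conv1(t(conv1(map))))
  attributes(out) <- attributes(map)[c("dim", "grid", "offset_px")]
  out
}

#' Detect nuclei from a nucleus map
#'
#' Treats every interior map cell above the detection threshold as a peak
#' candidate, refines each to sub-grid precision by a separable quadratic
#' fit, keeps the strongest candidate per `min_separation_px` neighbourhood
#' (greedy non-maximum suppression), and expands each kept peak to a closed
#' polygon contour: along `n_rays` radial directions the
#' contour radius is where the total stain optical density first falls below
#' `contour_level` of the per-nucleus peak density, clipped at the maximum
#' radius. Centers are reported in 0-based image-pixel coordinates.
#'
#' @param nucleus_map smoothed map from [smooth_to_nucleus_map()].
#' @param image the source image (array or list with `image`).
#' @param params a [scoring_params()].
#' @param background RGB background level.
#' @param decon optional precomputed [stain_deconvolve()] result.
#' @return data.frame with columns center_row, center_col, peak, radius_px
#'   and a list column `contour` (n_rays x 2 matrices, closed implicitly);
#'   zero rows when nothing is detected.
#' @export
extract_nuclei <- function(nucleus_map, image, params = scoring_params(),
                           background = c(1, 1, 1), decon = NULL) {
  img <- if (is.list(image)) image$image else image
  grid <- attr(nucleus_map, "grid") %||% params$grid
  offset <- attr(nucleus_map, "offset_px") %||% ((grid$window_px - 1) / 2)
  m <- nucleus_map
  nr <- nrow(m); nc <- ncol(m)
  empty <- data.frame(center_row = numeric(0), center_col = numeric(0),
                      peak = numeric(0), radius_px = numeric(0))
  empty$contour <- list()
  if (nr < 3L || nc < 3L) return(empty)

  # candidate peaks: every interior cell above the detection threshold;
  # greedy non-maximum suppression below resolves ridges between close
  # nuclei that a plain local-maximum test would merge
  idx <- which(m > params$detection_threshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  pr <- idx[, 1]; pc <- idx[, 2]
  val <- m[cbind(pr, pc)]

  # sub-grid quadratic refinement along each axis (skipped at map borders
  # where the 3-point stencil is incomplete)
  refine <- function(vm1, v0, vp1) {
    den <- vm1 - 2 * v0 + vp1
    d <- ifelse(abs(den) > 1e-12, 0.5 * (vm1 - vp1) / den, 0)
    pmin(pmax(d, -0.5), 0.5)
  }
  dr <- dc <- numeric(length(val))
  ir <- pr > 1L & pr < nr
  ic <- pc > 1L & pc < nc
  dr[ir] <- refine(m[cbind(pr[ir] - 1L, pc[ir])], val[ir],
                   m[cbind(pr[ir] + 1L, pc[ir])])
  dc[ic] <- refine(m[cbind(pr[ic], pc[ic] - 1L)], val[ic],
                   m[cbind(pr[ic], pc[ic] + 1L)])
  cr <- (pr - 1L + dr) * grid$stride_px + offset
  cc <- (pc - 1L + dc) * grid$stride_px + offset

  # non-maximum suppression, strongest peak first
  ord <- order(-val, cr, cc)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0L ||
        min((cr[keep] - cr[i])^2 + (cc[keep] - cc[i])^2) >=
        params$min_separation_px^2) {
      keep <- c(keep, i)
    }
  }
  keep <- keep[order(cr[keep], cc[keep])]
  cr <- cr[keep]; cc <- cc[keep]; val <- val[keep]

  if (is.null(decon)) decon <- stain_deconvolve(img, background)
  dens <- decon$hematoxylin + decon$dab
  h <- nrow(dens); w <- ncol(dens)
  at <- function(r, c) dens[cbind(pmin(pmax(round(r) + 1L, 1L), h),
                                  pmin(pmax(round(c) + 1L, 1L), w))]
  max_r <- params$max_radius_factor * params$expected_radius_px
  angles <- seq(0, 2 * pi, length.out = params$n_rays + 1L)[-(params$n_rays + 1L)]
  steps <- seq(0.5, max_r, by = 0.5)

  contours <- vector("list", length(cr))
  radius <- numeric(length(cr))
  for (i in seq_along(cr)) {
    peak_dens <- mean(at(cr[i] + c(-1, -1, -1, 0, 0, 0, 1, 1, 1),
                         cc[i] + rep(c(-1, 0, 1), 3)))
    lev <- params$contour_level * peak_dens
    rad <- vapply(angles, function(a) {
      v <- at(cr[i] + steps * cos(a), cc[i] + steps * sin(a))
      hit <- which(v < lev)
      if (length(hit) == 0L) max_r else steps[hit[1]]
    }, numeric(1))
    contours[[i]] <- cbind(row = cr[i] + rad * cos(angles),
                           col = cc[i] + rad * sin(angles))
    radius[i] <- mean(rad)
  }
  out <- data.frame(center_row = cr, center_col = cc, peak = val,
                    radius_px = radius)
  out$contour <- contours
  out
}

# Mean DAB amount and brightness inside a star-shaped ray contour.
contour_stats <- function(decon, center, ray_radii, angles) {
  h <- nrow(decon$dab); w <- ncol(decon$dab)
  rmax <- max(ray_radii)
  rr <- max(0, floor(center[1] - rmax)):min(h - 1, ceiling(center[1] + rmax))
  cc <- max(0, floor(center[2] - rmax)):min(w - 1, ceiling(center[2] + rmax))
  if (length(rr) == 0L || length(cc) == 0L) {
    return(list(area = 0L, dab = NA_real_, brightness = NA_real_))
  }
  dy <- outer(rr - center[1], rep(1, length(cc)))
  dx <- outer(rep(1, length(rr)), cc - center[2])
  d <- sqrt(dy^2 + dx^2)
  ang <- atan2(dx, dy) %% (2 * pi) # matches (cos, sin) on (row, col)
  # linear interpolation of the ray radius at each pixel's angle
  k <- length(angles)
  step <- 2 * pi / k
  i0 <- floor(ang / step)
  frac <- ang / step - i0
  r_at <- ray_radii[(i0 %% k) + 1L] * (1 - frac) + ray_radii[((i0 + 1L) %% k) + 1L] * frac
  inside <- d <= r_at
  area <- sum(inside)
  if (area == 0L) return(list(area = 0L, dab = NA_real_, brightness = NA_real_))
  px_r <- rr[row(dy)[inside]] + 1L
  px_c <- cc[col(dx)[inside]] + 1L
  list(area = area,
       dab = mean(decon$dab[cbind(px_r, px_c)]),
       brightness = mean(decon$brightness[cbind(px_r, px_c)]))
}

#' Classify DAB positivity of detected nuclei
#'
#' Stain-separates the pixels inside each nucleus contour into hematoxylin
#' and DAB amounts; a nucleus is Ki67-positive iff its mean DAB amount
#' exceeds `dab_threshold` and its mean brightness stays below
#' `brightness_threshold`. Contours with fewer than 3 px are flagged invalid
#' and excluded from counts.
#'
#' @param image source image (array or list with `image`).
#' @param calls data.frame from [extract_nuclei()].
#' @param params a [scoring_params()].
#' @param background RGB background level.
#' @param decon optional precomputed [stain_deconvolve()] result.
#' @return `calls` with columns dab_od, brightness, valid, positive added.
#' @export
classify_positivity <- function(image, calls, params = scoring_params(),
                                background = c(1, 1, 1), decon = NULL) {
  img <- if (is.list(image)) image$image else image
  if (is.null(decon)) decon <- stain_deconvolve(img, background)
  n <- nrow(calls)
  dab <- numeric(n); bri <- numeric(n); valid <- logical(n)
  angles <- seq(0, 2 * pi, length.out = params$n_rays + 1L)[-(params$n_rays + 1L)]
  for (i in seq_len(n)) {
    ctr <- c(calls$center_row[i], calls$center_col[i])
    rays <- sqrt(rowSums((calls$contour[[i]] - rep(ctr, each = params$n_rays))^2))
    st <- contour_stats(decon, ctr, rays, angles)
    valid[i] <- st$area >= 3L
    dab[i] <- st$dab; bri[i] <- st$brightness
  }
  calls$dab_od <- dab
  calls$brightness <- bri
  calls$valid <- valid
  calls$positive <- valid & !is.na(dab) & dab > params$dab_threshold &
    bri < params$brightness_threshold
  calls
}

#' Detect and classify all nuclei in an image
#'
#' Runs the full chain: probability map, Gaussian nucleus map, peak
#' extraction, contouring, and DAB positivity.
#'
#' @param image array or [generate_slide()] result (whose spec supplies the
#'   background level).
#' @param classifier trained patch classifier.
#' @param params a [scoring_params()].
#' @param background RGB background; taken from the slide spec when present.
#' @return classified calls data.frame (see [classify_positivity()]).
#' @export
detect_nuclei <- function(image, classifier, params = scoring_params(),
                          background = NULL) {
  if (is.list(image) && !is.null(image$spec)) {
    background <- background %||% image$spec$background
  }
  background <- background %||% c(1, 1, 1)
  img <- if (is.list(image)) image$image else image
  pm <- compute_probability_map(img, classifier, params$grid, background)
  nm <- smooth_to_nucleus_map(pm, params$sigma_grid)
  decon <- stain_deconvolve(img, background)
  calls <- extract_nuclei(nm, img, params, background, decon = decon)
  if (nrow(calls) == 0L) {
    calls$dab_od <- numeric(0); calls$brightness <- numeric(0)
    calls$valid <- logical(0); calls$positive <- logical(0)
    return(calls)
  }
  classify_positivity(img, calls, params, background, decon = decon)
}

# Count a call set inside a half-open ROI and form a Ki67 score.
score_from_calls <- function(calls, roi, area_mm2) {
  inroi <- calls$valid &
    calls$center_row >= roi[1] & calls$center_row < roi[3] &
    calls$center_col >= roi[2] & calls$center_col < roi[4]
  n_total <- sum(inroi)
  n_positive <- sum(inroi & calls$positive)
  structure(list(
    roi = roi, area_mm2 = area_mm2, n_total = n_total,
    n_positive = n_positive,
    index = if (n_total > 0L) 100 * n_positive / n_total else NA_real_,
    defined = n_total > 0L
  ), class = "ki67_score")
}

#' @export
print.ki67_score <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("Ki67 score: undefined (no nuclei in %.4f mm^2 ROI)\n", x$area_mm2))
  } else {
    cat(sprintf("Ki67 score: %.1f%% (%d of %d nuclei positive, %.4f mm^2 ROI)\n",
                x$index, x$n_positive, x$n_total, x$area_mm2))
  }
  invisible(x)
}

#' Ki67 proliferation index of a region of interest
#'
#' Runs the full scoring chain restricted to a half-open rectangular ROI
#' `c(r0, c0, r1, c1)` (0-based; rows r0 <= r < r1, columns c0 <= c < c1).
#' The image is analysed with a margin of one window width around the ROI so
#' nuclei near its edge are seen in full; only calls whose centers lie inside
#' the ROI are counted. A cell-free ROI yields a flagged undefined score, not
#' zero.
#'
#' @param image array or [generate_slide()] result.
#' @param roi integer vector c(r0, c0, r1, c1).
#' @param classifier trained patch classifier.
#' @param params a [scoring_params()].
#' @param background RGB background level (from the slide spec when present).
#' @param microns_per_pixel resolution; from the slide spec when present.
#' @return a `ki67_score`: list(roi, area_mm2, n_total, n_positive, index,
#'   defined).
#' @export
score_roi <- function(image, roi, classifier, params = scoring_params(),
                      background = NULL, microns_per_pixel = NULL) {
  if (is.list(image) && !is.null(image$spec)) {
    background <- background %||% image$spec$background
    microns_per_pixel <- microns_per_pixel %||% image$spec$microns_per_pixel
  }
  microns_per_pixel <- microns_per_pixel %||% params$microns_per_pixel
  img <- if (is.list(image)) image$image else image
  h <- dim(img)[1]; w <- dim(img)[2]
  stopifnot(length(roi) == 4L, roi[1] >= 0, roi[2] >= 0,
            roi[3] <= h, roi[4] <= w, roi[1] < roi[3], roi[2] < roi[4])
  m <- params$grid$window_px
  r0 <- max(0L, floor(roi[1]) - m); r1 <- min(h, ceiling(roi[3]) + m)
  c0 <- max(0L, floor(roi[2]) - m); c1 <- min(w, ceiling(roi[4]) + m)
  sub <- img[(r0 + 1L):r1, (c0 + 1L):c1, , drop = FALSE]
  calls <- detect_nuclei(sub, classifier, params, background %||% c(1, 1, 1))
  calls$center_row <- calls$center_row + r0
  calls$center_col <- calls$center_col + c0
  area_mm2 <- (roi[3] - roi[1]) * (roi[4] - roi[2]) * (microns_per_pixel / 1000)^2
  score_from_calls(calls, roi, area_mm2)
}

#' Find the highest-Ki67 hotspot ROI
#'
#' Automated surrogate for the pathologist's practice of marking the square
#' region (1 mm^2 by default) with the highest Ki67 positivity: square ROIs
#' slide over the image at a coarse stride and the ROI maximising the Ki67
#' index among those holding at least `min_cells` nuclei is returned; ties
#' break toward larger nucleus counts, then the top-left position.
#'
#' @param image array or [generate_slide()] result.
#' @param classifier trained patch classifier.
#' @param roi_area_mm2 hotspot area (default 1 mm^2).
#' @param params a [scoring_params()]; `min_cells` gates candidate ROIs.
#' @param coarse_stride_px ROI sliding stride (default a quarter ROI side).
#' @param background,microns_per_pixel as in [score_roi()].
#' @return list(roi, score) where score is the winning `ki67_score`.
#' @export
find_hotspot <- function(image, classifier, roi_area_mm2 = 1,
                         params = scoring_params(), coarse_stride_px = NULL,
                         background = NULL, microns_per_pixel = NULL) {
  if (is.list(image) && !is.null(image$spec)) {
    background <- background %||% image$spec$background
    microns_per_pixel <- microns_per_pixel %||% image$spec$microns_per_pixel
  }
  microns_per_pixel <- microns_per_pixel %||% params$microns_per_pixel
  img <- if (is.list(image)) image$image else image
  h <- dim(img)[1]; w <- dim(img)[2]
  side <- round(sqrt(roi_area_mm2) * 1000 / microns_per_pixel)
  if (side > h || side > w) {
    stop(sprintf("image (%d x %d px) smaller than a %.3g mm^2 ROI (%d px side)",
                 h, w, roi_area_mm2, side), call. = FALSE)
  }
  stride <- coarse_stride_px %||% max(1L, round(side / 4))
  calls <- detect_nuclei(img, classifier, params, background %||% c(1, 1, 1))
  area_mm2 <- (side * microns_per_pixel / 1000)^2
  r_starts <- unique(c(seq(0L, h - side, by = stride), h - side))
  c_starts <- unique(c(seq(0L, w - side, by = stride), w - side))
  best <- NULL
  for (r0 in r_starts) for (c0 in c_starts) {
    sc <- score_from_calls(calls, c(r0, c0, r0 + side, c0 + side), area_mm2)
    if (sc$n_total < params$min_cells) next
    if (is.null(best) ||
        sc$index > best$index + 1e-12 ||
        (abs(sc$index - best$index) <= 1e-12 && sc$n_total > best$n_total)) {
      best <- sc
    }
  }
  if (is.null(best)) {
    stop(sprintf(paste0("no ROI reaches min_cells = %d nuclei; ",
                        "consider a lower `min_cells`"),
                 params$min_cells), call. = FALSE)
  }
  list(roi = best$roi, score = best)
}
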