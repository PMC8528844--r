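#' Specification for a synthetic H-DAB slide
#'
#' Describes a synthetic Ki67-stained image: tumor nuclei are rendered as
#' roughly elliptical blobs, DAB-positive (brown-dominant) or
#' hematoxylin-only (blue-dominant); stromal nuclei are elongated and
#' hematoxylin-only, standing in for the stroma/"noise" the patch classifier
#' must treat as background. All pixel coordinates in this package are
#' 0-based, row-major, top-left anchored.
#'
#' @param width_px,height_px image dimensions in pixels.
#' @param microns_per_pixel resolution (default 0.5 um/px, so a 1 mm^2 region
#'   of interest is 2000 x 2000 px).
#' @param n_tumor_nuclei,n_stromal_nuclei nucleus counts (non-negative).
#' @param positive_fraction fraction of tumor nuclei that are DAB-positive,
#'   in \[0, 1\]. The realised positive count is the nearest integer
#'   (ties to even) of `positive_fraction * n_tumor_nuclei`.
#' @param nucleus_radius_px mean tumor nucleus radius in px.
#' @param radius_jitter relative sd of per-nucleus radius.
#' @param min_separation_px minimum distance between nucleus centers; default
#'   3 radii, which the 10 px probability-map grid can resolve.
#' @param hema_mean,hema_sd,dab_mean,dab_sd per-nucleus chromogen OD amounts
#'   (mean/sd of the hematoxylin and DAB stain intensities).
#' @param background RGB triple of unstained background, in \[0, 1\].
#' @param noise_sd pixelwise RGB noise sd.
#' @param seed integer seed; the slide is deterministic given the spec.
#' @return an object of class `slide_spec`.
#' @export
slide_spec <- function(width_px = 320L, height_px = 320L,
                       microns_per_pixel = 0.5,
                       n_tumor_nuclei = 110L, n_stromal_nuclei = 22L,
                       positive_fraction = 0.2,
                       nucleus_radius_px = 7, radius_jitter = 0.12,
                       min_separation_px = 3 * nucleus_radius_px,
                       hema_mean = 0.55, hema_sd = 0.08,
                       dab_mean = 0.70, dab_sd = 0.10,
                       background = c(0.94, 0.93, 0.96),
                       noise_sd = 0.008, seed = 1L) {
  spec <- structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    microns_per_pixel = microns_per_pixel,
    n_tumor_nuclei = as.integer(n_tumor_nuclei),
    n_stromal_nuclei = as.integer(n_stromal_nuclei),
    positive_fraction = positive_fraction,
    nucleus_radius_px = nucleus_radius_px, radius_jitter = radius_jitter,
    min_separation_px = min_separation_px,
    hema_mean = hema_mean, hema_sd = hema_sd,
    dab_mean = dab_mean, dab_sd = dab_sd,
    background = background, noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "slide_spec")
  validate_slide_spec(spec)
  spec
}

#' @keywords internal
validate_slide_spec <- function(spec) {
  stopifnot(spec$width_px > 0, spec$height_px > 0,
            spec$microns_per_pixel > 0,
            spec$n_tumor_nuclei >= 0, spec$n_stromal_nuclei >= 0,
            spec$nucleus_radius_px > 0, spec$min_separation_px > 0,
            length(spec$background) == 3L,
            all(spec$background > 0 & spec$background <= 1))
  stop_if_not_scalar_prob(spec$positive_fraction, "positive_fraction")
  invisible(spec)
}

# Rejection-sample nucleus centers (0-based, continuous) with a hard minimum
# separation; margin keeps every nucleus fully inside the image.
place_centers <- function(n, height, width, margin, min_sep) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  if (2 * margin >= height || 2 * margin >= width) {
    stop("image too small for nuclei of this radius", call. = FALSE)
  }
  centers <- matrix(NA_real_, n, 2L)
  placed <- 0L
  max_tries <- 300L * n
  tries <- 0L
  while (placed < n && tries < max_tries) {
    tries <- tries + 1L
    cand <- c(runif(1, margin, height - margin), runif(1, margin, width - margin))
    if (placed > 0L) {
      d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
        (centers[seq_len(placed), 2] - cand[2])^2
      if (min(d2) < min_sep^2) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  if (placed < n) {
    stop(sprintf(paste0("cannot place %d nuclei at min separation %.1f px in a ",
                        "%d x %d image; achievable maximum here is about %d"),
                 n, min_sep, height, width, placed), call. = FALSE)
  }
  centers
}

#' Generate a synthetic H-DAB slide with ground-truth nuclei
#'
#' Renders the slide under the two-chromogen Beer-Lambert mixing model of
#' [hdab_stain_matrix()]: per-nucleus stain amounts accumulate in OD space and
#' are mapped to RGB as `background * 10^-OD`. DAB-positive tumor nuclei get a
#' DAB load plus a light hematoxylin counterstain; negative tumor nuclei and
#' stromal nuclei are hematoxylin-only, stroma elongated and fainter.
#'
#' @param spec a [slide_spec()].
#' @return list with `image` (height x width x 3 array in \[0, 1\]),
#'   `ground_truth` (data.frame: center_row, center_col (0-based px),
#'   radius_px, cell_class in tumor/stroma, ki67_positive), and the `spec`.
#' @export
generate_slide <- function(spec) {
  validate_slide_spec(spec)
  with_seed(spec$seed, {
    h <- spec$height_px; w <- spec$width_px
    r <- spec$nucleus_radius_px
    n_tum <- spec$n_tumor_nuclei; n_str <- spec$n_stromal_nuclei
    n <- n_tum + n_str
    centers <- place_centers(n, h, w, margin = 1.6 * r, min_sep = spec$min_separation_px)

    n_pos <- as.integer(round(spec$positive_fraction * n_tum))
    pos <- rep(FALSE, n)
    if (n_tum > 0L) pos[sample.int(n_tum)[seq_len(n_pos)]] <- TRUE
    cls <- rep(c("tumor", "stroma"), c(n_tum, n_str))

    radii <- pmax(r * (1 + rnorm(n, 0, spec$radius_jitter)), 2)
    radii[cls == "stroma"] <- radii[cls == "stroma"] * 0.8
    aspect <- ifelse(cls == "tumor", runif(n, 1.0, 1.25), runif(n, 2.5, 3.5))
    theta <- runif(n, 0, pi)
    amp_h <- pmax(rnorm(n, spec$hema_mean, spec$hema_sd), 0.15)
    amp_d <- pmax(rnorm(n, spec$dab_mean, spec$dab_sd), 0.2)

    od_h <- matrix(0, h, w)
    od_d <- matrix(0, h, w)
    for (i in seq_len(n)) {
      a <- radii[i] * sqrt(aspect[i])   # semi-major
      b <- radii[i] / sqrt(aspect[i])   # semi-minor
      rmax <- ceiling(a) + 1L
      rr <- max(1L, floor(centers[i, 1] - rmax) + 1L):min(h, ceiling(centers[i, 1] + rmax) + 1L)
      cc <- max(1L, floor(centers[i, 2] - rmax) + 1L):min(w, ceiling(centers[i, 2] + rmax) + 1L)
      dy <- (rr - 1) - centers[i, 1]
      dx <- (cc - 1) - centers[i, 2]
      ct <- cos(theta[i]); st <- sin(theta[i])
      u1 <- outer(dy, dx, function(y, x) (y * ct + x * st) / a)
      u2 <- outer(dy, dx, function(y, x) (-y * st + x * ct) / b)
      u <- sqrt(u1^2 + u2^2)
      wgt <- pmin(pmax((1.05 - u) / 0.30, 0), 1) # soft-edged ellipse
      if (cls[i] == "stroma") {
        od_h[rr, cc] <- od_h[rr, cc] + 0.55 * amp_h[i] * wgt
      } else if (pos[i]) {
        od_d[rr, cc] <- od_d[rr, cc] + amp_d[i] * wgt
        od_h[rr, cc] <- od_h[rr, cc] + 0.15 * amp_h[i] * wgt
      } else {
        od_h[rr, cc] <- od_h[rr, cc] + amp_h[i] * wgt
      }
    }

    m <- hdab_stain_matrix()
    img <- array(0, c(h, w, 3L))
    for (ch in 1:3) {
      plane <- spec$background[ch] * 10^-(od_h * m[ch, 1] + od_d * m[ch, 2])
      plane <- plane + rnorm(h * w, 0, spec$noise_sd)
      img[, , ch] <- pmin(pmax(plane, 0), 1)
    }

    gt <- data.frame(
      center_row = centers[, 1], center_col = centers[, 2],
      radius_px = radii, cell_class = cls, ki67_positive = pos,
      stringsAsFactors = FALSE
    )
    list(image = img, ground_truth = gt, spec = spec)
  })
}

#' Ground-truth Ki67 index of a slide or region
#'
#' @param ground_truth ground-truth data.frame from [generate_slide()].
#' @param roi optional half-open ROI `c(r0, c0, r1, c1)` (0-based) restricting
#'   the count to nuclei whose centers fall inside.
#' @return percentage of tumor nuclei flagged Ki67-positive; `NA` when the
#'   region holds no tumor nuclei.
#' @export
ground_truth_index <- function(ground_truth, roi = NULL) {
  gt <- ground_truth
  if (!is.null(roi)) {
    keep <- gt$center_row >= roi[1] & gt$center_row < roi[3] &
      gt$center_col >= roi[2] & gt$center_col < roi[4]
    gt <- gt[keep, , drop = FALSE]
  }
  tum <- gt[gt$cell_class == "tumor", , drop = FALSE]
  if (nrow(tum) == 0L) return(NA_real_)
  100 * sum(tum$ki67_positive) / nrow(tum)
}

#' Write / read a slide image (8-bit RGB PNG or TIFF)
#'
#' @param image height x width x 3 array in \[0, 1\].
#' @param path output path; format chosen by extension (.png or .tif/.tiff;
#'   TIFF requires the `tiff` package).
#' @export
write_slide_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required to write TIFF", call. = FALSE)
    }
    tiff::writeTIFF(image, path, bits.per.sample = 8L)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_slide_image
#' @export
read_slide_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required to read TIFF", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}

#' Write / read ground-truth nuclei as CSV
#' @param ground_truth data.frame as produced by [generate_slide()].
#' @param path CSV path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  utils::write.csv(ground_truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  gt <- utils::read.csv(path, stringsAsFactors = FALSE)
  gt$ki67_positive <- as.logical(gt$ki67_positive)
  gt
}
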