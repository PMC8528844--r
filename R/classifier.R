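#' Patch features for nucleus-probability classification
#'
#' The classical patch backend summarises each 80 x 80 window by stain and
#' intensity statistics of nested, window-centered boxes: mean hematoxylin
#' amount, mean DAB amount and mean brightness over the full window and over
#' centered 20 px and 10 px boxes, the brightness sd over the 20 px box, and
#' center-minus-window contrasts. Computed either per patch or, much faster,
#' for all grid anchors at once from summed-area tables of the deconvolved
#' image (the two paths agree exactly).
#'
#' @name patch_features
#' @keywords internal
NULL

patch_feature_names <- function() {
  c("h_full", "d_full", "b_full",
    "h_c20", "d_c20", "b_c20",
    "h_c10", "d_c10", "b_c10",
    "b_sd20", "h_contrast", "d_contrast", "b_contrast",
    "centroid_off20", "centroid_off10")
}

# Summed-area tables of the stain-deconvolved image.
image_feature_tables <- function(image, background = c(1, 1, 1)) {
  img <- if (is.list(image)) image$image else image
  dec <- stain_deconvolve(img, background)
  tot <- dec$hematoxylin + dec$dab
  h <- dim(img)[1]; w <- dim(img)[2]
  list(
    h = integral_image(dec$hematoxylin),
    d = integral_image(dec$dab),
    b = integral_image(dec$brightness),
    b2 = integral_image(dec$brightness^2),
    t = integral_image(tot),
    tr = integral_image(tot * (seq_len(h) - 1L)),
    tc = integral_image(tot * matrix(seq_len(w) - 1L, h, w, byrow = TRUE)),
    height = h, width = w,
    decon = dec
  )
}

# Feature matrix for a set of 0-based window anchors.
anchor_features <- function(ft, anchors, window_px) {
  wp <- as.integer(window_px)
  box_mean <- function(sat, r0, c0, s) box_sum(sat, r0, c0, s, s) / (s * s)
  centered <- function(s) {
    off <- (wp - s) %/% 2L
    list(r0 = anchors$row + off, c0 = anchors$col + off, s = as.integer(s))
  }
  sizes <- c(full = wp, c20 = min(20L, wp), c10 = min(10L, wp))
  cols <- list()
  for (nm in names(sizes)) {
    bx <- centered(sizes[[nm]])
    cols[[paste0("h_", nm)]] <- box_mean(ft$h, bx$r0, bx$c0, bx$s)
    cols[[paste0("d_", nm)]] <- box_mean(ft$d, bx$r0, bx$c0, bx$s)
    cols[[paste0("b_", nm)]] <- box_mean(ft$b, bx$r0, bx$c0, bx$s)
  }
  bx <- centered(sizes[["c20"]])
  m1 <- box_mean(ft$b, bx$r0, bx$c0, bx$s)
  m2 <- box_mean(ft$b2, bx$r0, bx$c0, bx$s)
  cols[["b_sd20"]] <- sqrt(pmax(m2 - m1^2, 0))
  cols[["h_contrast"]] <- cols[["h_c10"]] - cols[["h_full"]]
  cols[["d_contrast"]] <- cols[["d_c10"]] - cols[["d_full"]]
  cols[["b_contrast"]] <- cols[["b_c10"]] - cols[["b_full"]]
  # offset of the stain-mass centroid from the window center: small when a
  # nucleus sits at the center, large on off-center or empty windows
  for (nm in c("c20", "c10")) {
    bx <- centered(sizes[[nm]])
    tsum <- box_sum(ft$t, bx$r0, bx$c0, bx$s, bx$s)
    rsum <- box_sum(ft$tr, bx$r0, bx$c0, bx$s, bx$s)
    csum <- box_sum(ft$tc, bx$r0, bx$c0, bx$s, bx$s)
    ctr_r <- anchors$row + (wp - 1) / 2
    ctr_c <- anchors$col + (wp - 1) / 2
    weak <- tsum < 1e-6
    off <- sqrt((rsum / pmax(tsum, 1e-6) - ctr_r)^2 +
                  (csum / pmax(tsum, 1e-6) - ctr_c)^2)
    off[weak] <- bx$s / 2 # no stain mass: maximal uninformative offset
    cols[[paste0("centroid_off", sub("c", "", nm))]] <- pmin(off, bx$s / 2)
  }
  x <- do.call(cbind, cols[patch_feature_names()])
  colnames(x) <- patch_feature_names()
  x
}

#' Features of a single extracted patch
#'
#' @param patch window_px x window_px x 3 array.
#' @param background RGB background level used for optical density.
#' @return named numeric vector of patch features.
#' @export
patch_features_one <- function(patch, background = c(1, 1, 1)) {
  ft <- image_feature_tables(patch, background)
  drop(anchor_features(ft, data.frame(row = 0L, col = 0L), dim(patch)[1]))
}

#' Sample labeled training patches from annotated slides
#'
#' Draws `per_slide` distinct window anchors per slide (without replacement),
#' labels each window positive when a ground-truth tumor-nucleus center lies
#' within `label_radius_px` of the window center (stroma and background are
#' the negative class), and splits the pooled set into training and validation
#' with exact counts from [training_split_counts()].
#'
#' @param slides list of [generate_slide()] results (each with `image`,
#'   `ground_truth`, `spec`).
#' @param per_slide patches sampled per slide.
#' @param split_fraction training fraction in (0, 1).
#' @param seed integer; sampling and the split shuffle are reproducible.
#' @param grid a [patch_grid()].
#' @param label_radius_px positive-label radius around the window center
#'   (default 7 px, the nominal nucleus radius).
#' @return list with `train` and `val` (each `list(x, y)`), and `counts`.
#' @export
sample_training_patches <- function(slides, per_slide, split_fraction = 0.8,
                                    seed = 1L, grid = patch_grid(),
                                    label_radius_px = 7) {
  counts <- training_split_counts(length(slides), per_slide, split_fraction)
  with_seed(seed, {
    xs <- vector("list", length(slides))
    ys <- vector("list", length(slides))
    for (i in seq_along(slides)) {
      sl <- slides[[i]]
      img <- sl$image
      anchors <- grid_anchors(grid, dim(img)[1], dim(img)[2])
      if (per_slide > nrow(anchors)) {
        stop(sprintf("per_slide = %d exceeds the %d distinct anchors available",
                     per_slide, nrow(anchors)), call. = FALSE)
      }
      take <- sort(sample.int(nrow(anchors), per_slide))
      anchors <- anchors[take, , drop = FALSE]
      ft <- image_feature_tables(img, sl$spec$background)
      xs[[i]] <- anchor_features(ft, anchors, grid$window_px)
      ys[[i]] <- label_anchors(anchors, sl$ground_truth, grid$window_px,
                               label_radius_px)
    }
    x <- do.call(rbind, xs)
    y <- unlist(ys)
    perm <- sample.int(nrow(x))
    x <- x[perm, , drop = FALSE]; y <- y[perm]
    idx <- seq_len(counts$n_train)
    list(train = list(x = x[idx, , drop = FALSE], y = y[idx]),
         val = list(x = x[-idx, , drop = FALSE], y = y[-idx]),
         counts = counts)
  })
}

# TRUE where a tumor-nucleus center lies within label_radius_px of the
# window center.
label_anchors <- function(anchors, ground_truth, window_px, label_radius_px) {
  ctr_r <- anchors$row + (window_px - 1) / 2
  ctr_c <- anchors$col + (window_px - 1) / 2
  tum <- ground_truth[ground_truth$cell_class == "tumor", , drop = FALSE]
  if (nrow(tum) == 0L) return(rep(FALSE, nrow(anchors)))
  vapply(seq_along(ctr_r), function(i) {
    min((tum$center_row - ctr_r[i])^2 + (tum$center_col - ctr_c[i])^2) <=
      label_radius_px^2
  }, logical(1))
}

#' Train the patch-level nucleus classifier
#'
#' The default `classical` backend is a ridge-regularised logistic regression
#' (glmnet, fixed lambda) on the patch features — deterministic given the
#' training set. The backend is a pluggable contract: any model exposing a
#' probability in \[0, 1\] per patch can stand behind the same interface (a
#' convolutional network would slot in here; none ships with this package).
#'
#' @param train list(x, y) from [sample_training_patches()].
#' @param val optional list(x, y); held-out accuracy at probability 0.5 is
#'   computed and stored as `validation_accuracy`.
#' @param backend `"classical"` (default) or `"cnn"` (not bundled; errors).
#' @param seed integer, kept for reproducibility metadata.
#' @param lambda ridge penalty of the classical backend.
#' @return object of class `patch_classifier`.
#' @export
train_patch_classifier <- function(train, val = NULL, backend = "classical",
                                   seed = 1L, lambda = 0.03) {
  backend <- match.arg(backend, c("classical", "cnn"))
  if (backend == "cnn") {
    stop("no CNN backend is bundled; supply your own via the classifier contract",
         call. = FALSE)
  }
  y <- as.logical(train$y)
  if (length(unique(y)) < 2L) {
    stop("training set must contain both nucleus and background patches",
         call. = FALSE)
  }
  fit <- with_seed(seed, glmnet::glmnet(
    train$x, factor(y, levels = c(FALSE, TRUE)),
    family = "binomial", alpha = 0, lambda = lambda, standardize = TRUE
  ))
  clf <- structure(list(
    backend = backend, fit = fit, lambda = lambda, seed = as.integer(seed),
    feature_names = colnames(train$x),
    n_train = length(y), n_val = if (is.null(val)) 0L else length(val$y),
    validation_accuracy = NA_real_
  ), class = "patch_classifier")
  if (!is.null(val) && length(val$y) > 0L) {
    p <- predict_probability(clf, val$x)
    clf$validation_accuracy <- mean((p > 0.5) == as.logical(val$y))
  }
  clf
}

#' Predict nucleus probability for patch features
#'
#' @param classifier a [train_patch_classifier()] result.
#' @param x feature matrix (rows = patches) or a single named feature vector.
#' @return vector of probabilities in \[0, 1\].
#' @export
predict_probability <- function(classifier, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  x <- x[, classifier$feature_names, drop = FALSE]
  as.numeric(stats::predict(classifier$fit, newx = x, type = "response",
                            s = classifier$lambda))
}

#' @export
print.patch_classifier <- function(x, ...) {
  cat(sprintf("patch_classifier (backend: %s, n_train = %d, n_val = %d)\n",
              x$backend, x$n_train, x$n_val))
  if (!is.na(x$validation_accuracy)) {
    cat(sprintf("  held-out accuracy: %.4f\n", x$validation_accuracy))
  }
  invisible(x)
}
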