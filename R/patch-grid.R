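#' Sliding-window patch grid
#'
#' The scoring pipeline applies an 80 x 80 px sliding window with a 10 px
#' stride to the stained image, producing one tile per anchor; the same grid
#' serves both training-patch extraction and inference. Anchors are 0-based
#' top-left corners in row-major order; every window lies fully inside the
#' image, so the grid has `floor((dim - window) / stride) + 1` anchors per
#' axis.
#'
#' @param window_px window side in pixels (default 80).
#' @param stride_px anchor spacing in pixels (default 10).
#' @return object of class `patch_grid`.
#' @export
patch_grid <- function(window_px = 80L, stride_px = 10L) {
  stopifnot(window_px >= 1L, stride_px >= 1L)
  structure(list(window_px = as.integer(window_px),
                 stride_px = as.integer(stride_px)),
            class = "patch_grid")
}

#' Grid dimensions and anchors for an image
#'
#' @param grid a [patch_grid()].
#' @param height_px,width_px image dimensions.
#' @return `grid_dims()`: c(n_rows, n_cols) of the anchor lattice.
#'   `grid_anchors()`: data.frame (row, col) of 0-based anchors, row-major.
#' @export
grid_dims <- function(grid, height_px, width_px) {
  if (height_px < grid$window_px || width_px < grid$window_px) {
    stop(sprintf("image (%d x %d) smaller than the %d px window",
                 height_px, width_px, grid$window_px), call. = FALSE)
  }
  c(floor((height_px - grid$window_px) / grid$stride_px) + 1L,
    floor((width_px - grid$window_px) / grid$stride_px) + 1L)
}

#' @rdname grid_dims
#' @export
grid_anchors <- function(grid, height_px, width_px) {
  nd <- grid_dims(grid, height_px, width_px)
  rows <- (seq_len(nd[1]) - 1L) * grid$stride_px
  cols <- (seq_len(nd[2]) - 1L) * grid$stride_px
  data.frame(row = rep(rows, each = nd[2]), col = rep(cols, times = nd[1]))
}

#' Extract sliding-window patches from an image
#'
#' @param image height x width x 3 array, or a list with an `image` element.
#' @param grid a [patch_grid()].
#' @return list of window_px x window_px x 3 arrays in row-major anchor order.
#' @export
extract_patches <- function(image, grid = patch_grid()) {
  img <- if (is.list(image)) image$image else image
  anchors <- grid_anchors(grid, dim(img)[1], dim(img)[2])
  wp <- grid$window_px
  lapply(seq_len(nrow(anchors)), function(i) {
    r0 <- anchors$row[i]; c0 <- anchors$col[i]
    img[(r0 + 1L):(r0 + wp), (c0 + 1L):(c0 + wp), , drop = FALSE]
  })
}

#' Training/validation patch bookkeeping
#'
#' Exact counts for sampling a fixed number of patches per slide and splitting
#' them into training and validation sets: `total = n_slides * per_slide`,
#' `n_train = round(total * split_fraction)`, `n_val = total - n_train`.
#'
#' @param n_slides number of slides.
#' @param per_slide patches sampled per slide.
#' @param split_fraction fraction assigned to training, in (0, 1).
#' @return list(total, n_train, n_val).
#' @export
training_split_counts <- function(n_slides, per_slide, split_fraction = 0.8) {
  stopifnot(n_slides >= 1L, per_slide >= 1L)
  if (!is.numeric(split_fraction) || split_fraction <= 0 || split_fraction >= 1) {
    stop("`split_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  total <- as.numeric(n_slides) * as.numeric(per_slide)
  n_train <- round(total * split_fraction)
  list(total = total, n_train = n_train, n_val = total - n_train)
}
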