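#' H-DAB stain model
#'
#' Two-chromogen Beer-Lambert model used both to render synthetic slides and
#' to deconvolve real or synthetic RGB images back into per-stain amounts.
#' Unit stain vectors are the standard H-DAB pair (hematoxylin blue,
#' 3,3'-diaminobenzidine brown) normalised to unit length in optical-density
#' (OD) space; transmitted light follows I = I0 * 10^(-OD).
#'
#' @format A 3 x 2 matrix; columns are the hematoxylin and DAB unit vectors.
#' @keywords internal
hdab_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.268, 0.570, 0.776)
  m <- cbind(hematoxylin = h / sqrt(sum(h^2)), dab = d / sqrt(sum(d^2)))
  rownames(m) <- c("r", "g", "b")
  m
}

#' Convert RGB intensities to optical density
#'
#' @param rgb numeric array (h x w x 3) or matrix (n x 3), values in (0, 1].
#' @param background length-3 RGB of unstained background (I0 per channel).
#' @return same shape as `rgb`, OD = -log10(I / I0), floored at 0.
#' @keywords internal
rgb_to_od <- function(rgb, background = c(1, 1, 1)) {
  eps <- 1 / 512
  if (length(dim(rgb)) == 3L) {
    od <- rgb
    for (ch in 1:3) {
      od[, , ch] <- pmax(-log10(pmax(rgb[, , ch], eps) / background[ch]), 0)
    }
  } else {
    od <- -log10(pmax(rgb, eps) / rep(background, each = nrow(rgb)))
    od <- pmax(od, 0)
  }
  od
}

#' Deconvolve an RGB image into hematoxylin and DAB amounts
#'
#' Solves the two-stain linear mixing model per pixel by least squares
#' (pseudo-inverse of the stain matrix), clamping amounts at zero. This is the
#' inverse of the rendering model used by [generate_slide()], so stain
#' separation is well-posed on synthetic slides.
#'
#' @param img numeric array (h x w x 3) in \[0, 1\].
#' @param background length-3 RGB background level.
#' @return list with matrices `hematoxylin` and `dab` (h x w, OD amounts) and
#'   `brightness` (mean RGB per pixel).
#' @export
stain_deconvolve <- function(img, background = c(1, 1, 1)) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  od <- rgb_to_od(img, background)
  m <- hdab_stain_matrix()
  pinv <- solve(crossprod(m), t(m)) # 2 x 3
  h <- dim(img)[1]; w <- dim(img)[2]
  odm <- matrix(od, ncol = 3L) # pixels x 3, column-major over (h, w)
  amounts <- odm %*% t(pinv)
  amounts[amounts < 0] <- 0
  list(
    hematoxylin = matrix(amounts[, 1], h, w),
    dab = matrix(amounts[, 2], h, w),
    brightness = matrix(rowMeans(matrix(img, ncol = 3L)), h, w)
  )
}
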