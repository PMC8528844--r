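# Internal helpers shared across modules.

#' Run code with a temporarily seeded RNG
#'
#' Seeds the generator for the duration of `expr` and restores the caller's
#' RNG state afterwards, so generators are deterministic given their `seed`
#' field without clobbering user randomness.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Summed-area table of a matrix
#'
#' Returns a (h+1) x (w+1) cumulative table `S` such that the sum of
#' `m[r1:r2, c1:c2]` (1-based, inclusive) is
#' `S[r2+1, c2+1] - S[r1, c2+1] - S[r2+1, c1] + S[r1, c1]`.
#' @keywords internal
integral_image <- function(m) {
  s <- rbind(0, apply(m, 2, cumsum))
  cbind(0, t(apply(s, 1, cumsum)))
}

#' Sum of box regions from a summed-area table
#'
#' `r0`, `c0` are 0-based top-left corners, `h`, `w` box dimensions; vectors
#' are recycled. Returns the vector of box sums.
#' @keywords internal
box_sum <- function(sat, r0, c0, h, w) {
  sat[cbind(r0 + h + 1L, c0 + w + 1L)] - sat[cbind(r0 + 1L, c0 + w + 1L)] -
    sat[cbind(r0 + h + 1L, c0 + 1L)] + sat[cbind(r0 + 1L, c0 + 1L)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
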