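#' Paired scores from two Ki67 readers
#'
#' Container for method-agreement analyses between two readouts of the same
#' samples (e.g. visual scoring versus the automated pipeline, or pipeline
#' versus ground truth). Pairs with a missing value in either reader are
#' dropped explicitly (pairwise-complete filtering) before any statistic.
#'
#' @param reader_a,reader_b numeric vectors of Ki67 percentages in \[0, 100\].
#' @param sample_id optional identifiers.
#' @return object of class `paired_scores` (a data.frame).
#' @export
paired_scores <- function(reader_a, reader_b, sample_id = NULL) {
  stopifnot(length(reader_a) == length(reader_b))
  if (is.null(sample_id)) sample_id <- seq_along(reader_a)
  keep <- !is.na(reader_a) & !is.na(reader_b)
  out <- data.frame(sample_id = sample_id[keep],
                    reader_a = reader_a[keep], reader_b = reader_b[keep])
  if (nrow(out) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  class(out) <- c("paired_scores", "data.frame")
  out
}

#' Spearman rank correlation between two readers
#'
#' Rho is computed on average-tie ranks; the p-value uses the exact
#' permutation null for n <= 8 (no ties) and the t approximation otherwise.
#'
#' @param paired a [paired_scores()] object (or anything with `reader_a` and
#'   `reader_b` columns).
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return list(rho, p_value, n, method, degenerate).
#' @export
spearman_concordance <- function(paired, alternative = "two.sided") {
  a <- paired$reader_a; b <- paired$reader_b
  n <- length(a)
  if (length(unique(a)) < 2L || length(unique(b)) < 2L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined", degenerate = TRUE))
  }
  rho <- stats::cor(rank(a), rank(b))
  ties <- anyDuplicated(a) > 0L || anyDuplicated(b) > 0L
  if (n <= 8L && !ties) {
    ct <- stats::cor.test(a, b, method = "spearman", exact = TRUE,
                          alternative = alternative)
    p <- ct$p.value
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- switch(alternative,
                two.sided = 2 * stats::pt(-abs(tstat), n - 2),
                greater = stats::pt(tstat, n - 2, lower.tail = FALSE),
                less = stats::pt(tstat, n - 2))
    p <- min(p, 1)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p, n = n, method = method, degenerate = FALSE)
}

#' Intraclass correlation for method agreement
#'
#' Single-rater intraclass correlation from the two-way mean-squares
#' decomposition. The default is the absolute-agreement, two-way
#' random-effects form ICC(2,1) — the standard for method-agreement studies,
#' penalising systematic offsets between readers — with the McGraw-Wong
#' F-based confidence interval and the F test of ICC = 0. The consistency
#' form ICC(C,1), insensitive to a constant offset, is also available.
#'
#' @param paired a [paired_scores()] object.
#' @param confidence confidence level for the interval (default 0.95).
#' @param form "agreement" (ICC(2,1), default) or "consistency" (ICC(C,1)).
#' @return list(icc, ci_low, ci_high, p_value, form, n, degenerate).
#' @export
icc_concordance <- function(paired, confidence = 0.95, form = "agreement") {
  form <- match.arg(form, c("agreement", "consistency"))
  x <- cbind(paired$reader_a, paired$reader_b)
  n <- nrow(x); k <- ncol(x)
  if (n < 5L) stop("need at least 5 pairs for the ICC", call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps) {
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p_value = NA_real_, form = form, n = n, degenerate = TRUE))
  }
  alpha <- 1 - confidence
  if (form == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    fl <- (msr / mse) / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- (msr / mse) * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_low <- stats::qf(1 - alpha / 2, n - 1, v)
    f_up <- stats::qf(1 - alpha / 2, v, n - 1)
    ci <- c(
      n * (msr - f_low * mse) /
        (f_low * (k * msc + (k * n - k - n) * mse) + n * msr),
      n * (f_up * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_up * msr)
    )
  }
  fstat <- msr / mse
  p <- stats::pf(fstat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc, ci_low = ci[1], ci_high = ci[2], p_value = p,
       form = form, n = n, degenerate = FALSE)
}

#' Classification accuracy with per-class rates
#'
#' @param predicted,truth equal-length label vectors (any type coercible to
#'   character; logical vectors are reported as positive/negative).
#' @return list(accuracy, n, per_class) where per_class holds sensitivity
#'   (recall) per observed class.
#' @export
classification_accuracy <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) >= 1L)
  pred <- as.character(predicted); tr <- as.character(truth)
  acc <- mean(pred == tr)
  per_class <- vapply(sort(unique(tr)), function(cl) {
    mean(pred[tr == cl] == cl)
  }, numeric(1))
  list(accuracy = acc, n = length(tr), per_class = per_class)
}
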