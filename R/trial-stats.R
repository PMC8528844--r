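#' Resolve a Ki67 value-or-range to a scalar
#'
#' Pathologists sometimes report a range of percent positivity; the analysis
#' convention is to use the highest number. Scalars pass through; for ranges
#' the upper bound is returned.
#'
#' @param x numeric vector of point values, or a two-column matrix /
#'   data.frame of (low, high) ranges (rows with `NA` high are treated as
#'   scalars).
#' @return numeric vector of resolved percentages.
#' @export
resolve_range <- function(x) {
  if (is.null(dim(x))) return(as.numeric(x))
  x <- as.matrix(x)
  stopifnot(ncol(x) == 2L)
  lo <- x[, 1]; hi <- x[, 2]
  bad <- !is.na(hi) & !is.na(lo) & lo > hi
  if (any(bad)) stop("range low exceeds high in rows: ",
                     paste(which(bad), collapse = ", "), call. = FALSE)
  ifelse(is.na(hi), lo, hi)
}

#' Log10(Ki67 + 1) transform
#'
#' Ki67 percentages are lognormally distributed and contain zeros, so tests
#' on levels use `log10(ki67 + 1)`.
#'
#' @param ki67 non-negative percentages.
#' @return log10(ki67 + 1).
#' @export
ki67_log10 <- function(ki67) {
  if (any(ki67 < 0, na.rm = TRUE)) stop("Ki67 must be >= 0", call. = FALSE)
  log10(ki67 + 1)
}

#' Paired post/pre change ratio with the +1 convention
#'
#' @param pre,post non-negative Ki67 percentages.
#' @return data.frame(ratio, log10_ratio) where
#'   `ratio = (post + 1) / (pre + 1)`, defined for zeros by the +1
#'   convention, and `log10_ratio = log10(ratio)`.
#' @export
paired_change_ratio <- function(pre, post) {
  if (any(pre < 0, na.rm = TRUE) || any(post < 0, na.rm = TRUE)) {
    stop("Ki67 must be >= 0", call. = FALSE)
  }
  r <- (post + 1) / (pre + 1)
  data.frame(ratio = r, log10_ratio = log10(r))
}

#' One-sample / paired Wilcoxon signed-rank test
#'
#' Paired pre/post comparison with average tie ranks; zero differences are
#' dropped (classic Wilcoxon, not the Pratt variant). The null is exact for
#' n <= 12 retained pairs (full sign-flip enumeration, valid under tied
#' magnitudes) and a tie-corrected normal approximation otherwise. `alternative` refers to the location of `post` relative to
#' `pre`; the trial's one-sided question "did Ki67 fall?" is
#' `alternative = "less"`.
#'
#' @param pre,post paired numeric vectors.
#' @param alternative "less" (post < pre), "greater" or "two.sided".
#' @return list(statistic, p_value, n_used, n_zero, method, alternative,
#'   all_zero).
#' @export
wilcoxon_signed_rank <- function(pre, post, alternative = "less") {
  alternative <- match.arg(alternative, c("less", "greater", "two.sided"))
  keep <- !is.na(pre) & !is.na(post)
  d <- post[keep] - pre[keep]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p_value = 1, n_used = 0L,
                n_zero = n_zero, method = "degenerate (all differences zero)",
                alternative = alternative, all_zero = TRUE))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 12L) {
    # exact sign-flip null, valid under tied magnitudes (average ranks)
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)
    p_le <- mean(sums <= w + 1e-9)
    p_ge <- mean(sums >= w - 1e-9)
    p <- switch(alternative, less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    method <- "exact (sign-flip enumeration)"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(
      d, mu = 0, alternative = alternative, exact = FALSE, correct = TRUE
    ))
    p <- wt$p.value
    method <- "normal approximation (tie-corrected)"
  }
  list(statistic = w, p_value = p, n_used = n, n_zero = n_zero,
       method = method, alternative = alternative, all_zero = FALSE)
}

#' Mann-Whitney U test on two groups of ratios
#'
#' Exact permutation null (full enumeration of group assignments, ties
#' handled by average ranks) when the pooled size is at most 12,
#' tie-corrected normal approximation otherwise. `alternative = "greater"`
#' tests that group A is stochastically greater than group B (in the trial:
#' premenopausal post/pre ratios larger, i.e. a smaller treatment effect).
#'
#' @param a,b numeric vectors (n >= 3 each).
#' @param alternative "greater", "less" or "two.sided".
#' @return list(statistic (U for group a), p_value, n_a, n_b, method,
#'   alternative).
#' @export
mann_whitney <- function(a, b, alternative = "greater") {
  alternative <- match.arg(alternative, c("greater", "less", "two.sided"))
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3L || length(b) < 3L) {
    stop("each group needs at least 3 observations", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  rk <- rank(c(a, b))
  u <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  if (na + nb <= 12L) {
    # exact permutation null over all group assignments (ties allowed)
    splits <- utils::combn(na + nb, na)
    us <- apply(splits, 2, function(ix) sum(rk[ix])) - na * (na + 1) / 2
    p_ge <- mean(us >= u - 1e-9)
    p_le <- mean(us <= u + 1e-9)
    p <- switch(alternative, greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    method <- "exact (permutation enumeration)"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(
      a, b, alternative = alternative, exact = FALSE, correct = TRUE
    ))
    p <- wt$p.value
    method <- "normal approximation (tie-corrected)"
  }
  list(statistic = u, p_value = p, n_a = na, n_b = nb,
       method = method, alternative = alternative)
}

#' Kruskal-Wallis test across three or more groups
#'
#' Tie-corrected H statistic with the chi-square approximation on k - 1
#' degrees of freedom.
#'
#' @param groups list of numeric vectors (>= 3 non-empty groups, each n >= 2).
#' @return list(statistic, p_value, df, n).
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  if (length(groups) < 3L) stop("need at least 3 non-empty groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), n = sum(lengths(groups)))
}

#' Classify patients as responders
#'
#' A responder shows a strict decrease of the readout after treatment; equal
#' values form their own category (they are coded separately from decreases),
#' as do increases. Patients with a missing half of the pair are excluded
#' with a message.
#'
#' @param table a `trial_table` (or any data.frame with the readout columns).
#' @param pre_col,post_col column names of the paired readout.
#' @return factor with levels responder / equal / increase, `NA` for excluded
#'   patients, aligned with `table` rows.
#' @export
classify_responders <- function(table, pre_col = "ki67_pre",
                                post_col = "ki67_post") {
  pre <- table[[pre_col]]; post <- table[[post_col]]
  out <- rep(NA_character_, nrow(table))
  miss <- is.na(pre) | is.na(post)
  if (any(miss)) {
    message(sum(miss), " patient(s) excluded for a missing pair")
  }
  out[!miss & post < pre] <- "responder"
  out[!miss & post == pre] <- "equal"
  out[!miss & post > pre] <- "increase"
  factor(out, levels = c("responder", "equal", "increase"))
}

#' Per-arm effect-size summary
#'
#' Mean percent decrease `100 * (1 - (post + 1)/(pre + 1))` per arm, over all
#' patients and over responders only, with standard errors of the mean and
#' responder counts.
#'
#' @param table a `trial_table`.
#' @param pre_col,post_col paired readout columns.
#' @return data.frame, one row per arm: n_pairs, n_responders,
#'   mean_decrease_all, sem_all, mean_decrease_responders, sem_responders.
#' @export
effect_size_summary <- function(table, pre_col = "ki67_pre",
                                post_col = "ki67_post") {
  cr <- paired_change_ratio(table[[pre_col]], table[[post_col]])
  dec <- 100 * (1 - cr$ratio)
  resp <- !is.na(dec) & table[[post_col]] < table[[pre_col]]
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  arms <- unique(table$arm)
  out <- do.call(rbind, lapply(arms, function(a) {
    sel <- table$arm == a & !is.na(dec)
    data.frame(
      arm = a, n_pairs = sum(sel), n_responders = sum(sel & resp),
      mean_decrease_all = mean(dec[sel]), sem_all = sem(dec[sel]),
      mean_decrease_responders = if (any(sel & resp)) mean(dec[sel & resp]) else NA_real_,
      sem_responders = if (any(sel & resp)) sem(dec[sel & resp]) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Association between residual estradiol and Ki67 effect size
#'
#' Among tamoxifen-treated patients whose post-treatment E2 exceeds the assay
#' detection limit (censored values are excluded), tests the inverse
#' association between post-treatment E2 and the magnitude of Ki67 decrease.
#' Primary readout: one-sided Spearman test of negative correlation between
#' E2 and percent decrease. Secondary: least-squares slope of log10 Ki67
#' ratio on log10 E2, with the one-sided p for a positive slope (higher E2,
#' smaller decrease). Neither is claimed to reproduce any particular
#' published statistic.
#'
#' @param table a `trial_table` with e2_post / e2_post_censored columns.
#' @param detection_limit pmol/L (default 44).
#' @param pre_col,post_col paired Ki67 columns.
#' @return list(n, sufficient, spearman = list(estimate, p_value),
#'   slope = list(estimate, p_value)); when fewer than 5 patients remain the
#'   result is flagged `sufficient = FALSE` with NA statistics.
#' @export
e2_association <- function(table, detection_limit = 44,
                           pre_col = "ki67_pre", post_col = "ki67_post") {
  sel <- table$arm %in% c("tamoxifen_pre", "tamoxifen_post") &
    !is.na(table$e2_post) & table$e2_post > detection_limit
  if (!is.null(table$e2_post_censored)) sel <- sel & !table$e2_post_censored
  sel <- sel & !is.na(table[[pre_col]]) & !is.na(table[[post_col]])
  n <- sum(sel)
  if (n < 5L) {
    return(list(n = n, sufficient = FALSE,
                spearman = list(estimate = NA_real_, p_value = NA_real_),
                slope = list(estimate = NA_real_, p_value = NA_real_)))
  }
  cr <- paired_change_ratio(table[[pre_col]][sel], table[[post_col]][sel])
  dec <- 100 * (1 - cr$ratio)
  e2 <- table$e2_post[sel]
  ct <- suppressWarnings(stats::cor.test(e2, dec, method = "spearman",
                                         alternative = "less"))
  fit <- stats::lm(cr$log10_ratio ~ log10(e2))
  sm <- summary(fit)$coefficients
  slope <- sm[2, 1]
  p_slope <- stats::pt(sm[2, 3], fit$df.residual, lower.tail = FALSE)
  list(n = n, sufficient = TRUE,
       spearman = list(estimate = unname(ct$estimate), p_value = ct$p.value),
       slope = list(estimate = slope, p_value = p_slope))
}

#' Full window-trial paired-response analysis
#'
#' Orchestrates the trial statistics: per-arm one-sided Wilcoxon signed-rank
#' tests on paired Ki67, the Mann-Whitney comparison of pre- versus
#' postmenopausal tamoxifen post/pre ratios (all patients and responders
#' only), the Kruskal-Wallis comparison across the postmenopausal arms,
#' responder classification, per-arm effect sizes, and the E2-gradient
#' association. All p-values are uncorrected for multiple testing and
#' labeled with their sidedness, matching the reporting convention of the
#' analyses this package implements.
#'
#' @param table a `trial_table`.
#' @param alpha nominal significance level recorded in the report.
#' @param detection_limit E2 detection limit in pmol/L.
#' @return list of class `trial_report`.
#' @export
run_trial_analysis <- function(table, alpha = 0.05, detection_limit = 44) {
  arms <- c("tamoxifen_pre", "tamoxifen_post", "anastrozole", "fulvestrant")
  arms <- arms[arms %in% table$arm]
  # paired tests on the log10(Ki67 + 1) scale, the same scale as the
  # post/pre log-ratio convention (differences are log ratios, symmetric
  # about zero under no effect)
  paired_tests <- lapply(arms, function(a) {
    sub <- table[table$arm == a, ]
    wilcoxon_signed_rank(ki67_log10(sub$ki67_pre), ki67_log10(sub$ki67_post),
                         alternative = "less")
  })
  names(paired_tests) <- arms
  ratios <- paired_change_ratio(table$ki67_pre, table$ki67_post)$ratio
  resp <- classify_responders(table)

  mwu <- mwu_resp <- NULL
  if (all(c("tamoxifen_pre", "tamoxifen_post") %in% arms)) {
    a <- ratios[table$arm == "tamoxifen_pre"]
    b <- ratios[table$arm == "tamoxifen_post"]
    mwu <- mann_whitney(a, b, alternative = "greater")
    ar <- ratios[table$arm == "tamoxifen_pre" & resp == "responder"]
    br <- ratios[table$arm == "tamoxifen_post" & resp == "responder"]
    mwu_resp <- if (length(ar) >= 3L && length(br) >= 3L) {
      mann_whitney(ar, br, alternative = "greater")
    }
  }
  post_arms <- c("tamoxifen_post", "anastrozole", "fulvestrant")
  kw <- if (all(post_arms %in% arms)) {
    kruskal_wallis(lapply(post_arms, function(a) ratios[table$arm == a]))
  }
  structure(list(
    n_per_arm = table(factor(table$arm, levels = arms)),
    paired_wilcoxon = paired_tests,
    menopause_comparison = mwu,
    menopause_comparison_responders = mwu_resp,
    postmenopausal_kruskal_wallis = kw,
    responders = table(table$arm, resp),
    effect_sizes = effect_size_summary(table),
    e2 = e2_association(table, detection_limit),
    alpha = alpha,
    note = "all p-values uncorrected; sidedness as labeled per test"
  ), class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  cat("Window-trial paired-response report\n")
  cat("-----------------------------------\n")
  for (a in names(x$paired_wilcoxon)) {
    pt <- x$paired_wilcoxon[[a]]
    cat(sprintf("  %-15s n=%2d  Wilcoxon signed-rank (1-sided, post<pre) p=%.4g\n",
                a, x$n_per_arm[[a]], pt$p_value))
  }
  if (!is.null(x$menopause_comparison)) {
    cat(sprintf("  pre vs post tamoxifen ratios: MWU (1-sided) p=%.4g\n",
                x$menopause_comparison$p_value))
  }
  if (!is.null(x$menopause_comparison_responders)) {
    cat(sprintf("  responders only:              MWU (1-sided) p=%.4g\n",
                x$menopause_comparison_responders$p_value))
  }
  if (!is.null(x$postmenopausal_kruskal_wallis)) {
    cat(sprintf("  postmenopausal arms: Kruskal-Wallis (2-sided) p=%.4g\n",
                x$postmenopausal_kruskal_wallis$p_value))
  }
  cat("  effect sizes (% decrease, all patients):\n")
  es <- x$effect_sizes
  for (i in seq_len(nrow(es))) {
    cat(sprintf("    %-15s %5.1f%% (SEM %.1f), responders only %5.1f%%\n",
                es$arm[i], es$mean_decrease_all[i], es$sem_all[i],
                es$mean_decrease_responders[i]))
  }
  if (x$e2$sufficient) {
    cat(sprintf("  E2 gradient (n=%d): Spearman rho=%.3f, 1-sided p=%.4g\n",
                x$e2$n, x$e2$spearman$estimate, x$e2$spearman$p_value))
  } else {
    cat(sprintf("  E2 gradient: insufficient patients above limit (n=%d)\n", x$e2$n))
  }
  cat("  note:", x$note, "\n")
  invisible(x)
}
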