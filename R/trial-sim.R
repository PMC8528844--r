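#' Specification for a synthetic window-trial table
#'
#' Emulates the paired pre/post design of a presurgical endocrine-therapy
#' window trial: premenopausal patients all receive tamoxifen, postmenopausal
#' patients are randomized to tamoxifen, anastrozole or fulvestrant. Default
#' paired sample sizes match the trial's evaluable pairs (29 premenopausal
#' tamoxifen, 14 postmenopausal tamoxifen, 15 anastrozole, 13 fulvestrant).
#' Per-patient post/pre Ki67 ratios (on the +1 scale) are lognormal with
#' arm-specific arithmetic means — defaults 0.65 for premenopausal and 0.37
#' for postmenopausal tamoxifen, i.e. ~35% and ~63% mean decreases.
#' Estradiol (E2) is lognormal by menopausal status and censored at the assay
#' detection limit (44 pmol/L); for most postmenopausal patients the
#' pre-treatment level falls below the limit. The inverse E2-effect coupling
#' is a Gaussian copula between log post-treatment E2 and log ratio with
#' correlation `e2_coupling`, so higher residual estradiol means a smaller
#' Ki67 decrease while the arm's ratio marginal (hence its mean) is
#' untouched.
#'
#' @param n_per_arm named integer vector of paired sample sizes for arms
#'   tamoxifen_pre, tamoxifen_post, anastrozole, fulvestrant.
#' @param mean_ratio named vector of mean post/pre ratios per arm.
#' @param ratio_mean_type how `mean_ratio` is interpreted: "arithmetic"
#'   (default; the arm's expected ratio, so a mean ratio of 0.37 yields a 63%
#'   mean decrease) or "geometric" (the lognormal median; a geometric mean of
#'   1 makes the log-ratio symmetric about zero, the exact no-effect null of
#'   the paired rank tests).
#' @param ratio_sdlog lognormal sd of the per-patient ratio (log scale).
#' @param ki67_meanlog,ki67_sdlog lognormal parameters of pre-treatment Ki67
#'   (%); draws are truncated to \[`ki67_min`, 100\].
#' @param ki67_min lower truncation of pre-treatment Ki67 (%).
#' @param e2_meanlog,e2_sdlog named (pre/post menopausal) lognormal
#'   parameters of pre-treatment E2 in pmol/L.
#' @param e2_post_sdlog lognormal sd of the post/pre E2 drift.
#' @param e2_limit assay detection limit in pmol/L (default 44).
#' @param e2_coupling copula correlation in \[0, 1) between log post E2 and
#'   log Ki67 ratio.
#' @param duration_mean named vector of mean treatment durations (days).
#' @param duration_sd sd of treatment duration.
#' @param seed integer seed.
#' @return object of class `trial_sim_spec`.
#' @export
trial_sim_spec <- function(
    n_per_arm = c(tamoxifen_pre = 29L, tamoxifen_post = 14L,
                  anastrozole = 15L, fulvestrant = 13L),
    mean_ratio = c(tamoxifen_pre = 0.65, tamoxifen_post = 0.37,
                   anastrozole = 0.33, fulvestrant = 0.42),
    ratio_mean_type = c("arithmetic", "geometric"),
    ratio_sdlog = 0.5,
    ki67_meanlog = log(15), ki67_sdlog = 0.8, ki67_min = 5,
    e2_meanlog = c(pre = log(300), post = log(15)),
    e2_sdlog = c(pre = 0.6, post = 0.7),
    e2_post_sdlog = 0.4,
    e2_limit = 44,
    e2_coupling = 0.5,
    duration_mean = c(tamoxifen_pre = 23.8, tamoxifen_post = 17.4,
                      anastrozole = 19.5, fulvestrant = 21.2),
    duration_sd = 5,
    seed = 1L) {
  arms <- c("tamoxifen_pre", "tamoxifen_post", "anastrozole", "fulvestrant")
  stopifnot(all(arms %in% names(n_per_arm)), all(arms %in% names(mean_ratio)),
            all(arms %in% names(duration_mean)))
  if (any(n_per_arm < 1L)) stop("all sample sizes must be >= 1", call. = FALSE)
  if (any(mean_ratio <= 0)) stop("mean ratios must be > 0", call. = FALSE)
  if (e2_limit <= 0) stop("detection limit must be > 0", call. = FALSE)
  if (e2_coupling < 0 || e2_coupling >= 1) {
    stop("`e2_coupling` must lie in [0, 1)", call. = FALSE)
  }
  ratio_mean_type <- match.arg(ratio_mean_type)
  structure(list(
    n_per_arm = n_per_arm[arms], mean_ratio = mean_ratio[arms],
    ratio_mean_type = ratio_mean_type, ratio_sdlog = ratio_sdlog,
    ki67_meanlog = ki67_meanlog, ki67_sdlog = ki67_sdlog, ki67_min = ki67_min,
    e2_meanlog = e2_meanlog, e2_sdlog = e2_sdlog,
    e2_post_sdlog = e2_post_sdlog, e2_limit = e2_limit,
    e2_coupling = e2_coupling,
    duration_mean = duration_mean[arms], duration_sd = duration_sd,
    seed = as.integer(seed)
  ), class = "trial_sim_spec")
}

#' Arm to menopausal-status mapping
#' @keywords internal
arm_menopause <- function(arm) ifelse(arm == "tamoxifen_pre", "pre", "post")

#' Generate a synthetic window-trial table
#'
#' One record per patient: arm, menopausal status, paired Ki67 percentages,
#' treatment duration, and paired E2 with censoring flags (values below the
#' detection limit are stored at the limit with `censored = TRUE`, never as
#' missing). The post-treatment Ki67 is `(pre + 1) * ratio - 1` clamped to
#' \[0, 100\], so the +1-convention ratio is reproduced exactly except at the
#' clamp boundaries. Deterministic given the spec seed.
#'
#' @param spec a [trial_sim_spec()].
#' @return data.frame of class `trial_table` with columns patient_id, arm,
#'   menopause, ki67_pre, ki67_post, treatment_days, e2_pre, e2_pre_censored,
#'   e2_post, e2_post_censored, true_ratio.
#' @export
generate_trial_table <- function(spec) {
  stopifnot(inherits(spec, "trial_sim_spec"))
  with_seed(spec$seed, {
    rows <- lapply(names(spec$n_per_arm), function(arm) {
      n <- spec$n_per_arm[[arm]]
      men <- arm_menopause(arm)
      # pre-treatment Ki67: truncated lognormal
      ki_pre <- numeric(n)
      for (i in seq_len(n)) {
        repeat {
          v <- stats::rlnorm(1, spec$ki67_meanlog, spec$ki67_sdlog)
          if (v >= spec$ki67_min && v <= 100) break
        }
        ki_pre[i] <- v
      }
      # E2: pre-treatment by menopausal status, post drifts multiplicatively
      z1 <- stats::rnorm(n)
      e2_pre <- exp(spec$e2_meanlog[[men]] + spec$e2_sdlog[[men]] *
                      stats::rnorm(n))
      e2_post <- exp(spec$e2_meanlog[[men]] + spec$e2_sdlog[[men]] * z1) *
        stats::rlnorm(n, 0, spec$e2_post_sdlog)
      # ratio copula-coupled to post E2 (marginal untouched)
      rho <- spec$e2_coupling
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
      meanlog <- if (spec$ratio_mean_type == "arithmetic") {
        log(spec$mean_ratio[[arm]]) - spec$ratio_sdlog^2 / 2
      } else {
        log(spec$mean_ratio[[arm]])
      }
      ratio <- exp(meanlog + spec$ratio_sdlog * z2)
      ki_post <- pmin(pmax((ki_pre + 1) * ratio - 1, 0), 100)
      dur <- pmax(stats::rnorm(n, spec$duration_mean[[arm]], spec$duration_sd), 7)
      data.frame(
        patient_id = paste0(arm, "_", seq_len(n)),
        arm = arm, menopause = men,
        ki67_pre = ki_pre, ki67_post = ki_post,
        treatment_days = dur,
        e2_pre = pmax(e2_pre, spec$e2_limit),
        e2_pre_censored = e2_pre < spec$e2_limit,
        e2_post = pmax(e2_post, spec$e2_limit),
        e2_post_censored = e2_post < spec$e2_limit,
        true_ratio = ratio,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("trial_table", "data.frame")
    out
  })
}

#' Write / read a trial table as TSV
#' @param table a `trial_table` data.frame.
#' @param path TSV path.
#' @export
write_trial_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("trial_table", "data.frame")
  out
}
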