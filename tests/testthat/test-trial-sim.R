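test_that("the trial generator is deterministic with valid ranges", {
  spec <- trial_sim_spec(seed = 12)
  t1 <- generate_trial_table(spec)
  t2 <- generate_trial_table(spec)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 29L + 14L + 15L + 13L)
  expect_true(all(t1$ki67_pre >= 0 & t1$ki67_pre <= 100))
  expect_true(all(t1$ki67_post >= 0 & t1$ki67_post <= 100))
  expect_true(all(t1$menopause[t1$arm == "tamoxifen_pre"] == "pre"))
  expect_true(all(t1$menopause[t1$arm != "tamoxifen_pre"] == "post"))
  # censored E2 stored at the limit, never missing
  expect_true(all(t1$e2_pre >= 44 & t1$e2_post >= 44))
  expect_false(anyNA(t1$e2_pre))
})

test_that("spec validation rejects impossible parameters", {
  expect_error(trial_sim_spec(mean_ratio = c(tamoxifen_pre = 0,
                                             tamoxifen_post = 0.4,
                                             anastrozole = 0.4,
                                             fulvestrant = 0.4)), "> 0")
  expect_error(trial_sim_spec(e2_limit = 0), "limit")
  expect_error(trial_sim_spec(e2_coupling = 1), "0, 1")
  expect_error(trial_sim_spec(n_per_arm = c(tamoxifen_pre = 0L,
                                            tamoxifen_post = 1L,
                                            anastrozole = 1L,
                                            fulvestrant = 1L)), ">= 1")
})

test_that("most postmenopausal pre-treatment E2 values are censored", {
  spec <- trial_sim_spec(n_per_arm = c(tamoxifen_pre = 5L,
                                       tamoxifen_post = 400L,
                                       anastrozole = 5L, fulvestrant = 5L),
                         seed = 8)
  tab <- generate_trial_table(spec)
  cens <- mean(tab$e2_pre_censored[tab$menopause == "post"])
  expect_gte(cens, 0.90)
})

test_that("arm ratio marginals match the spec regardless of coupling", {
  big <- c(tamoxifen_pre = 1000L, tamoxifen_post = 1000L,
           anastrozole = 5L, fulvestrant = 5L)
  for (rho in c(0, 0.6)) {
    tab <- generate_trial_table(trial_sim_spec(n_per_arm = big,
                                               e2_coupling = rho, seed = 14))
    for (arm in c("tamoxifen_pre", "tamoxifen_post")) {
      r <- tab$true_ratio[tab$arm == arm]
      target <- trial_sim_spec()$mean_ratio[[arm]]
      expect_lt(abs(mean(r) - target) / (stats::sd(r) / sqrt(length(r))), 4)
    }
  }
  # post-tamoxifen at ratio 0.37: realised mean decrease ~ 63%
  tab <- generate_trial_table(trial_sim_spec(n_per_arm = big, seed = 15))
  dec <- 100 * (1 - paired_change_ratio(
    tab$ki67_pre[tab$arm == "tamoxifen_post"],
    tab$ki67_post[tab$arm == "tamoxifen_post"])$ratio)
  expect_lt(abs(mean(dec) - 63), 3 * stats::sd(dec) / sqrt(length(dec)) + 0.5)
})

test_that("generator marginals pass a KS check at the spec distributions", {
  spec <- trial_sim_spec(n_per_arm = c(tamoxifen_pre = 5000L,
                                       tamoxifen_post = 5L,
                                       anastrozole = 5L, fulvestrant = 5L),
                         seed = 77)
  tab <- generate_trial_table(spec)
  r <- tab$true_ratio[tab$arm == "tamoxifen_pre"]
  meanlog <- log(spec$mean_ratio[["tamoxifen_pre"]]) - spec$ratio_sdlog^2 / 2
  ks <- suppressWarnings(stats::ks.test(log(r), "pnorm", meanlog,
                                        spec$ratio_sdlog))
  expect_gt(ks$p.value, 0.01)
  # pre-treatment E2 for premenopausal patients: lognormal at spec parameters
  ks2 <- suppressWarnings(stats::ks.test(
    log(tab$e2_pre[tab$menopause == "pre" & !tab$e2_pre_censored]),
    "pnorm", spec$e2_meanlog[["pre"]], spec$e2_sdlog[["pre"]]))
  expect_gt(ks2$p.value, 0.01)
})

test_that("the E2 coupling induces the inverse association it claims", {
  spec <- trial_sim_spec(n_per_arm = c(tamoxifen_pre = 800L,
                                       tamoxifen_post = 5L,
                                       anastrozole = 5L, fulvestrant = 5L),
                         e2_coupling = 0.6, seed = 21)
  tab <- generate_trial_table(spec)
  sel <- tab$arm == "tamoxifen_pre" & !tab$e2_post_censored
  dec <- 100 * (1 - tab$true_ratio[sel])
  expect_lt(stats::cor(tab$e2_post[sel], dec, method = "spearman"), -0.3)
})

test_that("trial tables round-trip through TSV", {
  tab <- generate_trial_table(trial_sim_spec(seed = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial_table(tab, path)
  back <- read_trial_table(path)
  expect_equal(back$ki67_pre, tab$ki67_pre, tolerance = 1e-9)
  expect_identical(back$arm, tab$arm)
  expect_identical(back$e2_pre_censored, tab$e2_pre_censored)
})
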