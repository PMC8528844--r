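test_that("range resolution uses the highest reported number", {
  expect_equal(resolve_range(cbind(10, 20)), 20)
  expect_equal(resolve_range(15), 15)
  expect_equal(resolve_range(cbind(7, 7)), 7)
  expect_equal(resolve_range(cbind(c(5, 3), c(NA, 9))), c(5, 9))
  expect_error(resolve_range(cbind(8, 2)), "low exceeds high")
})

test_that("the log10(Ki67 + 1) transform and +1 ratio behave at the anchors", {
  expect_equal(ki67_log10(0), 0)
  expect_equal(ki67_log10(9), 1)
  expect_equal(ki67_log10(99), 2)
  expect_error(ki67_log10(-1), ">= 0")
  expect_equal(paired_change_ratio(10, 10)$ratio, 1)
  expect_equal(paired_change_ratio(10, 10)$log10_ratio, 0)
  expect_equal(paired_change_ratio(19, 9)$ratio, 0.5)
  expect_equal(paired_change_ratio(0, 0)$ratio, 1)
})

test_that("signed-rank p equals 1/2^n for a uniform shift and matches enumeration", {
  pre <- (1:8) + 5
  res <- wilcoxon_signed_rank(pre, pre - 2, alternative = "less")
  expect_equal(res$p_value, 1 / 2^8)

  all_equal <- wilcoxon_signed_rank(pre, pre)
  expect_true(all_equal$all_zero)
  expect_equal(all_equal$p_value, 1)

  set.seed(5)
  pre <- runif(10, 5, 40)
  post <- pre + rnorm(10, -2, 4)
  res <- wilcoxon_signed_rank(pre, post, alternative = "less")
  # brute-force oracle over all 2^10 sign assignments
  d <- post - pre
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 10)))
  w_all <- drop(signs %*% r)
  expect_equal(res$p_value, mean(w_all <= w_obs + 1e-9))
  res2 <- wilcoxon_signed_rank(pre, post, alternative = "two.sided")
  expect_equal(res2$p_value,
               min(1, 2 * min(mean(w_all <= w_obs + 1e-9),
                              mean(w_all >= w_obs - 1e-9))))
})

test_that("Mann-Whitney matches the exact arrangement null", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(res$p_value, 1 / 20) # most extreme of 6!/(3!3!) arrangements

  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3), alternative = "two.sided")
  expect_equal(same$p_value, 1)

  set.seed(6)
  a <- rnorm(5); b <- rnorm(5, 0.6)
  res <- mann_whitney(a, b, alternative = "greater")
  rk <- rank(c(a, b))
  u_obs <- sum(rk[1:5]) - 15
  splits <- utils::combn(10, 5)
  u_all <- apply(splits, 2, function(ix) sum(rk[ix])) - 15
  expect_equal(res$p_value, mean(u_all >= u_obs - 1e-9)) # all 252 splits
  expect_error(mann_whitney(c(1, 2), c(3, 4, 5)), "at least 3")
})

test_that("Kruskal-Wallis recovers the closed-form H and the permutation null", {
  ident <- kruskal_wallis(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(ident$statistic, 0, tolerance = 1e-12)
  expect_equal(ident$p_value, 1, tolerance = 1e-12)

  # tie-free closed form: rank sums 3, 7, 11 -> H = 12/42 * 89.5 - 21 = 32/7
  sep <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(sep$statistic, 32 / 7, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3, 4:6)), "at least 3")

  set.seed(9)
  g <- list(rnorm(5), rnorm(5, 0.8), rnorm(5, 0.3))
  kw <- kruskal_wallis(g)
  x <- unlist(g); lab <- rep(1:3, each = 5)
  set.seed(1)
  h_perm <- replicate(5000,
                      stats::kruskal.test(split(x, sample(lab)))$statistic)
  p_perm <- mean(h_perm >= kw$statistic - 1e-9)
  expect_lt(abs(kw$p_value - p_perm), 0.02)
})

test_that("responder classification treats equality as its own category", {
  tab <- data.frame(ki67_pre = c(20, 10, 10, NA),
                    ki67_post = c(10, 10, 15, 5))
  expect_message(resp <- classify_responders(tab), "excluded")
  expect_equal(as.character(resp),
               c("responder", "equal", "increase", NA))
})

test_that("effect-size summaries match their definitions", {
  tab <- data.frame(arm = rep("tamoxifen_post", 3),
                    ki67_pre = c(19, 39, 9), ki67_post = c(9, 19, 4))
  es <- effect_size_summary(tab)
  expect_equal(es$mean_decrease_all, 50)
  expect_equal(es$sem_all, 0)
  expect_equal(es$n_responders, 3L)

  # one responder, one doubling patient: all-patient mean < responders-only
  tab2 <- data.frame(arm = "a", ki67_pre = c(19, 9), ki67_post = c(9, 19))
  es2 <- effect_size_summary(tab2)
  expect_lt(es2$mean_decrease_all, es2$mean_decrease_responders)
  # % decrease and ratio are consistent: decrease = 100 * (1 - ratio)
  r <- paired_change_ratio(tab2$ki67_pre, tab2$ki67_post)$ratio
  expect_equal(es2$mean_decrease_all, mean(100 * (1 - r)))
})

test_that("the E2 association flags insufficient data when all are censored", {
  tab <- data.frame(arm = rep("tamoxifen_post", 8), menopause = "post",
                    ki67_pre = runif(8, 10, 30), ki67_post = runif(8, 5, 20),
                    e2_post = rep(44, 8), e2_post_censored = TRUE)
  res <- e2_association(tab)
  expect_false(res$sufficient)
  expect_true(is.na(res$spearman$p_value))
})

test_that("the full trial report is deterministic and null tables stay quiet", {
  tab <- generate_trial_table(trial_sim_spec(seed = 55))
  r1 <- run_trial_analysis(tab)
  r2 <- run_trial_analysis(tab)
  expect_identical(r1, r2)
  expect_match(r1$note, "uncorrected")

  flat <- tab
  flat$ki67_post <- flat$ki67_pre # all ratios exactly 1
  rn <- run_trial_analysis(flat)
  expect_true(all(vapply(rn$paired_wilcoxon, `[[`, numeric(1), "p_value") == 1))
  expect_equal(unname(rn$effect_sizes$mean_decrease_all), rep(0, 4))
})
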