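make_em <- function(seed = 3, ...) {
  tab <- generate_trial_table(trial_sim_spec(seed = seed))
  generate_expression(expression_sim_spec(seed = seed, ...), tab)
}

test_that("expression generation is deterministic with controlled missingness", {
  e1 <- make_em(seed = 4)
  e2 <- make_em(seed = 4)
  expect_identical(e1$values, e2$values)
  # missing fraction close to the requested rate on a larger matrix
  tab <- generate_trial_table(trial_sim_spec(seed = 5))
  em <- generate_expression(expression_sim_spec(missing_rate = 0.05, seed = 5),
                            tab)
  expect_lt(abs(mean(is.na(em$values)) - 0.05), 0.01)
  expect_true(all(rowSums(!is.na(em$values)) >= 1))
  # unknown gene-set members are reported by name
  bad <- expression_sim_spec(gene_sets = list(x = gene_set("x", "NOPE1")),
                             seed = 1)
  expect_error(generate_expression(bad, tab), "NOPE1")
})

test_that("without noise the MKI67 change tracks the patient log ratio exactly", {
  tab <- generate_trial_table(trial_sim_spec(seed = 6))
  spec <- expression_sim_spec(noise_sd = 0, probe_sd = 0, batch_sd = 0,
                              missing_rate = 0, latent_scale = 2, seed = 6)
  em <- generate_expression(spec, tab)
  gmat <- collapse_probes(em$values, em$probe_gene)
  diff <- gmat["MKI67", em$samples$time == "after"] -
    gmat["MKI67", em$samples$time == "before"]
  lr <- log10((tab$ki67_post + 1) / (tab$ki67_pre + 1))
  expect_equal(unname(diff), 2 * lr, tolerance = 1e-10)
})

test_that("knn imputation matches a brute-force oracle and honours contracts", {
  set.seed(11)
  x <- matrix(rnorm(50 * 20), 50, 20)
  x[sample(length(x), 60)] <- NA
  x[1, ] <- rnorm(20) # guarantee at least one complete row
  filled <- knn_impute(x, k = 10)
  expect_identical(filled[!is.na(x)], x[!is.na(x)]) # observed untouched
  expect_false(anyNA(filled))

  # quadratic oracle: explicit all-pairs loop
  oracle <- x
  for (i in 1:50) {
    for (j in which(is.na(x[i, ]))) {
      d <- rep(Inf, 50)
      for (u in 1:50) {
        if (u == i) next
        shared <- !is.na(x[i, ]) & !is.na(x[u, ])
        if (!any(shared) || is.na(x[u, j])) next
        d[u] <- sqrt(mean((x[i, shared] - x[u, shared])^2))
      }
      nb <- order(d, seq_len(50))[1:10]
      nb <- nb[is.finite(d[nb])]
      oracle[i, j] <- mean(x[nb, j])
    }
  }
  expect_equal(filled, oracle, tolerance = 1e-12)

  # a duplicated row donates its value exactly at k = 1
  y <- matrix(rnorm(8 * 6), 8, 6)
  y[2, ] <- y[1, ]
  y[2, 3] <- NA
  expect_equal(knn_impute(y, k = 1)[2, 3], y[1, 3])
  # fully-missing rows are named in the error
  z <- y; z[5, ] <- NA
  rownames(z) <- paste0("p", 1:8)
  expect_error(knn_impute(z, k = 2), "p5")
  expect_equal(knn_impute(y[, 1:6], k = 1)[!is.na(y)], y[!is.na(y)])
})

test_that("probe collapse takes per-gene medians with the even-count convention", {
  x <- rbind(c(1, 4), c(2, 5), c(9, 6), c(7, 7), c(1, 0), c(3, 2))
  pg <- data.frame(probe_id = paste0("p", 1:6),
                   gene = c("g1", "g1", "g1", "g2", "g3", "g3"))
  out <- collapse_probes(x, pg)
  expect_equal(out["g1", ], c(2, 5)) # odd count: middle value
  expect_equal(out["g2", ], c(7, 7)) # single probe passes through
  expect_equal(out["g3", ], c(2, 1)) # even count: mean of middle two

  # collapse-then-subset equals subset-then-collapse for disjoint sets
  em <- make_em(seed = 7, missing_rate = 0)
  g_all <- collapse_probes(em$values, em$probe_gene)
  sub_genes <- em$gene_sets$AURKA$genes
  rows <- em$probe_gene$gene %in% sub_genes
  g_sub <- collapse_probes(em$values[rows, , drop = FALSE],
                           em$probe_gene[rows, , drop = FALSE])
  expect_equal(g_all[rownames(g_sub), ], g_sub)
})

test_that("signature scores are weighted means with exact linearity", {
  gmat <- matrix(rnorm(5 * 8, 7), 5, 8,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  one <- signature_score(gmat, gene_set("solo", "g2"), standardize = FALSE)
  expect_equal(one$score, unname(gmat["g2", ]))

  s_pos <- signature_score(gmat, gene_set("ab", c("g1", "g2")),
                           standardize = FALSE)
  s_neg <- signature_score(gmat, gene_set("ab", c("g1", "g2"), c(1, -1)),
                           standardize = FALSE)
  expect_equal(s_pos$score - s_neg$score, unname(gmat["g2", ]))

  expect_warning(
    low <- signature_score(gmat, gene_set("half", c("g1", "missing1", "m2"))),
    "absent")
  expect_true(attr(low, "low_coverage"))
  expect_error(signature_score(gmat, gene_set("none", "absent_gene")),
               "no genes")
})

test_that("noise-free signature scores rank-match the latent factor", {
  tab <- generate_trial_table(trial_sim_spec(seed = 8))
  spec <- expression_sim_spec(noise_sd = 0, probe_sd = 0, batch_sd = 0,
                              missing_rate = 0, loading_range = c(1, 1),
                              seed = 8)
  em <- generate_expression(spec, tab)
  gmat <- collapse_probes(em$values, em$probe_gene)
  sc <- signature_score(gmat, em$gene_sets$AURKA)
  lr <- log10((tab$ki67_post + 1) / (tab$ki67_pre + 1))
  latent_after_minus_before <- 2 * lr
  d <- sc$score[em$samples$time == "after"] -
    sc$score[em$samples$time == "before"]
  expect_gt(stats::cor(d, latent_after_minus_before, method = "spearman"),
            0.999)
})

test_that("the moderated t equals the ordinary paired t when the prior is off", {
  em <- make_em(seed = 9, missing_rate = 0)
  gmat <- collapse_probes(em$values, em$probe_gene)
  sel <- em$samples$arm == "tamoxifen_post"
  res <- moderated_t(gmat[1:50, sel], em$samples$patient_id[sel],
                     em$samples$time[sel], prior_df = 0)
  pats <- unique(em$samples$patient_id[sel])
  for (g in c(1, 17, 42)) {
    before <- gmat[g, sel][em$samples$time[sel] == "before"]
    after <- gmat[g, sel][em$samples$time[sel] == "after"]
    tt <- stats::t.test(after, before, paired = TRUE)
    expect_equal(res$t[g], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p_value[g], tt$p.value, tolerance = 1e-12)
  }
})

test_that("shrinkage concentrates variance estimates under a common truth", {
  set.seed(13)
  n_genes <- 400; n <- 6
  d <- matrix(rnorm(n_genes * n, 0, 1), n_genes, n) # shared true variance 1
  gmat <- cbind(matrix(0, n_genes, n), d) # before zeros, after = diffs
  rownames(gmat) <- paste0("g", seq_len(n_genes))
  patient <- rep(paste0("p", 1:n), 2)
  time <- rep(c("before", "after"), each = n)
  res <- moderated_t(gmat, patient, time)
  s2_raw <- apply(d, 1, stats::var)
  d0 <- attr(res, "prior_df")
  s02 <- attr(res, "prior_var")
  s2_post <- if (is.infinite(d0)) rep(s02, n_genes) else
    (d0 * s02 + (n - 1) * s2_raw) / (d0 + n - 1)
  expect_lt(stats::var(s2_post), stats::var(s2_raw))
  expect_gt(d0, 1) # strong shared-variance signal, heavy shrinkage
})

test_that("the moderated t agrees closely with an independent implementation", {
  skip_if_not_installed("limma")
  set.seed(14)
  n_genes <- 200; n <- 8
  d <- matrix(rnorm(n_genes * n, 0, exp(rnorm(n_genes, 0, 0.4))),
              n_genes, n)
  d[1:10, ] <- d[1:10, ] + 1.5
  gmat <- cbind(matrix(0, n_genes, n), d)
  rownames(gmat) <- paste0("g", seq_len(n_genes))
  res <- moderated_t(gmat, rep(paste0("p", 1:n), 2),
                     rep(c("before", "after"), each = n))
  fit <- limma::eBayes(limma::lmFit(d, matrix(1, n, 1)))
  expect_gt(stats::cor(res$t, fit$t[, 1]), 0.999)
  expect_equal(attr(res, "prior_df"), fit$df.prior, tolerance = 0.2)
})

test_that("arm comparisons on expression changes behave at their anchors", {
  # identical difference vectors -> one-sided p = 0.5, ANOVA p = 1
  n <- 6
  diffs <- rnorm(n)
  gmat <- matrix(0, 1, 8 * n, dimnames = list("MKI67", NULL))
  samples <- data.frame(
    patient_id = rep(paste0("p", 1:(4 * n)), 2),
    time = rep(c("before", "after"), each = 4 * n),
    arm = rep(rep(c("tamoxifen_pre", "tamoxifen_post", "anastrozole",
                    "fulvestrant"), each = n), 2)
  )
  gmat[1, samples$time == "after"] <- rep(diffs, 4)
  res <- compare_arm_effects_mrna(gmat, samples)
  expect_equal(res$menopause_t$p_value, 0.5, tolerance = 1e-9)
  expect_equal(res$postmenopausal_anova$p_value, 1, tolerance = 1e-9)
})

test_that("the full expression report detects the simulated proliferation drop", {
  em <- make_em(seed = 16)
  rep <- run_expression_analysis(em)
  expect_true(all(rep$mki67_p < 0.05))
  for (s in names(rep$signature_wilcoxon)) {
    ps <- vapply(rep$signature_wilcoxon[[s]], `[[`, numeric(1), "p_value")
    expect_true(all(ps < 0.05))
  }
})

test_that("expression matrices round-trip through TSV with metadata", {
  em <- make_em(seed = 18)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(em, path)
  back <- read_expression_matrix(path)
  expect_equal(back$values, em$values, tolerance = 1e-9)
  expect_identical(back$samples$sample_id, em$samples$sample_id)
  # gene-set files round-trip too
  gs_path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_set(em$gene_sets$GENE70, gs_path)
  gs <- read_gene_set(gs_path)
  expect_identical(gs$genes, em$gene_sets$GENE70$genes)
  expect_identical(gs$weights, em$gene_sets$GENE70$weights)
})
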