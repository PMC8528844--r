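#' Default end-to-end run configuration
#'
#' A plain nested list, losslessly round-trippable through YAML, holding one
#' explicit seed per stochastic stage plus the stage parameters that differ
#' from package defaults. `slide_panel` controls the synthetic concordance
#' panel (number of ROIs and the range of true positive fractions).
#'
#' @param out_dir output directory for [run_end_to_end()].
#' @return named list of class `run_config`.
#' @export
default_run_config <- function(out_dir = "ki67window_run") {
  structure(list(
    out_dir = out_dir,
    seeds = list(slides = 101L, patches = 11L, classifier = 2L,
                 trial = 31L, expression = 41L),
    slide_panel = list(n_rois = 20L, positive_fraction_range = c(0.05, 0.60),
                      n_train_slides = 4L, per_slide = 400L,
                      split_fraction = 0.8),
    scoring = list(detection_threshold = 0.25, min_separation_px = 15,
                   dab_threshold = 0.2, brightness_threshold = 0.8,
                   min_cells = 30L),
    trial = list(alpha = 0.05, e2_limit = 44),
    expression = list(k = 10L, center_batches = FALSE)
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Static checks of the module invariants; returns `character(0)` when the
#' configuration is acceptable, otherwise the list of violations (warnings
#' prefixed "warning:"). Never mutates its input.
#'
#' @param config a [default_run_config()]-shaped list.
#' @return character vector of violations.
#' @export
validate_run_config <- function(config) {
  v <- character(0)
  need_seeds <- c("slides", "patches", "classifier", "trial", "expression")
  missing_seed <- setdiff(need_seeds, names(config$seeds %||% list()))
  if (length(missing_seed) > 0L) {
    v <- c(v, paste0("missing seed(s): ", paste(missing_seed, collapse = ", ")))
  }
  pf <- config$slide_panel$positive_fraction_range
  if (!is.null(pf) && (any(pf < 0) || any(pf > 1))) {
    v <- c(v, "slide_panel$positive_fraction_range outside [0, 1]")
  }
  sc <- config$scoring
  if (!is.null(sc$detection_threshold) &&
      (sc$detection_threshold <= 0 || sc$detection_threshold >= 1)) {
    v <- c(v, "scoring$detection_threshold outside (0, 1)")
  }
  if (!is.null(sc$window_px) && !is.null(sc$stride_px) &&
      sc$stride_px > sc$window_px) {
    v <- c(v, "warning: stride exceeds window; pixels between anchors go unexamined")
  }
  if (!is.null(config$trial$e2_limit) && config$trial$e2_limit <= 0) {
    v <- c(v, "trial$e2_limit must be positive")
  }
  if (!is.null(config$expression$k) && config$expression$k < 1) {
    v <- c(v, "expression$k must be >= 1")
  }
  v
}

#' Read / write a run configuration as YAML
#' @param config a run configuration list.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' Run the full synthetic pipeline end to end
#'
#' Executes the five stages on synthetic data: (1) simulate a slide panel
#' with ground truth, (2) train the patch classifier and score every panel
#' ROI, (3) validate the automated indices against ground truth (Spearman +
#' ICC), (4) simulate a trial table and run the paired-response analysis,
#' (5) simulate expression data and run the expression analysis. Per-stage
#' outputs and a manifest (inputs, parameters, file checksums) are written
#' under `config$out_dir`; identical configurations give identical manifest
#' checksums.
#'
#' @param config a [default_run_config()]; violations abort the run.
#' @return the manifest (invisibly a list), with stage summaries.
#' @export
run_end_to_end <- function(config = default_run_config()) {
  viol <- validate_run_config(config)
  hard <- viol[!startsWith(viol, "warning:")]
  if (length(hard) > 0L) {
    stop("invalid configuration:\n  ", paste(hard, collapse = "\n  "),
         call. = FALSE)
  }
  for (w in viol[startsWith(viol, "warning:")]) warning(w, call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  sp <- config$slide_panel
  sc <- config$scoring
  params <- scoring_params(detection_threshold = sc$detection_threshold,
                           min_separation_px = sc$min_separation_px,
                           dab_threshold = sc$dab_threshold,
                           brightness_threshold = sc$brightness_threshold,
                           min_cells = sc$min_cells)

  # 1. simulate slides
  panel <- stage("simulate", {
    pf <- seq(sp$positive_fraction_range[1], sp$positive_fraction_range[2],
              length.out = sp$n_rois)
    lapply(seq_along(pf), function(i) {
      generate_slide(slide_spec(positive_fraction = pf[i],
                                seed = config$seeds$slides + i))
    })
  })
  train_slides <- stage("simulate", {
    pf <- c(0.1, 0.3, 0.5, 0.2)
    lapply(seq_len(sp$n_train_slides), function(i) {
      generate_slide(slide_spec(positive_fraction = pf[(i - 1L) %% 4L + 1L],
                                seed = config$seeds$slides + 1000L + i))
    })
  })

  # 2. train + score
  scored <- stage("score", {
    samp <- sample_training_patches(train_slides, per_slide = sp$per_slide,
                                    split_fraction = sp$split_fraction,
                                    seed = config$seeds$patches)
    clf <- train_patch_classifier(samp$train, samp$val,
                                  seed = config$seeds$classifier)
    roi <- c(60, 60, 260, 260)
    rows <- lapply(seq_along(panel), function(i) {
      s <- score_roi(panel[[i]], roi, clf, params)
      data.frame(slide = i, index_auto = s$index,
                 index_truth = ground_truth_index(panel[[i]]$ground_truth, roi),
                 n_total = s$n_total, n_positive = s$n_positive,
                 area_mm2 = s$area_mm2)
    })
    list(classifier = clf, table = do.call(rbind, rows))
  })
  utils::write.csv(scored$table, file.path(config$out_dir, "roi_scores.csv"),
                   row.names = FALSE)

  # 3. validate
  agreement <- stage("validate", {
    pairs <- paired_scores(scored$table$index_truth, scored$table$index_auto)
    list(spearman = spearman_concordance(pairs),
         icc = icc_concordance(pairs),
         classifier_accuracy = scored$classifier$validation_accuracy)
  })

  # 4. trial statistics
  trial <- stage("trial-stats", {
    tab <- generate_trial_table(trial_sim_spec(seed = config$seeds$trial))
    write_trial_table(tab, file.path(config$out_dir, "trial_table.tsv"))
    run_trial_analysis(tab, alpha = config$trial$alpha,
                       detection_limit = config$trial$e2_limit)
  })

  # 5. expression
  expression <- stage("expression", {
    tab <- read_trial_table(file.path(config$out_dir, "trial_table.tsv"))
    em <- generate_expression(expression_sim_spec(seed = config$seeds$expression),
                              tab)
    write_expression_matrix(em, file.path(config$out_dir, "expression.tsv"))
    run_expression_analysis(em, k = config$expression$k,
                            center_batches = config$expression$center_batches)
  })

  report <- list(
    stages = c("simulate", "score", "validate", "trial-stats", "expression"),
    agreement = list(spearman_rho = agreement$spearman$rho,
                     icc = agreement$icc$icc,
                     classifier_accuracy = agreement$classifier_accuracy),
    trial = list(
      wilcoxon_p = vapply(trial$paired_wilcoxon, `[[`, numeric(1), "p_value"),
      mwu_p = trial$menopause_comparison$p_value,
      kruskal_p = trial$postmenopausal_kruskal_wallis$p_value,
      e2_p = trial$e2$spearman$p_value),
    expression = list(mki67_p = expression$mki67_p,
                      menopause_t_p = expression$arm_comparison$menopause_t$p_value)
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- sort(list.files(config$out_dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    config = unclass(config),
    stages = report$stages,
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files))),
    package_version = tryCatch(
      as.character(utils::packageVersion("ki67window")),
      error = function(e) "dev")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(manifest, list(report = report)))
}
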