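#' Gene-set registry helpers
#'
#' A gene set is a list with a `name`, a character vector `genes`, and
#' optional per-gene direction `weights` (+1 / -1, defaulting to +1). The
#' bundled synthetic registry mimics the structure of the proliferation
#' signatures used for expression-based readouts (MKI67 alone plus five
#' multi-gene sets, one of them carrying mixed direction weights); the member
#' lists are synthetic placeholders over the simulated gene universe, and
#' real published lists can be supplied as plain-text files instead.
#'
#' @param name set name.
#' @param genes character vector of member genes (non-empty).
#' @param weights optional numeric vector of +1/-1, same length as `genes`.
#' @return object of class `gene_set`.
#' @export
gene_set <- function(name, genes, weights = NULL) {
  stopifnot(length(genes) >= 1L)
  if (is.null(weights)) weights <- rep(1, length(genes))
  stopifnot(length(weights) == length(genes), all(weights %in% c(-1, 1)))
  structure(list(name = name, genes = genes, weights = weights),
            class = "gene_set")
}

#' @param gene_names gene universe to draw placeholder members from; must
#'   contain "MKI67".
#' @rdname gene_set
#' @export
default_gene_sets <- function(gene_names) {
  stopifnot("MKI67" %in% gene_names)
  pool <- setdiff(gene_names, "MKI67")
  sizes <- c(AURKA = 10L, CIN70 = 70L, GGI = 40L, GENE70 = 70L, E2F3 = 20L)
  stopifnot(length(pool) >= sum(sizes))
  sets <- list(MKI67 = gene_set("MKI67", "MKI67"))
  at <- 0L
  for (nm in names(sizes)) {
    g <- pool[(at + 1L):(at + sizes[[nm]])]
    at <- at + sizes[[nm]]
    w <- rep(1, length(g))
    if (nm == "GENE70") w[seq_len(20L)] <- -1 # mixed-direction placeholder
    sets[[nm]] <- gene_set(nm, g, w)
  }
  sets
}

#' Read / write gene sets as two-column text files
#'
#' Format: one member per line, `gene<TAB>weight` with an optional weight
#' column (+1/-1, default +1); the set name is the file name without
#' extension.
#'
#' @param path file path (read) or output path (write).
#' @export
read_gene_set <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  w <- if (ncol(raw) >= 2L) as.numeric(raw[[2]]) else rep(1, nrow(raw))
  gene_set(tools::file_path_sans_ext(basename(path)), raw[[1]], w)
}

#' @param set a [gene_set()].
#' @rdname read_gene_set
#' @export
write_gene_set <- function(set, path) {
  utils::write.table(data.frame(set$genes, set$weights), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Specification for a synthetic expression matrix
#'
#' Emulates the array data feeding the expression-side proliferation
#' readouts: probe x sample log-intensities in which the signature-set genes
#' load on a latent proliferation factor per sample; the factor drops after
#' treatment in proportion to the patient's log Ki67 ratio. Genes are
#' represented by 1-3 probes, values carry injected missing entries and an
#' additive batch offset.
#'
#' @param n_genes gene-universe size including MKI67 (default 1000).
#' @param gene_sets optional named list of [gene_set()]s; defaults to
#'   [default_gene_sets()] over the simulated universe.
#' @param latent_scale latent-factor change per unit log10 Ki67 ratio.
#' @param latent_sd between-patient sd of the baseline latent factor.
#' @param loading_range range of per-gene loadings on the latent factor.
#' @param baseline_mean,baseline_sd per-gene baseline log-intensity.
#' @param noise_sd residual probe noise sd.
#' @param probe_sd systematic probe offset sd within a gene.
#' @param probe_probs probabilities of a gene having 1, 2 or 3 probes.
#' @param missing_rate missing-at-random rate in \[0, 1).
#' @param n_batches number of batches (samples split evenly).
#' @param batch_sd sd of additive per-probe batch offsets.
#' @param seed integer seed.
#' @return object of class `expression_sim_spec`.
#' @export
expression_sim_spec <- function(n_genes = 1000L, gene_sets = NULL,
                                latent_scale = 2, latent_sd = 0.5,
                                loading_range = c(0.5, 1),
                                baseline_mean = 7, baseline_sd = 1,
                                noise_sd = 0.3, probe_sd = 0.3,
                                probe_probs = c(0.6, 0.3, 0.1),
                                missing_rate = 0.02,
                                n_batches = 2L, batch_sd = 0.2, seed = 1L) {
  stopifnot(n_genes >= 250L, length(probe_probs) == 3L,
            abs(sum(probe_probs) - 1) < 1e-8, n_batches >= 1L)
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes), gene_sets = gene_sets,
    latent_scale = latent_scale, latent_sd = latent_sd,
    loading_range = loading_range,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    noise_sd = noise_sd, probe_sd = probe_sd, probe_probs = probe_probs,
    missing_rate = missing_rate, n_batches = as.integer(n_batches),
    batch_sd = batch_sd, seed = as.integer(seed)
  ), class = "expression_sim_spec")
}

#' Generate a synthetic probe x sample expression matrix
#'
#' Produces one before and one after sample per patient of the trial table.
#' The per-sample latent proliferation factor is the patient's baseline
#' factor, shifted after treatment by `latent_scale * log10((post+1)/(pre+1))`
#' of the patient's Ki67 pair, so expression-based proliferation readouts
#' track the simulated IHC response.
#'
#' @param spec an [expression_sim_spec()].
#' @param trial a non-empty `trial_table` from [generate_trial_table()].
#' @return object of class `expression_matrix`: list(values (probe x sample
#'   matrix with NAs), probe_gene (probe_id, gene), samples (sample_id,
#'   patient_id, time, arm, menopause, batch), gene_sets).
#' @export
generate_expression <- function(spec, trial) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  if (nrow(trial) == 0L) stop("trial table is empty", call. = FALSE)
  with_seed(spec$seed, {
    genes <- c("MKI67", sprintf("G%04d", seq_len(spec$n_genes - 1L)))
    sets <- spec$gene_sets %||% default_gene_sets(genes)
    unknown <- setdiff(unique(unlist(lapply(sets, `[[`, "genes"))), genes)
    if (length(unknown) > 0L) {
      stop("gene sets reference unknown genes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }

    n_pat <- nrow(trial)
    samples <- data.frame(
      sample_id = paste0(trial$patient_id, rep(c("_before", "_after"), each = n_pat)),
      patient_id = rep(trial$patient_id, 2L),
      time = rep(c("before", "after"), each = n_pat),
      arm = rep(trial$arm, 2L), menopause = rep(trial$menopause, 2L),
      stringsAsFactors = FALSE
    )
    samples$batch <- rep_len(paste0("batch", seq_len(spec$n_batches)),
                             nrow(samples))

    log_ratio <- log10((trial$ki67_post + 1) / (trial$ki67_pre + 1))
    base_factor <- stats::rnorm(n_pat, 0, spec$latent_sd)
    latent <- c(base_factor, base_factor + spec$latent_scale * log_ratio)

    in_set <- genes %in% unlist(lapply(sets, `[[`, "genes"))
    loading <- ifelse(in_set,
                      stats::runif(length(genes), spec$loading_range[1],
                                   spec$loading_range[2]), 0)
    loading[genes == "MKI67"] <- 1
    direction <- rep(1, length(genes))
    for (s in sets) direction[match(s$genes, genes)] <- s$weights
    baseline <- stats::rnorm(length(genes), spec$baseline_mean, spec$baseline_sd)

    gene_vals <- baseline +
      (direction * loading) %o% latent # genes x samples
    n_probes <- sample(1:3, length(genes), replace = TRUE, prob = spec$probe_probs)
    probe_gene <- data.frame(
      probe_id = paste0("p_", rep(genes, n_probes), "_",
                        unlist(lapply(n_probes, seq_len))),
      gene = rep(genes, n_probes), stringsAsFactors = FALSE
    )
    offs <- stats::rnorm(nrow(probe_gene), 0, spec$probe_sd)
    vals <- gene_vals[rep(seq_along(genes), n_probes), , drop = FALSE] + offs
    vals <- vals + stats::rnorm(length(vals), 0, spec$noise_sd)

    if (spec$batch_sd > 0 && spec$n_batches > 1L) {
      for (b in unique(samples$batch)[-1]) {
        shift <- stats::rnorm(nrow(vals), 0, spec$batch_sd)
        vals[, samples$batch == b] <- vals[, samples$batch == b] + shift
      }
    }
    if (spec$missing_rate > 0) {
      mask <- matrix(stats::runif(length(vals)) < spec$missing_rate,
                     nrow(vals), ncol(vals))
      # keep at least one observed value per probe
      all_gone <- rowSums(!mask) == 0L
      mask[all_gone, 1L] <- FALSE
      vals[mask] <- NA_real_
    }
    dimnames(vals) <- list(probe_gene$probe_id, samples$sample_id)
    structure(list(values = vals, probe_gene = probe_gene, samples = samples,
                   gene_sets = sets),
              class = "expression_matrix")
  })
}

#' Write / read an expression matrix as TSV plus sidecar metadata
#'
#' The matrix is written probes x samples with a leading probe_id and gene
#' column; metadata goes to `<path>.meta.tsv` (sample_id, patient_id, time,
#' arm, menopause, batch).
#'
#' @param em an `expression_matrix`.
#' @param path TSV path for the matrix.
#' @export
write_expression_matrix <- function(em, path) {
  tab <- data.frame(probe_id = em$probe_gene$probe_id,
                    gene = em$probe_gene$gene, em$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(em$samples, paste0(path, ".meta.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  samples <- utils::read.delim(paste0(path, ".meta.tsv"),
                               stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(vals) <- tab$probe_id
  structure(list(values = vals,
                 probe_gene = tab[, 1:2],
                 samples = samples, gene_sets = NULL),
            class = "expression_matrix")
}
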