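#' Configuration for the synthetic block-correlated expression generator
#'
#' Describes a two-group study in which genes fall into blocks with a
#' specified within-block correlation per group (a block may be correlated
#' in only one group, emulating co-expression lost or gained in disease),
#' plus unstructured noise genes.  Defaults mirror a small case-control
#' microarray study: 8 normal and 9 disease samples.
#'
#' @param blocks List of blocks, each a list/vector with elements
#'   `n_genes` (>= 2), `rho_normal` and `rho_disease` (each in \[0, 1)).
#' @param n_noise_genes Number of unstructured genes (default 0).
#' @param n_normal_samples,n_disease_samples Samples per group
#'   (defaults 8 and 9).
#' @param seed Mandatory integer seed; all randomness in
#'   [generate_dataset()] flows from it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(blocks, n_noise_genes = 0L,
                             n_normal_samples = 8L, n_disease_samples = 9L,
                             seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("an explicit integer seed is required")
  if (!length(blocks) && n_noise_genes < 2L)
    stop("at least 2 genes in total are required")
  blocks <- lapply(seq_along(blocks), function(i) {
    b <- as.list(blocks[[i]])
    if (is.null(b$block_id)) b$block_id <- paste0("B", i)
    if (is.null(b$n_genes) || b$n_genes < 2L)
      stop("each block needs n_genes >= 2")
    for (f in c("rho_normal", "rho_disease")) {
      if (is.null(b[[f]])) stop("each block needs ", f)
      if (b[[f]] < 0 || b[[f]] >= 1)
        stop(f, " must lie in [0, 1); got ", b[[f]])
    }
    b
  })
  if (n_normal_samples < 3L || n_disease_samples < 3L)
    stop("at least 3 samples per group are required downstream")
  structure(list(blocks = blocks,
                 n_noise_genes = as.integer(n_noise_genes),
                 n_normal_samples = as.integer(n_normal_samples),
                 n_disease_samples = as.integer(n_disease_samples),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a two-group expression matrix with planted correlation blocks
#'
#' Within each group independently, every gene of block `b` is drawn as
#' `x = sqrt(rho) * z + sqrt(1 - rho) * e`, where `z` is a per-sample
#' latent block factor and `e` is independent standard Gaussian noise, so
#' two genes of the same block have population correlation exactly `rho`
#' (the group's configured value).  Noise genes are pure `e`.  Cross-block
#' and noise-gene population correlations are 0.  Output is deterministic
#' given the config's seed.
#'
#' @param cfg A [synthetic_config()] object.
#' @return List with `expression` (a `coex_expr`) and `truth` (class
#'   `synthetic_truth`): a data frame with one row per gene (`gene_id`,
#'   `block_id` -- `NA` for noise genes -- `rho_normal`, `rho_disease`).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n_s <- c(normal = cfg$n_normal_samples, disease = cfg$n_disease_samples)
  gene_ids <- unlist(lapply(cfg$blocks, function(b)
    sprintf("%s_g%02d", b$block_id, seq_len(b$n_genes))))
  noise_ids <- if (cfg$n_noise_genes > 0L)
    sprintf("noise_g%03d", seq_len(cfg$n_noise_genes)) else character()
  all_ids <- c(gene_ids, noise_ids)
  sample_ids <- c(sprintf("N%02d", seq_len(n_s[["normal"]])),
                  sprintf("D%02d", seq_len(n_s[["disease"]])))
  groups <- stats::setNames(
    rep(c("normal", "disease"), n_s), sample_ids)
  vals <- matrix(NA_real_, length(all_ids), length(sample_ids),
                 dimnames = list(all_ids, sample_ids))
  for (grp in c("normal", "disease")) {
    ns <- n_s[[grp]]
    cols <- names(groups)[groups == grp]
    rho_field <- paste0("rho_", grp)
    for (b in cfg$blocks) {
      z <- stats::rnorm(ns)
      rho <- b[[rho_field]]
      rows <- sprintf("%s_g%02d", b$block_id, seq_len(b$n_genes))
      e <- matrix(stats::rnorm(b$n_genes * ns), b$n_genes, ns)
      vals[rows, cols] <- sqrt(rho) * rep(z, each = b$n_genes) +
        sqrt(1 - rho) * e
    }
    if (length(noise_ids))
      vals[noise_ids, cols] <- matrix(stats::rnorm(length(noise_ids) * ns),
                                      length(noise_ids), ns)
  }
  truth <- data.frame(
    gene_id = all_ids,
    block_id = c(unlist(lapply(cfg$blocks, function(b)
      rep(b$block_id, b$n_genes))), rep(NA_character_, length(noise_ids))),
    rho_normal = c(unlist(lapply(cfg$blocks, function(b)
      rep(b$rho_normal, b$n_genes))), rep(0, length(noise_ids))),
    rho_disease = c(unlist(lapply(cfg$blocks, function(b)
      rep(b$rho_disease, b$n_genes))), rep(0, length(noise_ids))),
    stringsAsFactors = FALSE)
  class(truth) <- c("synthetic_truth", "data.frame")
  list(expression = expression_matrix(vals, groups), truth = truth)
}

#' Expected galaxy category of every planted within-block gene pair
#'
#' Applies the strong/weak truth table to the configured population
#' correlations: a block pair is expected strong in a group when that
#' group's `rho >= threshold`.  Mirrors [classify_pairs()] on the truth
#' instead of the sample correlations.
#'
#' @param truth `synthetic_truth` data frame from [generate_dataset()].
#' @param threshold Co-expression threshold in \[0, 1\].
#' @return Data frame with columns `gene_i`, `gene_j`, `block_id`,
#'   `category` (one row per unordered within-block pair, canonical
#'   order).
#' @export
planted_pair_categories <- function(truth, threshold) {
  blocks <- unique(truth$block_id[!is.na(truth$block_id)])
  rows <- lapply(blocks, function(bid) {
    sub <- truth[!is.na(truth$block_id) & truth$block_id == bid, ]
    if (nrow(sub) < 2L) return(NULL)
    g <- sort(sub$gene_id)
    cmb <- utils::combn(g, 2L)
    sn <- sub$rho_normal[1L] >= threshold
    sd_ <- sub$rho_disease[1L] >= threshold
    cat_ <- if (sn && sd_) "common_strong" else if (sn) "normal_specific_strong"
            else if (sd_) "disease_specific_strong" else "common_weak"
    data.frame(gene_i = cmb[1L, ], gene_j = cmb[2L, ], block_id = bid,
               category = cat_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_i = character(), gene_j = character(),
                      block_id = character(), category = character(),
                      stringsAsFactors = FALSE)
  out$category <- factor(out$category, levels = galaxy_categories)
  out
}

#' Synthetic gene sets over the planted blocks
#'
#' Builds one term per block (members = the block's genes) so that the
#' enrichment and pair-mapping stages can be exercised against a counting
#' oracle, plus one catch-all term over all genes.
#'
#' @param truth `synthetic_truth` data frame from [generate_dataset()].
#' @return Named list of member vectors, with a `descriptions` attribute
#'   (same shape as [read_gene_sets()] output).
#' @export
synthetic_gene_sets <- function(truth) {
  blocks <- unique(truth$block_id[!is.na(truth$block_id)])
  sets <- lapply(blocks, function(bid)
    sort(truth$gene_id[!is.na(truth$block_id) & truth$block_id == bid]))
  names(sets) <- paste0("TERM_", blocks)
  sets$TERM_ALL <- sort(truth$gene_id)
  attr(sets, "descriptions") <- stats::setNames(
    c(paste("genes of block", blocks), "all genes"), names(sets))
  sets
}

#' Write synthetic gene sets as a GMT file
#'
#' @param sets Named list from [synthetic_gene_sets()].
#' @param path Output GMT path.
#' @return `sets`, invisibly.
#' @export
write_gene_sets_gmt <- function(sets, path) {
  descr <- attr(sets, "descriptions")
  if (is.null(descr)) descr <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(t)
    paste(c(t, descr[[t]], sets[[t]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(sets)
}
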