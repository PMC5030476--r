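#' Run the full differential co-expression pipeline
#'
#' Orchestrates the analysis end to end: read (or accept) the expression
#' matrix; optionally collapse probes to genes; optionally restrict the
#' gene universe to miRNA-target consensus candidates; compute the
#' per-group absolute Pearson co-expression of all gene pairs; detect the
#' disease-specific cutoff point at the maximum deviation between the two
#' exceedance distributions and test it against the Smirnov critical
#' deviation; classify pairs into the four galaxy regions; and, when gene
#' sets are supplied, run EASE/FDR enrichment on the analyzed genes and
#' the one-sided Fisher mapping test with Bonferroni correction on each
#' significant term.  All artifacts are written under `out_dir`.
#'
#' @param config A named list (or path to a YAML file with the same
#'   fields):
#'   \describe{
#'     \item{expression}{Path to an expression TSV, or a `coex_expr`.}
#'     \item{groups}{Named vector or path to the group sidecar (required
#'       when `expression` is a path).}
#'     \item{probe_map}{Optional path / named vector for probe collapsing.}
#'     \item{predictions}{Optional path / data frame of miRNA target
#'       predictions; when present the analysis is restricted to the
#'       consensus candidate targets.}
#'     \item{mirnas}{Optional miRNA ids to vote on (default: all in the
#'       prediction table).}
#'     \item{min_databases}{Consensus vote threshold (default 4).}
#'     \item{gene_sets}{Optional path (GMT / two-column) or named list.}
#'     \item{background}{`"annotated"` (default: measured genes in at
#'       least one set), `"all_measured"`, or a character vector.}
#'     \item{alpha}{KS significance level (default 0.05).}
#'     \item{ease_max, fdr_max}{Enrichment thresholds (default 0.05).}
#'     \item{mapping_alpha}{Mapping-test error rate (default 0.05).}
#'     \item{out_dir}{Output directory (created if needed).}
#'     \item{plots}{Write PNG figures (default `TRUE`).}
#'   }
#' @return Invisibly, a list with elements `expression`, `analyzed_genes`,
#'   `coexpression`, `cutoff`, `classification`, `summary`, and (when gene
#'   sets are supplied) `enrichment`, `significant_terms`, `mapping`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- config
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  say("coexgalaxy %s | run started %s",
      as.character(utils::packageVersion("coexgalaxy")),
      format(Sys.time(), "%Y-%m-%d %H:%M:%S"))

  # --- data_io ---------------------------------------------------------
  m <- cfg$expression
  if (is.character(m)) m <- read_expression(m, cfg$groups)
  stopifnot(inherits(m, "coex_expr"))
  say("expression: %d rows x %d samples (%d normal, %d disease)",
      nrow(m$values), ncol(m$values),
      sum(m$groups == "normal"), sum(m$groups == "disease"))
  if (!is.null(cfg$probe_map)) {
    pm <- cfg$probe_map
    if (is.character(pm) && length(pm) == 1L && file.exists(pm))
      pm <- read_probe_map(pm)
    m <- collapse_probes(m, pm)
    say("probe collapsing: %d gene rows", nrow(m$values))
  }
  measured_genes <- rownames(m$values)

  # --- target_consensus (optional) ------------------------------------
  if (!is.null(cfg$predictions)) {
    preds <- cfg$predictions
    if (is.character(preds)) preds <- read_predictions(preds)
    mirnas <- cfg$mirnas
    if (is.null(mirnas)) mirnas <- sort(unique(preds$mirna_id))
    min_db <- if (is.null(cfg$min_databases)) 4L else cfg$min_databases
    sets <- lapply(mirnas, function(mi)
      consensus_per_mirna(preds, mi, min_db))
    names(sets) <- mirnas
    cand <- cluster_candidates(sets)
    say("consensus candidates: %d genes over %d miRNAs (>= %d databases)",
        nrow(cand), length(mirnas), min_db)
    genes <- restrict_to_measured(cand, m)
    say("candidates measured on the array: %d", length(genes))
    m <- expression_matrix(m$values[genes, , drop = FALSE], m$groups)
  }

  # --- coexpression ----------------------------------------------------
  m <- drop_degenerate_genes(m)
  tab <- pairwise_coexpression(m)
  say("co-expression: %d genes -> %d pairs per group",
      nrow(m$values), nrow(tab))
  write_coexpression(tab, file.path(cfg$out_dir, "coexpression.tsv"))

  # --- cutoff_detection ------------------------------------------------
  alpha <- if (is.null(cfg$alpha)) 0.05 else cfg$alpha
  cut <- detect_cutoff(tab, alpha)
  say("cutoff: D = %.6g at C = %.6g (grid of %d thresholds); D_critical = %.6g; %s",
      cut$D, cut$C, cut$grid_size, cut$D_critical,
      if (cut$significant) "distributions differ (D > D_critical)"
      else "no significant difference")
  say("note: gene pairs share genes and are not independent; the critical")
  say("deviation treats them as independent, exactly as in the source method")
  jsonlite::write_json(
    list(D = cut$D, C = cut$C, D_critical = cut$D_critical,
         alpha = cut$alpha, n_normal_pairs = cut$n_normal_pairs,
         n_disease_pairs = cut$n_disease_pairs,
         significant = cut$significant, grid_size = cut$grid_size),
    file.path(cfg$out_dir, "cutoff.json"), auto_unbox = TRUE, digits = NA)

  # --- pair_classification --------------------------------------------
  cls <- classify_pairs(tab, cut$C)
  smry <- galaxy_summary(cls)
  say("galaxy: %s",
      paste(sprintf("%s = %d (%.3f%%)", names(smry$counts), smry$counts,
                    smry$percentages), collapse = "; "))
  write_classification(cls, file.path(cfg$out_dir, "classification.tsv"))
  jsonlite::write_json(
    list(n_pairs = smry$n_pairs, counts = as.list(smry$counts),
         percentages = as.list(smry$percentages),
         group_counts = as.list(smry$group_counts)),
    file.path(cfg$out_dir, "galaxy_summary.json"),
    auto_unbox = TRUE, digits = NA)
  do_plots <- is.null(cfg$plots) || isTRUE(cfg$plots)
  if (do_plots) {
    plot_exceedance(tab, cut, file.path(cfg$out_dir, "exceedance.png"))
    plot_galaxy(cls, cut$C, file.path(cfg$out_dir, "galaxy.png"))
  }

  result <- list(expression = m, analyzed_genes = sort(rownames(m$values)),
                 coexpression = tab, cutoff = cut, classification = cls,
                 summary = smry)

  # --- enrichment + pair_mapping (optional) ---------------------------
  if (is.null(cfg$gene_sets)) {
    say("no gene sets supplied; stopping after classification")
    writeLines(log_lines, log_path)
    return(invisible(result))
  }
  gs <- cfg$gene_sets
  if (is.character(gs) && length(gs) == 1L) gs <- read_gene_sets(gs)
  bg <- cfg$background
  if (is.null(bg) || identical(bg, "annotated")) {
    bg <- annotated_background(measured_genes, gs)
  } else if (identical(bg, "all_measured")) {
    bg <- measured_genes
  }
  say("enrichment background: %d genes", length(unique(bg)))
  ease_max <- if (is.null(cfg$ease_max)) 0.05 else cfg$ease_max
  fdr_max <- if (is.null(cfg$fdr_max)) 0.05 else cfg$fdr_max
  enr <- enrich_terms(rownames(m$values), gs, bg)
  utils::write.table(enr, file.path(cfg$out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- significant_terms(enr, ease_max, fdr_max)
  say("enrichment: %d terms scored, %d significant (EASE < %g, FDR < %g)",
      nrow(enr), nrow(sig), ease_max, fdr_max)
  result$enrichment <- enr
  result$significant_terms <- sig
  if (nrow(sig)) {
    map_alpha <- if (is.null(cfg$mapping_alpha)) 0.05 else cfg$mapping_alpha
    mapping <- map_gene_sets(gs[sig$term_id], cls, map_alpha)
    utils::write.table(mapping, file.path(cfg$out_dir, "mapping.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("mapping: %d terms tested, %d significantly mapped (Bonferroni < %g)",
        attr(mapping, "n_tested"), sum(mapping$significant), map_alpha)
    result$mapping <- mapping
  } else {
    say("mapping stage skipped: no significant terms")
    warning("mapping stage skipped: no significant terms")
  }
  writeLines(log_lines, log_path)
  invisible(result)
}
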