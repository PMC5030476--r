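#' Read miRNA target-prediction tables
#'
#' Predictions are consumed as frozen local files, never fetched live:
#' database contents drift over time, so reproducible runs require a
#' snapshot.  The expected layout is a TSV with a header and columns
#' `mirna_id`, `database_name`, `gene_id`.
#'
#' @param path Path to the prediction TSV.
#' @return A data frame with columns `mirna_id`, `database_name`,
#'   `gene_id`, deduplicated (one row per miRNA/database/gene triple).
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  need <- c("mirna_id", "database_name", "gene_id")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("prediction table lacks column(s): ", paste(missing, collapse = ", "))
  unique(df[, need])
}

#' Consensus target genes of one miRNA by database vote
#'
#' A gene is a consensus target when it is predicted by at least
#' `min_databases` of the databases that cover the miRNA (each database
#' votes at most once per gene, regardless of transcript multiplicity).
#'
#' @param preds Prediction table as returned by [read_predictions()].
#' @param mirna miRNA identifier to vote on.
#' @param min_databases Minimum number of supporting databases (default 4,
#'   i.e. "at least four out of five" when five databases are supplied).
#' @return Sorted character vector of consensus gene ids.
#' @export
consensus_per_mirna <- function(preds, mirna, min_databases = 4L) {
  sub <- unique(preds[preds$mirna_id == mirna, c("database_name", "gene_id")])
  dbs <- unique(sub$database_name)
  if (length(dbs) < min_databases)
    stop(sprintf("miRNA '%s' is covered by %d database(s); %d required",
                 mirna, length(dbs), min_databases))
  votes <- table(sub$gene_id)
  sort(names(votes)[votes >= min_databases])
}

#' Combine per-miRNA consensus sets into cluster-level candidates
#'
#' Takes the union over all cluster members, retaining which miRNAs voted
#' for each gene.
#'
#' @param consensus_sets Named list, miRNA id -> character vector of
#'   consensus gene ids (as from [consensus_per_mirna()]).
#' @return Data frame with columns `gene_id`, `n_mirnas`, `mirnas`
#'   (comma-separated supporting miRNAs), sorted by gene id.
#' @export
cluster_candidates <- function(consensus_sets) {
  if (!length(consensus_sets) || all(lengths(consensus_sets) == 0L))
    stop("all consensus sets are empty; nothing to combine")
  genes <- sort(unique(unlist(consensus_sets, use.names = FALSE)))
  support <- lapply(genes, function(g)
    names(consensus_sets)[vapply(consensus_sets, function(s) g %in% s, NA)])
  data.frame(
    gene_id  = genes,
    n_mirnas = lengths(support),
    mirnas   = vapply(support, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
}

#' Restrict candidate genes to those measured on the array
#'
#' @param candidates Character vector of gene ids, or the data frame
#'   returned by [cluster_candidates()].
#' @param m A `coex_expr` object.
#' @return Sorted character vector of candidate genes present in `m`.
#' @export
restrict_to_measured <- function(candidates, m) {
  stopifnot(inherits(m, "coex_expr"))
  if (is.data.frame(candidates)) candidates <- candidates$gene_id
  found <- sort(intersect(candidates, rownames(m$values)))
  if (!length(found))
    stop("no candidate gene is present in the expression matrix")
  message(sprintf("%d of %d candidate genes measured on the array",
                  length(found), length(unique(candidates))))
  found
}
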