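#' All annotated gene pairs of a term among the analyzed genes
#'
#' The member genes of a term are intersected with the analyzed gene
#' universe and paired in all possible combinations; pairs are returned in
#' canonical lexicographic order (`gene_i < gene_j`).
#'
#' @param members Character vector: the term's member gene ids.
#' @param analyzed_genes Character vector: genes present in the pair
#'   classification.
#' @return Data frame with columns `gene_i`, `gene_j` (zero rows, with a
#'   warning, when fewer than 2 members overlap).
#' @export
annotated_pairs <- function(members, analyzed_genes) {
  g <- sort(intersect(unique(members), analyzed_genes))
  if (length(g) < 2L) {
    warning("fewer than 2 annotated genes among the analyzed genes; no pairs")
    return(data.frame(gene_i = character(), gene_j = character(),
                      stringsAsFactors = FALSE))
  }
  cmb <- utils::combn(g, 2L)
  data.frame(gene_i = cmb[1L, ], gene_j = cmb[2L, ], stringsAsFactors = FALSE)
}

#' 2x2 contingency table of annotated pairs over the specific categories
#'
#' Maps annotated gene pairs onto the pair classification and counts, in
#' the orientation rows = (normal-specific view, disease-specific view),
#' columns = (strong, weak):
#' `a` = mapped normal-specific strongly co-expressed pairs,
#' `b` = mapped normal-specific weakly co-expressed pairs,
#' `c` = mapped disease-specific strongly co-expressed pairs,
#' `d` = mapped disease-specific weakly co-expressed pairs.
#' Because a normal-specific strong pair IS a disease-specific weak pair
#' (and vice versa), `a = d` and `b = c` by construction; pairs strong or
#' weak in both groups contribute to no cell.
#'
#' @param pairs Data frame of annotated pairs (`gene_i`, `gene_j`).
#' @param p Classified pair table from [classify_pairs()]; every annotated
#'   pair must be present.
#' @return Named integer vector `c(a=, b=, c=, d=)`.
#' @export
contingency <- function(pairs, p) {
  idx <- match(pair_key(pairs$gene_i, pairs$gene_j),
               pair_key(p$gene_i, p$gene_j))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("annotated pair (%s, %s) absent from the classification",
                 pairs$gene_i[bad], pairs$gene_j[bad]))
  }
  cats <- p$category[idx]
  nss <- sum(cats == "normal_specific_strong")
  dss <- sum(cats == "disease_specific_strong")
  c(a = nss, b = dss, c = dss, d = nss)
}

#' One-sided Fisher exact test for a 2x2 table
#'
#' Upper-tail exact hypergeometric probability for the table
#' `[[a, b], [c, d]]` with all margins fixed: the probability of observing
#' a count in the top-left cell at least as large as `a` (alternative:
#' more normal-specific strongly than disease-specific strongly
#' co-expressed pairs).
#'
#' @param a,b,c,d Non-negative cell counts, not all zero.
#' @return One-sided p-value in (0, 1\].
#' @export
fisher_one_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  if (any(a + b + c + d == 0)) stop("all-zero contingency table")
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' @param p p-value(s) in (0, 1\].
#' @param m Number of tested terms (>= 1).
#' @return `min(1, m * p)`, vectorized over `p`.
#' @export
bonferroni <- function(p, m) {
  if (m < 1L) stop("m must be at least 1")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  pmin(1, m * p)
}

#' Significance decision for a mapping test
#'
#' @param p_bonferroni Bonferroni-corrected p-value(s).
#' @param alpha Error rate (default 0.05).
#' @return `TRUE` iff `p_bonferroni < alpha` (strictly), vectorized.
#' @export
mapping_significance <- function(p_bonferroni, alpha = 0.05) {
  p_bonferroni < alpha
}

#' Map gene sets onto the pair classification and test each term
#'
#' For every term: forms all annotated gene pairs among the analyzed
#' genes, builds the specific-category 2x2 table, runs the one-sided
#' Fisher exact test, and Bonferroni-corrects over the number of tested
#' terms.  Terms with fewer than 2 overlapping genes, or whose annotated
#' pairs all fall in the common categories (an all-zero table), are
#' reported with `NA` p-values and do not count toward the Bonferroni
#' multiplier.
#'
#' @param gene_sets Named list of member vectors (typically the
#'   significant terms' sets).
#' @param p Classified pair table from [classify_pairs()].
#' @param alpha Error rate for the corrected decision (default 0.05).
#' @return Data frame with one row per term: `term_id`, `n_genes`,
#'   `n_pairs`, `a`, `b`, `c`, `d`, `p_one_sided`, `p_bonferroni`,
#'   `significant`, sorted by `p_one_sided`.
#' @export
map_gene_sets <- function(gene_sets, p, alpha = 0.05) {
  if (!length(gene_sets)) stop("no gene sets supplied")
  analyzed <- unique(c(p$gene_i, p$gene_j))
  rows <- lapply(names(gene_sets), function(term) {
    g <- sort(intersect(unique(gene_sets[[term]]), analyzed))
    if (length(g) < 2L)
      return(data.frame(term_id = term, n_genes = length(g), n_pairs = 0L,
                        a = NA_integer_, b = NA_integer_, c = NA_integer_,
                        d = NA_integer_, p_one_sided = NA_real_,
                        stringsAsFactors = FALSE))
    ap <- annotated_pairs(g, analyzed)
    ct <- contingency(ap, p)
    pv <- if (sum(ct) == 0) NA_real_ else
      fisher_one_sided(ct[["a"]], ct[["b"]], ct[["c"]], ct[["d"]])
    data.frame(term_id = term, n_genes = length(g), n_pairs = nrow(ap),
               a = ct[["a"]], b = ct[["b"]], c = ct[["c"]], d = ct[["d"]],
               p_one_sided = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- sum(!is.na(out$p_one_sided))
  if (m == 0L) {
    warning("no term produced a testable contingency table")
    out$p_bonferroni <- NA_real_
  } else {
    out$p_bonferroni <- ifelse(is.na(out$p_one_sided), NA_real_,
                               bonferroni(ifelse(is.na(out$p_one_sided), 1,
                                                 out$p_one_sided), m))
  }
  out$significant <- !is.na(out$p_bonferroni) &
    mapping_significance(out$p_bonferroni, alpha)
  out <- out[order(out$p_one_sided, out$term_id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- m
  out
}
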