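#' Absolute Pearson co-expression of two expression profiles
#'
#' The co-expression level of two genes within one group is the absolute
#' value of the Pearson product-moment correlation of their profiles,
#' `|cor(x, y)|`, a scalar in \[0, 1\]: a high value indicates a strong
#' linear relationship in either the positive or the negative direction.
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @return `|r|` in \[0, 1\].
#' @export
abs_pearson <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (length(x) < 3L) stop("at least 3 samples are required per group")
  if (anyNA(x) || anyNA(y)) stop("missing values in expression profiles")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in a profile")
  abs(stats::cor(x, y))
}

#' Remove genes whose co-expression is undefined
#'
#' Drops genes with missing values or zero variance within either group,
#' logging each removal with its reason.  Correlations are computed within
#' group only, so a gene constant in just one group is still unusable.
#'
#' @param m A `coex_expr` object.
#' @return A `coex_expr` with the offending genes removed.
#' @export
drop_degenerate_genes <- function(m) {
  stopifnot(inherits(m, "coex_expr"))
  bad_na <- rownames(m$values)[apply(m$values, 1L, anyNA)]
  vn <- group_values(m, "normal")
  vd <- group_values(m, "disease")
  rv <- function(v) apply(v, 1L, function(x) if (anyNA(x)) NA_real_ else stats::var(x))
  bad_const <- rownames(m$values)[!rownames(m$values) %in% bad_na &
                                    (rv(vn) == 0 | rv(vd) == 0)]
  if (length(bad_na))
    message(sprintf("dropping %d gene(s) with missing values: %s",
                    length(bad_na), paste(bad_na, collapse = ", ")))
  if (length(bad_const))
    message(sprintf("dropping %d gene(s) with zero within-group variance: %s",
                    length(bad_const), paste(bad_const, collapse = ", ")))
  keep <- setdiff(rownames(m$values), c(bad_na, bad_const))
  if (length(keep) < 2L)
    stop("fewer than 2 genes remain after dropping degenerate genes")
  expression_matrix(m$values[keep, , drop = FALSE], m$groups)
}

#' Per-group absolute Pearson co-expression for all gene pairs
#'
#' Computes, for every unordered gene pair, the co-expression level in the
#' normal group (from normal-group columns only) and in the disease group
#' (from disease-group columns only).  For `g` genes the result has
#' `g(g-1)/2` rows.  Pairs are stored in canonical lexicographic order
#' (`gene_i < gene_j`) so that joins and set operations are deterministic.
#'
#' @param m A `coex_expr` object that has passed [drop_degenerate_genes()];
#'   both groups must have at least 3 samples.
#' @return Data frame with columns `gene_i`, `gene_j`, `c_normal`,
#'   `c_disease` (each correlation in \[0, 1\]).
#' @seealso [write_coexpression()]
#' @export
pairwise_coexpression <- function(m) {
  stopifnot(inherits(m, "coex_expr"))
  if (any(table(m$groups) < 3L))
    stop("at least 3 samples per group are required to compute correlations")
  if (nrow(m$values) < 2L) stop("at least 2 genes are required")
  g <- sort(rownames(m$values))
  vn <- t(m$values[g, m$groups == "normal", drop = FALSE])
  vd <- t(m$values[g, m$groups == "disease", drop = FALSE])
  if (any(apply(vn, 2L, stats::sd) == 0) || any(apply(vd, 2L, stats::sd) == 0))
    stop("correlation undefined: zero variance in a profile; ",
         "run drop_degenerate_genes() first")
  cn <- abs(stats::cor(vn))
  cd <- abs(stats::cor(vd))
  ut <- upper.tri(cn)
  idx <- which(ut, arr.ind = TRUE)
  data.frame(
    gene_i    = g[idx[, 1L]],
    gene_j    = g[idx[, 2L]],
    c_normal  = pmin(cn[ut], 1),
    c_disease = pmin(cd[ut], 1),
    stringsAsFactors = FALSE)
}

#' Write a co-expression table to TSV at full precision
#'
#' @param tab Data frame from [pairwise_coexpression()].
#' @param path Output path.
#' @return `tab`, invisibly.
#' @export
write_coexpression <- function(tab, path) {
  out <- tab
  out$c_normal <- format(out$c_normal, digits = 17, trim = TRUE)
  out$c_disease <- format(out$c_disease, digits = 17, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

# internal canonical pair key used for joins between pair tables
pair_key <- function(gene_i, gene_j) paste(gene_i, gene_j, sep = "\r")
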