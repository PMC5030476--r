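#' Four-way co-expression categories
#'
#' Internal constant: category levels of the co-expression galaxy.
#' @keywords internal
galaxy_categories <- c("normal_specific_strong", "disease_specific_strong",
                       "common_strong", "common_weak")

#' Classify gene pairs as strong/weak per group at a cutoff
#'
#' A pair is strongly co-expressed in a group when its co-expression level
#' is greater than or equal to the cutoff `C` (the boundary is strong),
#' and weakly co-expressed otherwise.  The four galaxy categories follow
#' from the two indicators:
#' strong in normal only -> `normal_specific_strong` (identically, a
#' disease-specific weakly co-expressed pair); strong in disease only ->
#' `disease_specific_strong` (identically, normal-specific weak); strong in
#' both -> `common_strong`; weak in both -> `common_weak`.
#'
#' @param tab Co-expression table from [pairwise_coexpression()].
#' @param C Cutoff in \[0, 1\].
#' @return `tab` with added columns `strong_normal`, `strong_disease`
#'   (logical) and `category` (factor over the four regions).
#' @export
classify_pairs <- function(tab, C) {
  if (C < 0 || C > 1) stop("cutoff must lie in [0, 1]")
  sn <- tab$c_normal >= C
  sd_ <- tab$c_disease >= C
  cat_ <- ifelse(sn & sd_, "common_strong",
          ifelse(sn & !sd_, "normal_specific_strong",
          ifelse(!sn & sd_, "disease_specific_strong", "common_weak")))
  tab$strong_normal <- sn
  tab$strong_disease <- sd_
  tab$category <- factor(cat_, levels = galaxy_categories)
  attr(tab, "cutoff") <- C
  tab
}

#' Summarize the co-expression galaxy
#'
#' Counts and percentages of the four regions, plus the per-group
#' strong/weak marginals (strong in normal = normal-specific strong +
#' common strong, and likewise for disease).
#'
#' @param p Classified pair table from [classify_pairs()].
#' @return Object of class `galaxy_summary`: list with `n_pairs`, `counts`
#'   (named integer vector over the four categories), `percentages`
#'   (100 * count / total), and `group_counts` (strong/weak per group).
#' @export
galaxy_summary <- function(p) {
  if (!nrow(p)) stop("empty pair classification")
  counts <- table(p$category)
  counts <- stats::setNames(as.integer(counts), names(counts))
  n <- sum(counts)
  group_counts <- c(
    strong_normal  = counts[["normal_specific_strong"]] + counts[["common_strong"]],
    weak_normal    = counts[["disease_specific_strong"]] + counts[["common_weak"]],
    strong_disease = counts[["disease_specific_strong"]] + counts[["common_strong"]],
    weak_disease   = counts[["normal_specific_strong"]] + counts[["common_weak"]])
  structure(list(
    n_pairs = n,
    counts = counts,
    percentages = 100 * counts / n,
    group_counts = group_counts), class = "galaxy_summary")
}

#' @export
print.galaxy_summary <- function(x, ...) {
  cat(sprintf("Co-expression galaxy over %d gene pairs\n", x$n_pairs))
  for (k in names(x$counts))
    cat(sprintf("  %-24s %8d  (%6.3f%%)\n", k, x$counts[[k]], x$percentages[[k]]))
  cat(sprintf("  strong/weak in normal : %d / %d\n",
              x$group_counts[["strong_normal"]], x$group_counts[["weak_normal"]]))
  cat(sprintf("  strong/weak in disease: %d / %d\n",
              x$group_counts[["strong_disease"]], x$group_counts[["weak_disease"]]))
  invisible(x)
}

#' Write a classified pair table to TSV
#'
#' @param p Classified pair table from [classify_pairs()].
#' @param path Output path.
#' @return `p`, invisibly.
#' @export
write_classification <- function(p, path) {
  out <- p[, c("gene_i", "gene_j", "c_normal", "c_disease", "category")]
  out$c_normal <- format(out$c_normal, digits = 17, trim = TRUE)
  out$c_disease <- format(out$c_disease, digits = 17, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(p)
}
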