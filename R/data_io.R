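#' Expression matrix with a two-level sample grouping
#'
#' Light container for a genes-by-samples matrix of normalized intensities
#' together with a `normal` / `disease` label per sample.  Row names are
#' gene (or probe) identifiers, column names are sample identifiers;
#' identifiers are opaque, case-sensitive strings and are matched exactly
#' everywhere in the package.
#'
#' @param values Numeric matrix, one row per gene, one column per sample.
#'   Row and column names are mandatory and must be unique.
#' @param groups Group label per sample: a named character vector or factor
#'   (names = sample ids) with values `"normal"` or `"disease"`.  Every
#'   column of `values` must be named, and both groups must be non-empty.
#' @return An object of class `coex_expr`: a list with elements `values`
#'   (the numeric matrix) and `groups` (a factor with levels
#'   `normal`, `disease`, aligned with the matrix columns).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' grp <- setNames(c("normal", "normal", "disease", "disease"), colnames(m))
#' expression_matrix(m, grp)
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row (gene) and column (sample) names")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicated gene/probe identifier(s): ", paste(dup, collapse = ", "))
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup))
    stop("duplicated sample identifier(s): ", paste(dup, collapse = ", "))
  if (is.factor(groups)) groups <- stats::setNames(as.character(groups), names(groups))
  if (is.null(names(groups)))
    stop("`groups` must be named by sample identifier")
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("sample(s) missing from the group specification: ",
         paste(missing, collapse = ", "))
  groups <- groups[colnames(values)]
  bad <- unique(groups[!groups %in% c("normal", "disease")])
  if (length(bad))
    stop("group labels must be 'normal' or 'disease'; found: ",
         paste(bad, collapse = ", "))
  groups <- factor(groups, levels = c("normal", "disease"))
  if (any(table(groups) == 0L))
    stop("both groups must be non-empty")
  structure(list(values = values, groups = groups), class = "coex_expr")
}

#' @export
print.coex_expr <- function(x, ...) {
  cat(sprintf("<coex_expr> %d genes x %d samples (%d normal, %d disease)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "normal"), sum(x$groups == "disease")))
  invisible(x)
}

#' @export
dim.coex_expr <- function(x) dim(x$values)

# columns of one group, as a genes x samples matrix
group_values <- function(m, group) {
  m$values[, m$groups == group, drop = FALSE]
}

#' Read an expression matrix from a tab-separated file
#'
#' The expected layout is one header row of sample identifiers, a first
#' column of gene (or probe) identifiers and a numeric body -- the usual
#' flattened series-matrix layout.  The literal strings `NA` and the empty
#' string are read as missing values; any other non-numeric cell is an
#' error reported with its (row, column) coordinates.
#'
#' @param path Path to a TSV file.
#' @param groups Either a named character vector / factor mapping sample id
#'   to `"normal"`/`"disease"`, or the path to a two-column sidecar file
#'   (sample id TAB group, no header) as read by [read_groups()].
#' @return A [expression_matrix()] object.
#' @seealso [write_expression()], [collapse_probes()]
#' @export
read_expression <- function(path, groups) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(groups) && length(groups) == 1L && is.null(names(groups))) {
    groups <- read_groups(groups)
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  samples <- header[-1L]
  dup <- unique(samples[duplicated(samples)])
  if (length(dup))
    stop("duplicated sample column(s) in ", path, ": ", paste(dup, collapse = ", "))
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated row identifier(s) in ", path, ": ", paste(dup, collapse = ", "))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !(body %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                 body[bad[1L, 1L], bad[1L, 2L]],
                 ids[bad[1L, 1L]], samples[bad[1L, 2L]]))
  dimnames(num) <- list(ids, samples)
  m <- expression_matrix(num, groups)
  message(sprintf("read %d rows x %d samples from %s",
                  nrow(num), ncol(num), path))
  m
}

#' Read a sample-to-group sidecar file
#'
#' @param path Two-column TSV (sample id TAB group), no header.
#' @return Named character vector mapping sample id to group label.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) != 2L)
    stop("group file must have exactly two columns (sample id, group)")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write an expression matrix (and optionally its groups) to TSV
#'
#' @param m A `coex_expr` object.
#' @param path Output TSV path (first column `id`, header of sample ids).
#' @param group_path Optional path for the two-column group sidecar.
#' @return `m`, invisibly.
#' @export
write_expression <- function(m, path, group_path = NULL) {
  df <- data.frame(id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(group_path)) {
    utils::write.table(
      data.frame(sample = colnames(m$values),
                 group = as.character(m$groups)),
      group_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  invisible(m)
}

#' Read a probe-to-gene map
#'
#' @param path Two-column TSV (probe id TAB gene id), no header.  Each
#'   probe must map to exactly one gene; several probes may map to the
#'   same gene.
#' @return Named character vector, names = probe ids, values = gene ids.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) != 2L)
    stop("probe map must have exactly two columns (probe id, gene id)")
  dup <- unique(df[[1L]][duplicated(df[[1L]])])
  if (length(dup))
    stop("probe(s) mapped more than once: ", paste(dup, collapse = ", "))
  stats::setNames(df[[2L]], df[[1L]])
}

#' Collapse probe-level rows to gene-level rows by averaging
#'
#' When a gene is interrogated by more than one probe, its expression row
#' becomes the arithmetic mean of all its probe rows, per sample, on the
#' already-normalized scale.  No re-normalization is performed.
#'
#' @param m A `coex_expr` object keyed by probe identifiers.
#' @param probe_map Named character vector (probe id -> gene id) as
#'   returned by [read_probe_map()].  Every row of `m` must be present.
#' @return A `coex_expr` object keyed by gene identifiers, rows sorted
#'   lexicographically.
#' @export
collapse_probes <- function(m, probe_map) {
  stopifnot(inherits(m, "coex_expr"))
  unmapped <- setdiff(rownames(m$values), names(probe_map))
  if (length(unmapped))
    stop("probe(s) absent from the probe map: ", paste(unmapped, collapse = ", "))
  genes <- probe_map[rownames(m$values)]
  sums <- rowsum(m$values, group = genes, reorder = TRUE)
  counts <- as.vector(table(genes)[rownames(sums)])
  vals <- sums / counts
  message(sprintf("collapsed %d probes to %d genes", nrow(m$values), nrow(vals)))
  expression_matrix(vals, m$groups)
}

#' Read gene sets from a GMT or two-column file
#'
#' GMT lines are `term TAB description TAB member TAB member ...` (the
#' MSigDB dialect); two-column lines are `term TAB gene`.  Duplicate
#' members are removed; terms left with no members are dropped with a
#' warning.
#'
#' @param path Path to the gene-set file.
#' @param format `"auto"` (default; GMT when any line has three or more
#'   fields), `"gmt"`, or `"two_column"`.
#' @return Named list of character vectors (term id -> member gene ids),
#'   with a `descriptions` attribute carrying the GMT description column
#'   (for two-column input, the term id itself).
#' @export
read_gene_sets <- function(path, format = c("auto", "gmt", "two_column")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no gene-set records in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "auto")
    format <- if (any(lengths(fields) >= 3L)) "gmt" else "two_column"
  if (format == "gmt") {
    short <- which(lengths(fields) < 2L)
    if (length(short))
      stop("malformed GMT line ", short[1L], ": fewer than two fields")
    terms <- vapply(fields, `[[`, "", 1L)
    descr <- vapply(fields, `[[`, "", 2L)
    members <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  } else {
    bad <- which(lengths(fields) != 2L)
    if (length(bad))
      stop("malformed two-column line ", bad[1L], ": expected 'term TAB gene'")
    term_col <- vapply(fields, `[[`, "", 1L)
    gene_col <- vapply(fields, `[[`, "", 2L)
    terms <- unique(term_col)
    descr <- terms
    members <- lapply(terms, function(t) unique(gene_col[term_col == t]))
  }
  dup <- unique(terms[duplicated(terms)])
  if (length(dup))
    stop("duplicated term(s): ", paste(dup, collapse = ", "))
  names(members) <- terms
  names(descr) <- terms
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning("dropping term(s) with no members: ",
            paste(terms[empty], collapse = ", "))
    members <- members[!empty]
    descr <- descr[!empty]
  }
  attr(members, "descriptions") <- descr
  members
}
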