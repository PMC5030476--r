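# Fixture builders shared across the test files.  Everything is generated
# in code; no fixture files are shipped.

# small expression object with named genes/samples and a fixed group split
make_expr <- function(values, n_normal) {
  samples <- colnames(values)
  grp <- stats::setNames(
    rep(c("normal", "disease"),
        c(n_normal, length(samples) - n_normal)), samples)
  expression_matrix(values, grp)
}

# random expression matrix: g genes, nn + nd samples, standard Gaussian
random_expr <- function(g, nn, nd, seed) {
  set.seed(seed)
  v <- matrix(rnorm(g * (nn + nd)), g,
              dimnames = list(sprintf("g%03d", seq_len(g)),
                              sprintf("s%02d", seq_len(nn + nd))))
  make_expr(v, nn)
}

# write a TSV expression fixture; returns the path
write_expr_tsv <- function(values, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(id = rownames(values), values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# textbook two-pass Pearson correlation, independent of stats::cor
two_pass_pearson <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# brute-force one-sided Fisher p by enumerating all tables with the
# observed margins and summing log-choose hypergeometric probabilities
brute_fisher_upper <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  x <- max(0, r1 + c1 - N):min(r1, c1)
  p <- exp(lchoose(r1, x) + lchoose(N - r1, c1 - x) - lchoose(N, c1))
  sum(p[x >= a]) / sum(p)
}

# a tiny co-expression table with hand-set values
toy_pairs <- function(cn, cd) {
  g <- sprintf("g%02d", seq_len(length(cn) + 1))
  data.frame(gene_i = g[1], gene_j = g[-1],
             c_normal = cn, c_disease = cd, stringsAsFactors = FALSE)
}
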