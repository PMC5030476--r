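test_that("annotated pairs enumerate all combinations of overlapping genes", {
  genes37 <- sprintf("g%02d", 1:37)
  ap <- annotated_pairs(genes37, genes37)
  expect_identical(nrow(ap), 666L)             # 37 * 36 / 2
  expect_true(all(ap$gene_i < ap$gene_j))
  expect_false(any(duplicated(paste(ap$gene_i, ap$gene_j))))

  expect_identical(nrow(annotated_pairs(c("a", "b"), c("a", "b", "c"))), 1L)
  expect_identical(nrow(annotated_pairs(sprintf("g%02d", 1:32),
                                        sprintf("g%02d", 1:40))), 496L)
  expect_warning(out <- annotated_pairs("a", c("a", "b")), "fewer than 2")
  expect_identical(nrow(out), 0L)
})

test_that("contingency cells count specific categories with a = d, b = c", {
  # 6 pairs: 2 normal-specific strong, 1 disease-specific strong, 3 common
  tab <- data.frame(
    gene_i = c("a", "a", "a", "b", "b", "c"),
    gene_j = c("b", "c", "d", "c", "d", "d"),
    c_normal  = c(0.9, 0.8, 0.2, 0.9, 0.1, 0.7),
    c_disease = c(0.1, 0.2, 0.9, 0.8, 0.2, 0.9), stringsAsFactors = FALSE)
  cls <- classify_pairs(tab, 0.5)
  ct <- contingency(tab[, c("gene_i", "gene_j")], cls)
  expect_identical(ct, c(a = 2L, b = 1L, c = 1L, d = 2L))
  expect_identical(ct[["a"]], ct[["d"]])
  expect_identical(ct[["b"]], ct[["c"]])
  # specific + common partitions the annotated pairs
  expect_identical(ct[["a"]] + ct[["b"]] +
                     sum(cls$category %in% c("common_strong", "common_weak")),
                   nrow(tab))

  # all-common input gives the empty table
  all_common <- classify_pairs(
    data.frame(gene_i = c("a", "a"), gene_j = c("b", "c"),
               c_normal = c(0.9, 0.1), c_disease = c(0.9, 0.1)), 0.5)
  expect_identical(contingency(all_common[, 1:2], all_common),
                   c(a = 0L, b = 0L, c = 0L, d = 0L))

  # unknown pair is rejected
  expect_error(
    contingency(data.frame(gene_i = "a", gene_j = "zz"), cls), "absent")
})

test_that("contingency identities hold on random classifications", {
  set.seed(17)
  for (rep in 1:20) {
    g <- sprintf("g%02d", 1:sample(5:15, 1))
    cmb <- t(utils::combn(g, 2))
    tab <- data.frame(gene_i = cmb[, 1], gene_j = cmb[, 2],
                      c_normal = runif(nrow(cmb)), c_disease = runif(nrow(cmb)),
                      stringsAsFactors = FALSE)
    cls <- classify_pairs(tab, runif(1))
    sub <- sort(sample(g, sample(2:length(g), 1)))
    ap <- annotated_pairs(sub, g)
    ct <- contingency(ap, cls)
    expect_identical(ct[["a"]], ct[["d"]])
    expect_identical(ct[["b"]], ct[["c"]])
    mapped_common <- sum(cls$category[match(paste(ap$gene_i, ap$gene_j),
                                            paste(cls$gene_i, cls$gene_j))] %in%
                           c("common_strong", "common_weak"))
    expect_identical(ct[["a"]] + ct[["b"]] + mapped_common, nrow(ap))
  }
})

test_that("one-sided Fisher matches brute-force enumeration and fisher.test", {
  cases <- list(c(186, 148, 148, 186), c(137, 111, 111, 137),
                c(5, 5, 5, 5), c(12, 3, 7, 9), c(0, 4, 4, 0), c(3, 0, 0, 3))
  for (t in cases) {
    p <- fisher_one_sided(t[1], t[2], t[3], t[4])
    expect_equal(p, brute_fisher_upper(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(matrix(t, 2, byrow = TRUE),
                                       alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
  expect_gt(fisher_one_sided(5, 5, 5, 5), 0.5)  # symmetric: tail holds the mode
  expect_error(fisher_one_sided(0, 0, 0, 0), "all-zero")
  expect_error(fisher_one_sided(-1, 2, 3, 4), "non-negative")
})

test_that("upper and lower Fisher tails partition the symmetric tables", {
  # for tables with a = d, b = c: swapping rows maps p to the opposite tail,
  # and p_upper + p_lower - P(observed) = 1
  for (t in list(c(186, 148, 148, 186), c(9, 4, 4, 9), c(2, 7, 7, 2))) {
    p_up <- fisher_one_sided(t[1], t[2], t[3], t[4])
    p_lo <- stats::phyper(t[1], t[1] + t[2], t[3] + t[4], t[1] + t[3])
    p_obs <- stats::dhyper(t[1], t[1] + t[2], t[3] + t[4], t[1] + t[3])
    expect_equal(p_up + p_lo - p_obs, 1, tolerance = 1e-12)
    expect_equal(fisher_one_sided(t[3], t[4], t[1], t[2]), p_lo,
                 tolerance = 1e-12)
  }
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.002, 11), 0.022)
  expect_equal(bonferroni(0.012, 11), 0.132)
  expect_equal(bonferroni(0.2, 11), 1)
  expect_error(bonferroni(0.1, 0), "at least 1")
  expect_true(mapping_significance(0.022))
  expect_false(mapping_significance(0.132))
  expect_false(mapping_significance(0.05))  # boundary: strictly smaller
})

test_that("mapping gene sets onto a classification reports per-term tests", {
  set.seed(33)
  g <- sprintf("g%02d", 1:12)
  cmb <- t(utils::combn(g, 2))
  tab <- data.frame(gene_i = cmb[, 1], gene_j = cmb[, 2],
                    c_normal = runif(nrow(cmb), 0.3, 1),
                    c_disease = runif(nrow(cmb), 0, 0.7),
                    stringsAsFactors = FALSE)
  cls <- classify_pairs(tab, 0.5)
  sets <- list(T1 = g[1:6], T2 = g[5:12], T_small = g[1])
  res <- suppressWarnings(map_gene_sets(sets, cls))
  expect_identical(nrow(res), 3L)
  expect_true(is.na(res$p_one_sided[res$term_id == "T_small"]))
  tested <- res[!is.na(res$p_one_sided), ]
  # Bonferroni multiplier is the number of tested terms only
  expect_equal(tested$p_bonferroni,
               pmin(1, attr(res, "n_tested") * tested$p_one_sided))
  expect_identical(attr(res, "n_tested"), 2L)
  for (r in seq_len(nrow(tested))) {
    ap <- annotated_pairs(sets[[tested$term_id[r]]], g)
    ct <- contingency(ap, cls)
    expect_identical(tested$a[r], ct[["a"]])
    expect_identical(tested$n_pairs[r], nrow(ap))
  }
})
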