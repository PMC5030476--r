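test_that("generation is deterministic and reproduces the configured shape", {
  cfg <- synthetic_config(
    blocks = list(list(n_genes = 5, rho_normal = 0.8, rho_disease = 0.1),
                  list(n_genes = 4, rho_normal = 0.2, rho_disease = 0.7)),
    n_noise_genes = 6, seed = 123)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$expression$values, ds2$expression$values)  # bit-identical
  expect_identical(dim(ds1$expression), c(15L, 17L))  # default 8 + 9 samples
  expect_identical(sum(ds1$expression$groups == "normal"), 8L)
  expect_identical(sum(ds1$expression$groups == "disease"), 9L)
  expect_identical(nrow(ds1$truth), 15L)
  expect_identical(sum(is.na(ds1$truth$block_id)), 6L)

  # different seed, different data
  cfg2 <- synthetic_config(cfg$blocks, 6, seed = 124)
  expect_false(identical(generate_dataset(cfg2)$expression$values,
                         ds1$expression$values))

  expect_error(synthetic_config(
    list(list(n_genes = 3, rho_normal = 1, rho_disease = 0)), seed = 1),
    "rho_normal")
  expect_error(synthetic_config(
    list(list(n_genes = 3, rho_normal = 0.5, rho_disease = 0.5))),
    "seed")
})

test_that("planted blocks reach their target correlation at large n", {
  cfg <- synthetic_config(
    blocks = list(list(n_genes = 12, rho_normal = 0.8, rho_disease = 0.8)),
    n_noise_genes = 0, n_normal_samples = 200, n_disease_samples = 200,
    seed = 31)
  ds <- generate_dataset(cfg)
  tab <- pairwise_coexpression(ds$expression)
  # sampling distribution of r at n = 200, rho = 0.8 (Fisher-z half-width)
  expect_gt(mean(tab$c_normal), 0.72)
  expect_lt(mean(tab$c_normal), 0.88)
  expect_gt(mean(tab$c_disease), 0.72)
  expect_lt(mean(tab$c_disease), 0.88)
})

test_that("cross-block and noise correlations are near zero at large n", {
  cfg <- synthetic_config(
    blocks = list(list(n_genes = 6, rho_normal = 0.9, rho_disease = 0.9),
                  list(n_genes = 6, rho_normal = 0.9, rho_disease = 0.9)),
    n_noise_genes = 8, n_normal_samples = 300, n_disease_samples = 300,
    seed = 77)
  ds <- generate_dataset(cfg)
  tab <- pairwise_coexpression(ds$expression)
  blk <- ds$truth$block_id[match(tab$gene_i, ds$truth$gene_id)]
  blk_j <- ds$truth$block_id[match(tab$gene_j, ds$truth$gene_id)]
  within <- !is.na(blk) & !is.na(blk_j) & blk == blk_j
  expect_lt(mean(tab$c_normal[!within]), 0.1)  # E|r| ~ 0.046 at n = 300
  expect_gt(mean(tab$c_normal[within]), 0.8)
})

test_that("planted pair categories follow the rho truth table", {
  cfg <- synthetic_config(
    blocks = list(list(n_genes = 3, rho_normal = 0.9, rho_disease = 0.0),
                  list(n_genes = 3, rho_normal = 0.8, rho_disease = 0.8),
                  list(n_genes = 3, rho_normal = 0.1, rho_disease = 0.9),
                  list(n_genes = 3, rho_normal = 0.1, rho_disease = 0.2)),
    n_noise_genes = 2, seed = 4)
  truth <- generate_dataset(cfg)$truth
  pc <- planted_pair_categories(truth, 0.45)
  expect_identical(nrow(pc), 12L)  # 4 blocks x 3 within-block pairs
  by_block <- vapply(split(as.character(pc$category), pc$block_id),
                     unique, "")
  expect_identical(by_block[["B1"]], "normal_specific_strong")
  expect_identical(by_block[["B2"]], "common_strong")
  expect_identical(by_block[["B3"]], "disease_specific_strong")
  expect_identical(by_block[["B4"]], "common_weak")
  expect_true(all(pc$gene_i < pc$gene_j))
})

test_that("synthetic gene sets cover the blocks and round-trip through GMT", {
  cfg <- synthetic_config(
    blocks = list(list(n_genes = 4, rho_normal = 0.9, rho_disease = 0.1),
                  list(n_genes = 3, rho_normal = 0.2, rho_disease = 0.8)),
    n_noise_genes = 3, seed = 2)
  truth <- generate_dataset(cfg)$truth
  sets <- synthetic_gene_sets(truth)
  expect_named(sets, c("TERM_B1", "TERM_B2", "TERM_ALL"))
  expect_length(sets$TERM_B1, 4L)
  expect_length(sets$TERM_ALL, 10L)
  gmt <- tempfile(fileext = ".gmt")
  write_gene_sets_gmt(sets, gmt)
  back <- read_gene_sets(gmt)
  expect_identical(back$TERM_B1, sets$TERM_B1)
  expect_identical(names(back), names(sets))
})
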