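test_that("expression TSV round-trips and invariants are enforced", {
  set.seed(11)
  v <- matrix(round(rnorm(12), 6), 3, 4,
              dimnames = list(c("gA", "gB", "gC"), paste0("s", 1:4)))
  path <- write_expr_tsv(v)
  grp <- stats::setNames(c("normal", "normal", "disease", "disease"),
                         colnames(v))
  m <- suppressMessages(read_expression(path, grp))
  expect_s3_class(m, "coex_expr")
  expect_identical(dim(m), c(3L, 4L))
  expect_equal(m$values, v)

  # write -> read is value-identical within formatting precision
  p2 <- tempfile(fileext = ".tsv")
  gp <- tempfile(fileext = ".tsv")
  write_expression(m, p2, gp)
  m2 <- suppressMessages(read_expression(p2, gp))
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  expect_identical(m2$groups, m$groups)

  # duplicated sample column is rejected, naming the column
  lines <- readLines(path)
  lines[1] <- "id\ts1\ts2\ts2\ts4"
  bad <- tempfile(fileext = ".tsv")
  writeLines(lines, bad)
  expect_error(read_expression(bad, grp), "s2")

  # non-numeric cell is rejected with row/column coordinates
  lines <- readLines(path)
  lines[3] <- sub("^gB\t[^\t]*", "gB\toops", lines[3])
  writeLines(lines, bad)
  expect_error(read_expression(bad, grp), "'oops'.*'gB'.*'s1'")

  # sample missing from the group spec is rejected
  expect_error(read_expression(path, grp[-2]), "s2")

  # both groups must be non-empty
  expect_error(
    expression_matrix(v, stats::setNames(rep("normal", 4), colnames(v))),
    "non-empty")
})

test_that("probe collapsing averages probe rows per gene", {
  v <- rbind(p1 = c(1, 3), p2 = c(3, 5), p3 = c(10, 20))
  colnames(v) <- c("s1", "s2")
  m <- make_expr(v, 1)  # 1 normal, 1 disease: io-level test only
  pm <- c(p1 = "G", p2 = "G", p3 = "H")
  out <- suppressMessages(collapse_probes(m, pm))
  expect_equal(out$values["G", ], c(s1 = 2, s2 = 4))
  expect_equal(out$values["H", ], c(s1 = 10, s2 = 20))  # single probe unchanged

  # unmapped probe is rejected and listed
  expect_error(collapse_probes(m, pm[-3]), "p3")
})

test_that("collapsing many probes matches a brute-force mean oracle", {
  set.seed(42)
  v <- matrix(rnorm(5 * 4), 5, 4,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:4)))
  m <- make_expr(v, 2)
  pm <- c(p1 = "gx", p2 = "gx", p3 = "gx", p4 = "gy", p5 = "gy")
  out <- suppressMessages(collapse_probes(m, pm))
  expect_identical(nrow(out$values), 2L)
  for (g in c("gx", "gy")) {
    probes <- names(pm)[pm == g]
    oracle <- colMeans(v[probes, , drop = FALSE])
    expect_equal(out$values[g, ], oracle)
  }
  # per-sample mass conservation: sum of gene means equals sum of per-gene means
  expect_equal(colSums(out$values),
               colMeans(v[1:3, ]) + colMeans(v[4:5, ]))

  # collapsing with the identity map is idempotent
  idmap <- stats::setNames(rownames(out$values), rownames(out$values))
  again <- suppressMessages(collapse_probes(out, idmap))
  expect_equal(again$values, out$values[order(rownames(out$values)), ])
})

test_that("gene sets parse from GMT and two-column formats", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("T1\tfirst term\ta\tb\tc\td\tb",   # one duplicate member
               "T2\tsecond term\tx\ty",
               "T3\tempty term"),
             gmt)
  expect_warning(sets <- read_gene_sets(gmt), "T3")
  expect_named(sets, c("T1", "T2"))
  expect_setequal(sets$T1, c("a", "b", "c", "d"))  # dedup: 5 entries -> 4
  expect_identical(attr(sets, "descriptions")[["T2"]], "second term")

  twocol <- tempfile(fileext = ".tsv")
  writeLines(c("T1\ta", "T1\tb", "T2\tz"), twocol)
  sets2 <- read_gene_sets(twocol)
  expect_length(sets2, 2L)
  expect_setequal(sets2$T1, c("a", "b"))

  writeLines(c("T1\ta", "justonefield"), twocol)
  expect_error(read_gene_sets(twocol, format = "two_column"), "line 2")
})
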