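test_that("TSV and GCT round-trips preserve values and identifiers", {
  e <- make_expr(5, 3, seed = 2)
  for (fmt in c("tsv", "gct")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_expression_matrix(e, path, format = fmt)
    back <- read_expression_matrix(path, format = fmt)
    expect_identical(gene_ids(back), gene_ids(e))
    expect_identical(sample_ids(back), sample_ids(e))
    expect_lt(max(abs(back$values - e$values)), 1e-12)
  }
})

test_that("GCT and TSV dialects yield the same matrix", {
  e <- make_expr(4, 2, seed = 3)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".gct")
  write_expression_matrix(e, p1, "tsv")
  write_expression_matrix(e, p2, "gct")
  expect_equal(read_expression_matrix(p1)$values,
               read_expression_matrix(p2)$values, tolerance = 1e-12)
})

test_that("malformed expression inputs raise typed errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), path)
  expect_error(read_expression_matrix(path), "gA")

  writeLines(c("gene_id\ts1\ts2", "gA\t1\toops"), path)
  expect_error(read_expression_matrix(path), "non-numeric")

  m <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s1")))
  expect_error(expression_matrix(m * 1.0), "duplicate sample")

  gct <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "5\t2", "NAME\tDescription\ts1\ts2", "gA\tna\t1\t2"), gct)
  expect_error(read_expression_matrix(gct), "dimension")
})

test_that("missing values are rejected by default and imputable by row mean", {
  m <- matrix(c(1, NA, 3, 5, 2, 4), 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_error(expression_matrix(m), "missing")
  imp <- expression_matrix(m, impute = "row-mean")
  expect_equal(imp$values["b", "s1"], 2)  # the row's only observed value
})

test_that("collapse_probes averages probes per gene on the log2 scale", {
  pv <- matrix(c(2, 4, 5.5), 3, 1,
               dimnames = list(c("p1", "p2", "p3"), "s1"))
  map <- c(p1 = "G", p2 = "G", p3 = "H")
  out <- collapse_probes(pv, map)
  expect_equal(out$values["G", "s1"], 3)    # mean of 2 and 4
  expect_equal(out$values["H", "s1"], 5.5)  # single probe passes through
})

test_that("collapse_probes matches an independent per-gene mean and is order-invariant", {
  set.seed(4)
  pv <- matrix(rnorm(10 * 3), 10, 3,
               dimnames = list(sprintf("p%02d", 1:10), paste0("s", 1:3)))
  map <- setNames(sprintf("G%d", c(1, 1, 1, 2, 2, 3, 3, 3, 3, 4)),
                  rownames(pv))
  out <- collapse_probes(pv, map)
  for (g in unique(map)) {
    expected <- colMeans(pv[names(map)[map == g], , drop = FALSE])
    expect_equal(out$values[g, ], expected, tolerance = 1e-12)
  }
  perm <- sample(nrow(pv))
  out2 <- collapse_probes(pv[perm, ], map)
  expect_equal(out$values, out2$values)
})

test_that("unmapped probes are dropped with a count and empty maps error", {
  pv <- matrix(1:4 * 1.0, 2, 2,
               dimnames = list(c("p1", "p2"), c("s1", "s2")))
  expect_message(collapse_probes(pv, c(p1 = "G", p2 = NA)), "1 probe")
  expect_error(collapse_probes(pv, c(p1 = NA_character_, p2 = NA)), "no probe")
})

test_that("GMT parsing follows the dialect and its error contract", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB\tC", "S2\tdesc\tD\tE"), path)
  sets <- read_gene_sets(path)
  expect_identical(sets[["S1"]], c("A", "B", "C"))
  expect_identical(sets[["S2"]], c("D", "E"))

  writeLines(c("S1\tdesc\tA", "S2\tonlytwo"), path)
  expect_error(read_gene_sets(path), "line 2")

  writeLines("S1\tdesc\tA\tA", path)
  expect_warning(sets <- read_gene_sets(path), "duplicate")
  expect_identical(sets[["S1"]], "A")

  # round trip
  writeLines(c("S1\tdesc\tA\tB\tC", "S2\tdesc\tD\tE"), path)
  sets <- read_gene_sets(path)
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gene_sets(sets, p2)
  expect_identical(unclass(read_gene_sets(p2))[1:2], unclass(sets)[1:2])
})

test_that("network reading merges duplicates, drops self-loops and thresholds", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t900", "B\tA\t900"), path)
  g <- read_network(path, score_threshold = 0.4)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 0.9)  # 0-1000 scale auto-detected

  writeLines(c("A\tA\t950", "A\tB\t800"), path)
  expect_warning(g <- read_network(path), "self-loop")
  expect_equal(igraph::ecount(g), 1)

  writeLines(c("A\tB\t900", "B\tC\t500", "C\tD\t100", "D\tE\t700",
               "E\tA\t300"), path)
  g <- read_network(path, score_threshold = 0.4)
  expect_equal(igraph::ecount(g), 3)  # two rows fall below 0.4

  writeLines(c("A\tB\t500", "B\tC\tnot_a_number"), path)
  expect_error(read_network(path), "non-numeric|scores outside")
})

test_that("network read/write is idempotent under re-serialization", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t900", "B\tC\t500", "C\tD\t450"), path)
  g1 <- read_network(path)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_network(g1, p2)
  g2 <- read_network(p2)
  el <- function(g) {
    e <- cbind(igraph::as_edgelist(g), igraph::E(g)$weight)
    e[order(e[, 1], e[, 2]), ]
  }
  expect_equal(el(g1), el(g2))
})

test_that("cell fraction tables are validated against their contract", {
  path <- withr::local_tempfile(fileext = ".tsv")
  frac <- matrix(1 / 22, 3, 22,
                 dimnames = list(paste0("s", 1:3), paste0("cell", 1:22)))
  write.table(data.frame(sample_id = rownames(frac), frac),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_cell_fractions(path)
  expect_equal(dim(m), c(3L, 22L))
  expect_true(all(abs(rowSums(m) - 1) < 1e-6))

  frac[1, 1] <- 0.9
  write.table(data.frame(sample_id = rownames(frac), frac),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cell_fractions(path), "sum to 1")
})

test_that("sample annotations attach in matrix column order", {
  ann <- data.frame(sample_id = c("s02", "s01"),
                    group = c("resistant", "sensitive"),
                    timepoint = c("pre", "pre"))
  e <- make_expr(3, 2, seed = 5, samples = ann)
  expect_identical(e$samples$sample_id, c("s01", "s02"))
  expect_identical(e$samples$group, c("sensitive", "resistant"))
})
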