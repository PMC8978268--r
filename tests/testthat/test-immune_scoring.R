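test_that("geometric-mean score is the log2 of the linear geometric mean", {
  m <- matrix(c(2, 4), 2, 1, dimnames = list(c("a", "b"), "s1"))
  e <- expression_matrix(m)
  expect_equal(unname(geometric_mean_score(e, c("a", "b"))), 3)
  expect_equal(unname(geometric_mean_score(e, "b")), 4)  # singleton identity

  e <- make_expr(30, 5, seed = 30)
  set <- sample(gene_ids(e), 10)
  ref <- apply(e$values[set, ], 2, function(x) log2(exp(mean(log(2^x)))))
  expect_equal(geometric_mean_score(e, set), ref, tolerance = 1e-10)
})

test_that("geometric-mean score is translation-equivariant on the log2 scale", {
  e <- make_expr(20, 4, seed = 31)
  set <- gene_ids(e)[1:5]
  base <- geometric_mean_score(e, set)
  shifted <- e
  shifted$values[set, ] <- shifted$values[set, ] + 1.7
  expect_equal(geometric_mean_score(shifted, set), base + 1.7,
               tolerance = 1e-12)
})

test_that("missing set genes are dropped and fully absent sets error", {
  e <- make_expr(10, 3, seed = 32)
  expect_message(s <- geometric_mean_score(e, c("g01", "g02", "nope")),
                 "1 gene")
  expect_equal(unname(s), unname(colMeans(e$values[c("g01", "g02"), ])))
  expect_error(geometric_mean_score(e, c("x", "y")), "no gene")
})

test_that("ssGSEA matches an independent brute-force running sum", {
  e <- make_expr(8, 5, seed = 33)
  set <- c("g02", "g05", "g07")
  fast <- ssgsea_score(e, set, alpha = 0.25)
  slow <- apply(e$values, 2, ssgsea_brute, set_genes = set, alpha = 0.25)
  expect_equal(fast, slow, tolerance = 1e-12)
  # and for a larger random instance with a different exponent
  e2 <- make_expr(40, 3, seed = 34)
  set2 <- sample(gene_ids(e2), 12)
  expect_equal(ssgsea_score(e2, set2, alpha = 0.5),
               apply(e2$values, 2, ssgsea_brute, set_genes = set2,
                     alpha = 0.5),
               tolerance = 1e-12)
})

test_that("ssGSEA is invariant under strictly monotone transforms", {
  e <- make_expr(25, 4, seed = 35)
  set <- gene_ids(e)[c(1, 5, 9, 13)]
  base <- ssgsea_score(e, set)
  tr <- e
  tr$values[, 1] <- 2 * tr$values[, 1] + 1
  tr$values[, 2] <- exp(tr$values[, 2])
  expect_lt(max(abs(ssgsea_score(tr, set) - base)), 1e-12)
})

test_that("the extremal arrangement maximizes the enrichment score", {
  n <- 12; m <- 3
  ids <- sprintf("g%02d", 1:n)
  top <- expression_matrix(matrix(n:1, n, 1, dimnames = list(ids, "s1")))
  es_top <- ssgsea_score(top, ids[1:m])
  set.seed(36)
  for (i in 1:20) {
    other <- sample(ids, m)
    if (identical(sort(other), sort(ids[1:m]))) next
    expect_gt(es_top, ssgsea_score(top, other))
  }
  expect_error(ssgsea_score(top, ids), "out-set")
})

test_that("score_signature_panel keeps set order and errors on absent sets", {
  e <- make_expr(60, 4, seed = 37)
  sets <- gene_set_collection(list(A = gene_ids(e)[1:7], B = gene_ids(e)[8:13],
                                   C = gene_ids(e)[14:18]))
  for (method in c("geometric_mean", "ssgsea")) {
    sc <- score_signature_panel(e, sets, method = method)
    expect_identical(colnames(sc), c("A", "B", "C"))
    expect_identical(rownames(sc), sample_ids(e))
    expect_false(anyNA(sc))
  }
  one <- expression_matrix(e$values[, 1, drop = FALSE])
  expect_equal(nrow(score_signature_panel(one, sets)), 1)
  bad <- gene_set_collection(list(A = gene_ids(e)[1:3], Z = c("no1", "no2")))
  expect_error(score_signature_panel(e, bad), "Z")
})

test_that("the 7-signature immune panel with documented sizes scores cleanly", {
  e <- make_expr(120, 6, seed = 38)
  sizes <- c(`MHC Class-I` = 7, `Adhesion Molecules` = 6, Chemokines = 5,
             `Cytolytic Marker` = 4, `IFNg Signature` = 6,
             `Immuno-costimulators` = 17, `Immuno-inhibitors` = 12)
  pool <- sample(gene_ids(e))
  sets <- list(); used <- 0
  for (nm in names(sizes)) {
    sets[[nm]] <- pool[used + seq_len(sizes[[nm]])]
    used <- used + sizes[[nm]]
  }
  sc <- score_signature_panel(e, gene_set_collection(sets))
  expect_equal(dim(sc), c(6L, 7L))
  expect_identical(colnames(sc), names(sizes))
  expect_equal(attr(sc, "genes_used"), sizes[colnames(sc)])
})

test_that("background z-normalization needs a stable null and recovers shifts", {
  e <- simulate_cohort(n_genes = 300, n_per_arm = c(10, 0, 10, 0),
                       n_de_genes = 0, seed = 39)$expr
  sim <- simulate_signatures(e, n_sets = 4, set_size = 15, shifted_sets = 1,
                             shift = 1.5, seed = 40)
  expect_error(score_signature_panel(sim$expr, sim$sets, method = "ssgsea_z",
                                     n_perm = 5), ">= 10")
  z <- score_signature_panel(sim$expr, sim$sets, method = "ssgsea_z",
                             n_perm = 20, seed = 41)
  expect_identical(attr(z, "method"), "ssgsea_z")
  grp <- sim$expr$samples$group
  cmp <- compare_groups(z, factor(grp, levels = c("resistant", "sensitive")))
  shifted <- cmp[cmp$feature == sim$shifted, ]
  expect_lt(shifted$p_value, 0.01)
  expect_identical(shifted$direction, "up")
})

test_that("per-sample and pooled background modes both run deterministically", {
  e <- make_expr(80, 6, seed = 42)
  sets <- gene_set_collection(list(A = gene_ids(e)[1:10],
                                   B = gene_ids(e)[21:35]))
  z1 <- background_normalize(e, sets, n_perm = 12, seed = 5)
  z2 <- background_normalize(e, sets, n_perm = 12, seed = 5)
  expect_identical(z1, z2)
  zp <- background_normalize(e, sets, n_perm = 12, seed = 5,
                             pooling = "per_sample")
  expect_equal(dim(zp), dim(z1))
  zg <- background_normalize(e, sets, n_perm = 12, seed = 5,
                             shuffle = "per_gene")
  expect_equal(dim(zg), dim(z1))
})

test_that("Wilcoxon comparison is exact on the textbook small sample", {
  scores <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(NULL, "f"))
  out <- compare_groups(scores, c("a", "a", "b", "b"))
  expect_equal(out$p_value, 1 / 3)  # 2/C(4,2), enumerable by hand
  expect_identical(out$direction, "down")

  const <- matrix(5, 4, 1, dimnames = list(NULL, "f"))
  outc <- compare_groups(const, c("a", "a", "b", "b"))
  expect_equal(outc$p_value, 1)
  expect_identical(outc$direction, "none")

  expect_error(compare_groups(scores, c("a", "a", "a", "a")), "two groups")
  expect_error(compare_groups(scores, c("a", "a", "a", "b")), ">= 2")
})

test_that("consensus matrices satisfy their structural invariants", {
  set.seed(43)
  x <- matrix(rnorm(20 * 3), 20)
  res <- consensus_cluster(x, k_range = 2:4, n_reps = 50, seed = 6)
  for (cons in res$consensus) {
    expect_true(isSymmetric(cons))
    expect_true(all(diag(cons) == 1))
    expect_true(all(cons >= 0 & cons <= 1))
  }
  expect_true(all(res$area >= 0 & res$area <= 1))
  expect_equal(unname(res$delta_area[1]), unname(res$area[1]))
  res2 <- consensus_cluster(x, k_range = 2:4, n_reps = 50, seed = 6)
  expect_identical(res, res2)
  expect_error(consensus_cluster(x, k_range = c(1, 3)), "k_range")
})

test_that("consensus clustering recovers separated blobs and flags noise", {
  set.seed(44)
  x <- rbind(matrix(rnorm(12 * 2, 0), ncol = 2),
             matrix(rnorm(12 * 2, 10), ncol = 2))
  res <- consensus_cluster(x, k_range = 2:5, n_reps = 100, seed = 7)
  expect_equal(res$chosen_k, 2)
  expect_false(res$low_confidence)
  truth <- rep(1:2, each = 12)
  agree <- max(mean(res$labels == truth), mean(res$labels == 3 - truth))
  expect_equal(agree, 1)

  noise <- matrix(rnorm(24 * 4), 24)
  rn <- consensus_cluster(noise, k_range = 2:5, n_reps = 100, seed = 8)
  expect_true(rn$low_confidence)
  expect_equal(rn$chosen_k, 2)  # smallest k fallback
})
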