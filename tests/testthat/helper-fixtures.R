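# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except through temporary files written by the tests.

make_expr <- function(n_genes = 8, n_samples = 6, seed = 1, samples = NULL) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, mean = 7, sd = 2), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(m, samples = samples)
}

# independent brute-force ssGSEA: literal running-sum loop, no shared code
# with the vectorized implementation under test
ssgsea_brute <- function(x, set_genes, alpha) {
  genes <- names(x)
  r <- rank(x, ties.method = "average")
  ord <- genes[order(r, decreasing = TRUE)]
  in_set <- ord %in% set_genes
  n <- length(x)
  w_sum <- sum(r[ord][in_set]^alpha)
  p_in <- 0; p_out <- 0; es <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) {
      p_in <- p_in + r[[ord[i]]]^alpha / w_sum
    } else {
      p_out <- p_out + 1 / (n - sum(in_set))
    }
    es <- es + (p_in - p_out)
  }
  es
}

# small random graph with named vertices
make_graph <- function(n = 20, p = 0.2, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# independent dense linear-solve reference for the random walk: with M the
# column-stochastic transition (mass from j split over its neighbors, i.e.
# t(W) for W the row-normalized adjacency), p = r * solve(I - (1-r) M) p0
rwr_dense_solve <- function(network, seeds, restart, weighted = TRUE) {
  A <- igraph::as_adjacency_matrix(
    network, attr = if (weighted && !is.null(igraph::E(network)$weight)) "weight",
    sparse = FALSE)
  deg <- colSums(A)
  M <- sweep(A, 2L, ifelse(deg == 0, 1, deg), "/")
  diag(M)[deg == 0] <- 1  # self-absorbing isolated nodes
  n <- nrow(A)
  p0 <- numeric(n); names(p0) <- rownames(A)
  p0[seeds] <- 1 / length(seeds)
  sol <- solve(diag(n) - (1 - restart) * M, restart * p0)
  names(sol) <- rownames(A)
  sol
}
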