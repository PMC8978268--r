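#' Random walk with restart on a gene network
#'
#' Network propagation from a set of seed genes. With `W` the
#' column-normalized (weighted) adjacency matrix and `p0` the uniform
#' distribution over seed genes present in the network, iterates
#'
#'   `p <- (1 - restart) * t(W) %*% p + restart * p0`
#'
#' until the L1 change drops below `tol` or `max_iter` is reached. The
#' stationary vector is the walker's visiting probability for every node;
#' it sums to 1 and is 0 on components unreachable from the seeds.
#' Zero-degree nodes are treated as absorbing into themselves so the
#' transition matrix stays column-stochastic.
#'
#' @param network An igraph graph with gene names; edge `weight`s are used
#'   when present unless `weighted = FALSE`.
#' @param seed_genes Character vector of seed gene ids. Seeds absent from
#'   the network are dropped with a warning; no seed present is an error.
#' @param restart Restart probability in (0, 1]; 0.7 is the conventional
#'   default for gene prioritization.
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap; non-convergence warns and returns the
#'   current vector with `converged = FALSE`.
#' @param weighted Use edge weights in the transition matrix.
#' @return A list of class `WalkResult`: `scores` (named numeric vector
#'   over all nodes), `seed_genes` (those actually used), `converged`,
#'   `iterations`.
#' @export
random_walk_with_restart <- function(network, seed_genes, restart = 0.7,
                                     tol = 1e-10, max_iter = 1000,
                                     weighted = TRUE) {
  if (restart <= 0 || restart > 1) abort("restart must be in (0, 1]")
  nodes <- igraph::V(network)$name
  seeds <- intersect(seed_genes, nodes)
  if (!length(seeds))
    abort("no seed gene present in the network; missing: ",
          paste(utils::head(setdiff(seed_genes, nodes), 10), collapse = ", "))
  if (length(seeds) < length(unique(seed_genes)))
    warning(length(unique(seed_genes)) - length(seeds),
            " seed gene(s) not in the network dropped", call. = FALSE)

  A <- igraph::as_adjacency_matrix(
    network, attr = if (weighted && !is.null(igraph::E(network)$weight)) "weight",
    sparse = TRUE)
  deg <- Matrix::colSums(A)
  isolated <- deg == 0
  inv_deg <- ifelse(isolated, 0, 1 / deg)
  # transition matrix, row i <- col j flow: P = A %*% diag(1/deg); t(W) p
  P <- A %*% Matrix::Diagonal(x = inv_deg)

  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  p0[seeds] <- 1 / length(seeds)
  p <- p0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p_new <- as.numeric((1 - restart) * (P %*% p) + restart * p0)
    # self-absorption keeps mass on isolated nodes (deg 0 columns are zero)
    if (any(isolated)) p_new[isolated] <- p_new[isolated] + (1 - restart) * p[isolated]
    names(p_new) <- nodes
    if (sum(abs(p_new - p)) < tol) {
      p <- p_new
      converged <- TRUE
      break
    }
    p <- p_new
  }
  if (!converged)
    warning("random walk did not converge in ", max_iter, " iterations",
            call. = FALSE)
  structure(list(scores = p, seed_genes = seeds, converged = converged,
                 iterations = iter),
            class = "WalkResult")
}

#' @export
print.WalkResult <- function(x, ...) {
  cat(sprintf("WalkResult: %d nodes, %d seeds, %s after %d iterations\n",
              length(x$scores), length(x$seed_genes),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Degree-preserving network rewiring
#'
#' Randomizes a network by repeated double-edge swaps that reject
#' self-loops and parallel edges, leaving every node's degree unchanged --
#' the conservative null model for network statistics that scale with
#' degree. The original edge-weight multiset is preserved by reassigning
#' it to the rewired edges in random order. A graph admitting no legal
#' swap (e.g. a triangle) is returned unchanged with a warning.
#'
#' @param network An igraph graph with >= 2 edges.
#' @param n_swaps Number of attempted swaps; default 10 edges' worth of
#'   mixing per edge (`10 * ecount`).
#' @param seed RNG seed.
#' @return A rewired igraph graph with the identical degree multiset.
#' @export
rewire_network <- function(network, n_swaps = 10 * igraph::ecount(network),
                           seed = NULL) {
  if (igraph::ecount(network) < 2) abort("need >= 2 edges to rewire")
  maybe_seed(seed)
  w <- igraph::E(network)$weight
  rewired <- igraph::rewire(
    network, igraph::keeping_degseq(loops = FALSE, niter = n_swaps))
  if (!is.null(w))  # rewire does not keep attributes; restore the multiset
    igraph::E(rewired)$weight <- sample(w)
  if (!identical(sort(igraph::degree(rewired)), sort(igraph::degree(network))))
    abort("internal error: rewiring changed the degree multiset")  # nocov
  same <- igraph::identical_graphs(rewired, network) ||
    isTRUE(all.equal(canonical_edges(rewired), canonical_edges(network)))
  if (same)
    warning("no legal degree-preserving swap changed the graph; returned unchanged",
            call. = FALSE)
  rewired
}

# internal: sorted canonical edge list for comparing graphs
canonical_edges <- function(g) {
  el <- igraph::as_edgelist(g)
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  el[order(el[, 1L], el[, 2L]), , drop = FALSE]
}

#' Walk-score significance against rewired-network nulls
#'
#' Runs the random walk on the observed network, then on `n_perm`
#' degree-preserving rewirings, and assigns every candidate gene an
#' add-one empirical p-value of its observed score against its own null
#' score distribution (per-gene null, direction greater). Walk scores
#' scale strongly with degree, so each gene is compared only against
#' itself across rewirings rather than against a pooled null.
#'
#' @param network An igraph graph.
#' @param seed_genes Seed set for the walk.
#' @param candidates Candidate gene ids to test (default: all non-seed
#'   nodes). Candidates absent from the network are dropped with a warning.
#' @param n_perm Number of rewired replicates (default 1000).
#' @param restart,weighted Passed to [random_walk_with_restart()].
#' @param null_model `"rewire"` (degree-preserving double-edge swaps) or
#'   `"label-shuffle"` (uniform relabeling of the nodes).
#' @param seed RNG seed.
#' @return A data frame with columns `gene`, `score`, `empirical_p`,
#'   ordered by increasing p then decreasing score; attributes
#'   `seed_set_name` (from `names(seed_genes)` if set via `seed_set_name`),
#'   `n_perm`.
#' @param seed_set_name Label stored on the result (used by
#'   [combine_walks()]).
#' @export
walk_significance <- function(network, seed_genes, candidates = NULL,
                              n_perm = 1000, restart = 0.7, weighted = TRUE,
                              null_model = c("rewire", "label-shuffle"),
                              seed = NULL, seed_set_name = "seed_set") {
  null_model <- match.arg(null_model)
  maybe_seed(seed)
  nodes <- igraph::V(network)$name
  if (is.null(candidates)) candidates <- setdiff(nodes, seed_genes)
  cand <- intersect(candidates, nodes)
  if (length(cand) < length(unique(candidates)))
    warning(length(unique(candidates)) - length(cand),
            " candidate(s) not in the network dropped", call. = FALSE)

  observed <- random_walk_with_restart(network, seed_genes,
                                       restart = restart, weighted = weighted)
  obs <- observed$scores[cand]

  exceed <- integer(length(cand))
  for (b in seq_len(n_perm)) {
    null_net <- switch(null_model,
      rewire = suppressWarnings(rewire_network(network)),
      `label-shuffle` = {
        g2 <- network
        igraph::V(g2)$name <- sample(nodes)
        g2
      })
    null_scores <- random_walk_with_restart(null_net, seed_genes,
                                            restart = restart,
                                            weighted = weighted)$scores
    exceed <- exceed + (null_scores[cand] >= obs)
  }
  p <- (1 + exceed) / (n_perm + 1)
  out <- data.frame(gene = cand, score = unname(obs),
                    empirical_p = unname(p), stringsAsFactors = FALSE)
  out <- out[order(out$empirical_p, -out$score), ]
  rownames(out) <- NULL
  attr(out, "seed_set_name") <- seed_set_name
  attr(out, "n_perm") <- n_perm
  out
}

#' Combine walk significance across seed sets
#'
#' A candidate resistance gene is retained when its walk score is
#' significant (`empirical_p < alpha`) with respect to at least `min_sets`
#' seed sets. Output is sorted by the number of supporting sets
#' (descending) and then the best p-value.
#'
#' @param results List of [walk_significance()] outputs, one per seed set.
#' @param alpha Per-set significance cutoff (default 0.01).
#' @param min_sets Minimum number of supporting seed sets (default 2).
#' @return A data frame with columns `gene`, `n_sets`, `best_p`.
#' @export
combine_walks <- function(results, alpha = 0.01, min_sets = 2) {
  if (length(results) < min_sets)
    abort("need at least min_sets = ", min_sets, " walk results")
  sig <- lapply(results, function(r) r[r$empirical_p < alpha, c("gene", "empirical_p")])
  all_sig <- do.call(rbind, sig)
  if (is.null(all_sig) || !nrow(all_sig))
    return(data.frame(gene = character(0), n_sets = integer(0),
                      best_p = numeric(0), stringsAsFactors = FALSE))
  n_sets <- table(all_sig$gene)
  best_p <- tapply(all_sig$empirical_p, all_sig$gene, min)
  keep <- names(n_sets)[n_sets >= min_sets]
  out <- data.frame(gene = keep, n_sets = as.integer(n_sets[keep]),
                    best_p = as.numeric(best_p[keep]), stringsAsFactors = FALSE)
  out <- out[order(-out$n_sets, out$best_p), ]
  rownames(out) <- NULL
  out
}
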