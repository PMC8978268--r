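#' Network connectivity permutation test
#'
#' Asks whether a gene set (e.g. the differentially expressed genes) is
#' more densely interconnected than a same-size random draw of network
#' genes. The null distribution is the induced edge count of `n_perm`
#' uniform node samples (without replacement, from all network nodes);
#' significance is the add-one upper-tail empirical p-value.
#'
#' @param network An igraph graph.
#' @param genes Gene set to test; ids absent from the network are dropped
#'   with a warning, and at least 2 must survive.
#' @param n_perm Number of null draws (default 1000).
#' @param seed RNG seed.
#' @return A list of class `NullDistribution`: `observed`, `null_values`,
#'   `p_value`, `direction = "greater"`, `n_perm`.
#' @export
connectivity_permutation_test <- function(network, genes, n_perm = 1000,
                                          seed = NULL) {
  maybe_seed(seed)
  nodes <- igraph::V(network)$name
  present <- intersect(genes, nodes)
  if (length(present) < length(unique(genes)))
    warning(length(unique(genes)) - length(present),
            " gene(s) not in the network dropped", call. = FALSE)
  if (length(present) < 2) abort("need >= 2 genes present in the network")
  if (length(present) == length(nodes))
    warning("gene set covers the whole network; the null is degenerate (p = 1)",
            call. = FALSE)

  observed <- induced_edge_count(network, present)
  null_values <- vapply(seq_len(n_perm), function(b) {
    igraph::ecount(igraph::induced_subgraph(network,
                                            sample(nodes, length(present))))
  }, numeric(1L))
  new_null_distribution(observed, null_values, direction = "greater")
}

#' Gene-set overlap enrichment by random comparison
#'
#' Permutation analogue of an over-representation test: the observed
#' statistic is the overlap between a query gene set and an annotation
#' gene set, and the null is the overlap of `n_perm` uniform same-size
#' query draws from the universe. Converges to the hypergeometric
#' upper-tail probability as `n_perm` grows, with p floored at
#' `1/(n_perm+1)`.
#'
#' @param query,annotation Character vectors, both subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @param n_perm Number of null draws (default 1000).
#' @param seed RNG seed.
#' @return A `NullDistribution` (direction greater).
#' @export
enrichment_permutation_test <- function(query, annotation, universe,
                                        n_perm = 1000, seed = NULL) {
  if (!length(annotation)) abort("empty annotation set")
  query <- unique(query); annotation <- unique(annotation)
  universe <- unique(universe)
  if (length(setdiff(query, universe)) || length(setdiff(annotation, universe)))
    abort("query and annotation must be subsets of the universe")
  maybe_seed(seed)
  observed <- length(intersect(query, annotation))
  in_ann <- universe %in% annotation
  null_values <- vapply(seq_len(n_perm), function(b) {
    sum(in_ann[sample.int(length(universe), length(query))])
  }, numeric(1L))
  new_null_distribution(observed, null_values, direction = "greater")
}

new_null_distribution <- function(observed, null_values,
                                  direction = c("greater", "less", "two.sided")) {
  direction <- match.arg(direction)
  structure(list(observed = observed, null_values = null_values,
                 p_value = empirical_p(observed, null_values, direction),
                 direction = direction, n_perm = length(null_values)),
            class = "NullDistribution")
}

#' @export
print.NullDistribution <- function(x, ...) {
  cat(sprintf("Permutation test (%s): observed = %g, null mean = %g, p = %g (n_perm = %d)\n",
              x$direction, x$observed, mean(x$null_values), x$p_value, x$n_perm))
  invisible(x)
}
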