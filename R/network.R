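#' Read a gene interaction network from a STRING-style edge list
#'
#' Expects whitespace- or tab-separated rows `geneA geneB score`, with or
#' without a header line. STRING distributes combined scores on a 0-1000
#' integer scale; some exports use 0-1. The scale is auto-detected: if any
#' score exceeds 1 all scores are divided by 1000. Self-loops are dropped
#' with a warning; reciprocal duplicate rows are merged keeping the
#' maximum weight; edges below `score_threshold` (after normalization) are
#' discarded.
#'
#' @param path File to read.
#' @param score_threshold Minimum normalized combined score to keep an
#'   edge; 0.4 is STRING's "medium confidence" default.
#' @return An undirected, simple, weighted [igraph][igraph::igraph-package]
#'   graph with gene ids as vertex names and weights in `(0, 1]`.
#' @export
read_network <- function(path, score_threshold = 0.4) {
  if (!file.exists(path)) abort("file not found: ", path)
  first <- readLines(path, n = 1L)
  toks <- strsplit(trimws(first), "[ \t]+")[[1L]]
  header <- length(toks) >= 3L && is.na(suppressWarnings(as.numeric(toks[3L])))
  tab <- utils::read.table(path, header = header, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) abort("edge list needs 3 columns: geneA geneB score")
  tab <- tab[, 1:3]
  names(tab) <- c("a", "b", "score")
  if (!is.numeric(tab$score)) abort("non-numeric score column in ", path)
  if (any(tab$score > 1)) tab$score <- tab$score / 1000
  if (any(tab$score < 0) || any(tab$score > 1))
    abort("scores outside [0, 1] after scale normalization")
  loops <- tab$a == tab$b
  if (any(loops)) {
    warning(sum(loops), " self-loop row(s) dropped", call. = FALSE)
    tab <- tab[!loops, , drop = FALSE]
  }
  tab <- tab[tab$score >= score_threshold, , drop = FALSE]
  if (!nrow(tab)) abort("no edge survives score_threshold = ", score_threshold)
  # canonical orientation, then merge duplicates keeping the max weight
  key_a <- pmin(tab$a, tab$b)
  key_b <- pmax(tab$a, tab$b)
  w <- tapply(tab$score, paste(key_a, key_b, sep = "\r"), max)
  ends <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ends[, 1L], to = ends[, 2L], weight = as.numeric(w)),
    directed = FALSE)
  g
}

#' Write a network back to an edge-list file
#'
#' Emits one row per edge (`geneA geneB score` on the 0-1 scale), so that
#' [read_network()] round-trips.
#'
#' @param network An igraph graph with a `weight` edge attribute.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network)
  w <- igraph::E(network)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  utils::write.table(data.frame(el[, 1L], el[, 2L], w), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Number of network edges induced by a gene set
#'
#' Counts edges whose two endpoints both lie in `genes` -- the
#' connectivity statistic whose permutation null
#' [connectivity_permutation_test()] builds.
#'
#' @param network An igraph graph.
#' @param genes Character vector of gene ids; ids absent from the network
#'   are dropped with a warning.
#' @return Integer edge count.
#' @export
induced_edge_count <- function(network, genes) {
  present <- intersect(genes, igraph::V(network)$name)
  if (length(present) < length(unique(genes)))
    warning(length(unique(genes)) - length(present),
            " gene(s) not in the network dropped", call. = FALSE)
  if (!length(present)) {
    warning("no gene of the set is in the network", call. = FALSE)
    return(0L)
  }
  igraph::ecount(igraph::induced_subgraph(network, present))
}
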