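#' Simulate a two-group pre/post chemotherapy expression cohort
#'
#' Generates a log2-scale expression matrix for four arms -- resistant and
#' sensitive patients, each sampled before (pre) and after (post)
#' chemotherapy -- with a block of planted differentially expressed genes.
#' Per-gene baseline means are drawn once from Normal(7, 2) (clipped at 0,
#' mimicking microarray dynamic range), i.i.d. Gaussian noise with standard
#' deviation `noise_sd` is added on the log2 scale, and the first
#' `n_de_genes` genes receive a mean shift of magnitude `de_logfc` in the
#' resistant-pre arm relative to sensitive-pre, with alternating sign
#' (odd-indexed planted genes up, even-indexed down).
#'
#' @param n_genes Number of genes.
#' @param n_per_arm Integer vector of arm sizes, in the order
#'   resistant-pre, resistant-post, sensitive-pre, sensitive-post. A single
#'   number is recycled to all four arms.
#' @param n_de_genes Number of planted differentially expressed genes.
#' @param de_logfc Planted mean shift in log2 units.
#' @param noise_sd Noise standard deviation in log2 units.
#' @param seed RNG seed; the cohort is a pure function of the arguments.
#' @return A list with `expr` (an `ExpressionMatrix` with `group` and
#'   `timepoint` annotations) and `truth` (data frame of planted genes and
#'   their direction, `up`/`down`).
#' @export
simulate_cohort <- function(n_genes = 2000, n_per_arm = 15, n_de_genes = 100,
                            de_logfc = 1.0, noise_sd = 0.5, seed = NULL) {
  if (length(n_per_arm) == 1L) n_per_arm <- rep(n_per_arm, 4L)
  problems <- c(
    if (n_de_genes > n_genes) "n_de_genes exceeds n_genes",
    if (noise_sd <= 0) "noise_sd must be > 0",
    if (any(n_per_arm < 0) || n_genes < 1) "counts must be non-negative",
    if (length(n_per_arm) != 4L) "n_per_arm must have length 1 or 4")
  if (length(problems)) abort("invalid cohort spec: ", paste(problems, collapse = "; "))
  maybe_seed(seed)

  arms <- data.frame(
    group = rep(c("resistant", "resistant", "sensitive", "sensitive"), n_per_arm),
    timepoint = rep(c("pre", "post", "pre", "post"), n_per_arm))
  tag <- c(resistant = "R", sensitive = "S")[arms$group]
  arms$sample_id <- sprintf("%s_%s_%02d", tag, arms$timepoint,
                            stats::ave(seq_len(nrow(arms)),
                                       paste(tag, arms$timepoint),
                                       FUN = seq_along))
  n_samples <- nrow(arms)

  genes <- sprintf("gene%04d", seq_len(n_genes))
  base <- pmax(stats::rnorm(n_genes, mean = 7, sd = 2), 0)
  values <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                   nrow = n_genes, dimnames = list(genes, arms$sample_id))
  values <- values + base

  direction <- character(0)
  if (n_de_genes > 0) {
    sign <- rep_len(c(1, -1), n_de_genes)
    direction <- ifelse(sign > 0, "up", "down")
    rpre <- arms$group == "resistant" & arms$timepoint == "pre"
    values[seq_len(n_de_genes), rpre] <-
      values[seq_len(n_de_genes), rpre] + sign * de_logfc
  }

  list(expr = expression_matrix(values,
                                samples = arms[, c("sample_id", "group", "timepoint")]),
       truth = data.frame(gene = genes[seq_len(n_de_genes)],
                          direction = direction,
                          stringsAsFactors = FALSE))
}

#' Simulate a scale-free interaction network with planted resistance genes
#'
#' Builds a preferential-attachment (Barabasi-Albert) backbone, carves out
#' disjoint seed gene sets (emulating curated drug-resistance, stemness and
#' transporter lists), and plants `n_planted` "resistance" genes that gain
#' extra edges to the members of two randomly chosen seed sets, each edge
#' drawn independently with probability `planted_link_prob`. At the default
#' link probability the planted genes sit in the immediate network
#' neighborhood of multiple seed sets -- exactly the configuration the
#' random-walk prioritization stage is designed to detect. All edge
#' weights are 1.
#'
#' @param n_nodes Number of genes (nodes).
#' @param attachment Edges added per node during preferential attachment
#'   (>= 1). The backbone then has exactly
#'   `attachment*(n_nodes-attachment) + choose(attachment, 2)` edges.
#' @param seed_set_sizes Sizes of the disjoint seed gene sets.
#' @param n_planted Number of planted resistance genes.
#' @param planted_link_prob Probability of each planted-gene-to-seed-member
#'   extra edge; 0 makes planted genes indistinguishable from the backbone.
#' @param seed RNG seed.
#' @return A list with `network` (igraph), `seed_sets`
#'   (`GeneSetCollection`), and `planted` (character vector of planted
#'   gene ids).
#' @export
simulate_network <- function(n_nodes = 500, attachment = 2,
                             seed_set_sizes = c(20, 20, 20, 20),
                             n_planted = 20, planted_link_prob = 0.8,
                             seed = NULL) {
  if (sum(seed_set_sizes) + n_planted > n_nodes)
    abort("invalid network spec: seed sets plus planted genes exceed n_nodes")
  if (attachment < 1) abort("invalid network spec: attachment must be >= 1")
  maybe_seed(seed)

  g <- igraph::sample_pa(n_nodes, m = attachment, directed = FALSE)
  igraph::V(g)$name <- sprintf("node%04d", seq_len(n_nodes))
  nodes <- igraph::V(g)$name

  special <- sample(nodes, sum(seed_set_sizes) + n_planted)
  seed_sets <- vector("list", length(seed_set_sizes))
  offset <- 0L
  for (i in seq_along(seed_set_sizes)) {
    seed_sets[[i]] <- special[offset + seq_len(seed_set_sizes[i])]
    offset <- offset + seed_set_sizes[i]
  }
  names(seed_sets) <- sprintf("seed_set_%d", seq_along(seed_sets))
  planted <- if (n_planted > 0) special[offset + seq_len(n_planted)] else character(0)

  if (n_planted > 0 && planted_link_prob > 0 && length(seed_sets) >= 2) {
    new_edges <- character(0)
    for (p in planted) {
      chosen <- sample(seq_along(seed_sets), 2L)
      targets <- unlist(seed_sets[chosen], use.names = FALSE)
      hit <- targets[stats::runif(length(targets)) < planted_link_prob]
      if (length(hit)) new_edges <- c(new_edges, rbind(p, hit))
    }
    if (length(new_edges)) {
      g <- igraph::add_edges(g, new_edges)
      g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
    }
  }
  # preferential attachment leaves no isolated node, but re-link defensively
  iso <- igraph::degree(g) == 0
  if (any(iso)) {
    message(sum(iso), " isolated node(s) re-linked to a random seed member")
    for (v in igraph::V(g)$name[iso])
      g <- igraph::add_edges(g, c(v, sample(unlist(seed_sets), 1L)))
  }
  igraph::E(g)$weight <- 1

  list(network = g,
       seed_sets = gene_set_collection(seed_sets),
       planted = planted)
}

#' Plant gene-set signatures into an expression cohort
#'
#' Draws `n_sets` disjoint random gene sets from the matrix and adds a
#' `shift` (log2 units) to the member genes of the first `shifted_sets`
#' sets in all samples of the named annotation group. Used to give the
#' immune-scoring stage a ground truth: scores of shifted sets should
#' separate the groups, scores of unshifted sets should not.
#'
#' @param expr An `ExpressionMatrix` with a `group` annotation.
#' @param n_sets Number of gene sets to draw.
#' @param set_size Genes per set.
#' @param shifted_sets How many sets (the first ones) receive the shift.
#' @param shift Planted shift in log2 units.
#' @param group Annotation value receiving the shift (e.g. `"resistant"`).
#' @param seed RNG seed.
#' @return A list with `expr` (shifted matrix), `sets`
#'   (`GeneSetCollection`), and `shifted` (names of the shifted sets).
#' @export
simulate_signatures <- function(expr, n_sets = 10, set_size = 20,
                                shifted_sets = 3, shift = 1.0,
                                group = "resistant", seed = NULL) {
  genes <- gene_ids(expr)
  if (n_sets * set_size > length(genes))
    abort("cannot draw ", n_sets, " disjoint sets of ", set_size,
          " genes from ", length(genes), " genes")
  if (shifted_sets > n_sets) abort("shifted_sets exceeds n_sets")
  if (is.null(expr$samples) || !"group" %in% names(expr$samples))
    abort("expr needs a `group` sample annotation")
  maybe_seed(seed)

  picked <- sample(genes, n_sets * set_size)
  sets <- split(picked, rep(seq_len(n_sets), each = set_size))
  names(sets) <- sprintf("signature_%02d", seq_len(n_sets))

  values <- expr$values
  in_group <- expr$samples$group == group
  if (shifted_sets > 0 && shift != 0) {
    for (i in seq_len(shifted_sets))
      values[sets[[i]], in_group] <- values[sets[[i]], in_group] + shift
  }
  list(expr = expression_matrix(values, samples = expr$samples),
       sets = gene_set_collection(sets),
       shifted = names(sets)[seq_len(shifted_sets)])
}
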