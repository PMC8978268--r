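#' Geometric-mean signature score
#'
#' Per-sample summary of a gene set on log2-scale data: the arithmetic
#' mean of the members' log2 values, which equals the log2 of the
#' geometric mean of the linear-scale expression values. Genes of the set
#' absent from the matrix are dropped (the count is reported via a
#' message); no gene present is an error.
#'
#' @param expr An `ExpressionMatrix` (log2 scale).
#' @param gene_set Character vector of gene ids.
#' @param set_name Name used in messages/errors.
#' @return Named numeric vector, one score per sample.
#' @export
geometric_mean_score <- function(expr, gene_set, set_name = "gene set") {
  present <- intersect(unique(gene_set), gene_ids(expr))
  if (!length(present))
    abort("no gene of ", set_name, " is present in the expression matrix")
  n_missing <- length(unique(gene_set)) - length(present)
  if (n_missing > 0)
    message(n_missing, " gene(s) of ", set_name, " absent from the matrix dropped")
  colMeans(expr$values[present, , drop = FALSE])
}

#' Single-sample gene set enrichment score (ssGSEA)
#'
#' Rank-based per-sample enrichment. Within each sample, genes are ranked
#' by expression (descending; ties get average ranks). Walking down the
#' ranked list, the in-set empirical CDF is accumulated with weights
#' `rank^alpha` (rank counted so the top gene has the largest rank value)
#' and the out-of-set ECDF with uniform weights; the enrichment score is
#' the sum over all positions of the difference between the two running
#' CDFs (the integral form of the running sum). Because only ranks enter,
#' the score is invariant under any strictly monotone transform of a
#' sample's expression values.
#'
#' @param expr An `ExpressionMatrix`.
#' @param gene_set Character vector of gene ids; must share at least one
#'   gene with the matrix and must not cover all of it.
#' @param alpha Rank-weighting exponent (default 0.25, the standard
#'   single-sample choice).
#' @param set_name Name used in messages/errors.
#' @return Named numeric vector, one enrichment score per sample.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25, set_name = "gene set") {
  genes <- gene_ids(expr)
  present <- intersect(unique(gene_set), genes)
  if (!length(present))
    abort("no gene of ", set_name, " is present in the expression matrix")
  if (length(present) == length(genes))
    abort(set_name, " covers every gene in the matrix; the out-set is empty")
  in_set <- genes %in% present
  n <- length(genes)
  n_out <- n - sum(in_set)
  apply(expr$values, 2L, function(x) {
    r <- rank(x, ties.method = "average")       # highest expression -> rank n
    ord <- order(r, decreasing = TRUE)
    in_ord <- in_set[ord]
    w <- ifelse(in_ord, r[ord]^alpha, 0)
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!in_ord) / n_out
    sum(p_in - p_out)
  })
}

#' Score a panel of signatures
#'
#' Applies the chosen scorer to every set of a collection; columns follow
#' the input set order.
#'
#' @param expr An `ExpressionMatrix`.
#' @param gene_sets A `GeneSetCollection` (or named list).
#' @param method `"geometric_mean"`, `"ssgsea"`, or `"ssgsea_z"`
#'   (background-normalized, see [background_normalize()]).
#' @param alpha ssGSEA exponent.
#' @param ... Further arguments for `"ssgsea_z"` (`n_perm`, `seed`,
#'   `shuffle`, `pooling`).
#' @return A samples-by-signatures numeric matrix of class
#'   `SignatureScores` with attributes `method` and `genes_used` (per-set
#'   count of genes actually present).
#' @export
score_signature_panel <- function(expr, gene_sets,
                                  method = c("geometric_mean", "ssgsea", "ssgsea_z"),
                                  alpha = 0.25, ...) {
  method <- match.arg(method)
  absent <- names(gene_sets)[vapply(gene_sets, function(s)
    !any(s %in% gene_ids(expr)), logical(1L))]
  if (length(absent))
    abort("gene set(s) fully absent from the matrix: ",
          paste(absent, collapse = ", "))
  if (method == "ssgsea_z")
    return(background_normalize(expr, gene_sets, alpha = alpha, ...))
  scorer <- switch(method,
                   geometric_mean = geometric_mean_score,
                   ssgsea = function(e, s, n) ssgsea_score(e, s, alpha, n))
  cols <- lapply(names(gene_sets), function(nm)
    scorer(expr, gene_sets[[nm]], nm))
  scores <- do.call(cbind, cols)
  colnames(scores) <- names(gene_sets)
  structure(scores, class = c("SignatureScores", class(scores)),
            method = method,
            genes_used = vapply(gene_sets, function(s)
              sum(unique(s) %in% gene_ids(expr)), integer(1L)))
}

#' Background-normalized ssGSEA scores
#'
#' Raw ssGSEA scores are not comparable across samples, so each score is
#' re-expressed as a z-score against a random background: the gene-to-value
#' assignment of the expression matrix is shuffled (per sample by default,
#' preserving each sample's expression distribution), the panel is
#' re-scored, and this is repeated `n_perm` times. For each signature the
#' null scores are pooled over replicates and samples, and the real score
#' is z-scored against that pool: `z = (real - mean(null)) / sd(null)`.
#'
#' @param expr An `ExpressionMatrix`.
#' @param gene_sets A `GeneSetCollection` (or named list).
#' @param n_perm Number of background replicates (default 100; a minimum
#'   of 10 is enforced -- the null standard deviation is too unstable to
#'   divide by below that).
#' @param alpha ssGSEA exponent.
#' @param shuffle `"per_sample"` (each column's values permuted
#'   independently across genes) or `"per_gene"` (each row permuted across
#'   samples).
#' @param pooling `"pooled"` (null pooled over replicates and samples, the
#'   default) or `"per_sample"` (each sample z-scored against its own
#'   replicate null).
#' @param seed RNG seed.
#' @return A `SignatureScores` matrix (method `"ssgsea_z"`).
#' @export
background_normalize <- function(expr, gene_sets, n_perm = 100, alpha = 0.25,
                                 shuffle = c("per_sample", "per_gene"),
                                 pooling = c("pooled", "per_sample"),
                                 seed = NULL) {
  shuffle <- match.arg(shuffle)
  pooling <- match.arg(pooling)
  if (n_perm < 10)
    abort("n_perm must be >= 10 for a stable background standard deviation")
  maybe_seed(seed)

  real <- score_signature_panel(expr, gene_sets, method = "ssgsea", alpha = alpha)
  n_samples <- ncol(expr$values)
  n_sets <- length(gene_sets)
  null_scores <- array(NA_real_, dim = c(n_samples, n_sets, n_perm))
  v <- expr$values
  for (b in seq_len(n_perm)) {
    perm <- if (shuffle == "per_sample") {
      apply(v, 2L, sample)
    } else {
      t(apply(v, 1L, sample))
    }
    dimnames(perm) <- dimnames(v)
    pe <- expression_matrix(perm, samples = expr$samples)
    null_scores[, , b] <- unclass(
      score_signature_panel(pe, gene_sets, method = "ssgsea", alpha = alpha))
  }

  z <- matrix(NA_real_, n_samples, n_sets,
              dimnames = dimnames(unclass(real)))
  for (j in seq_len(n_sets)) {
    if (pooling == "pooled") {
      pool <- as.vector(null_scores[, j, ])
      s <- stats::sd(pool)
      if (!is.finite(s) || s == 0)
        abort("zero background variance for signature ", colnames(real)[j])
      z[, j] <- (real[, j] - mean(pool)) / s
    } else {
      for (i in seq_len(n_samples)) {
        pool <- null_scores[i, j, ]
        s <- stats::sd(pool)
        if (!is.finite(s) || s == 0)
          abort("zero background variance for signature ", colnames(real)[j])
        z[i, j] <- (real[i, j] - mean(pool)) / s
      }
    }
  }
  structure(z, class = c("SignatureScores", "matrix", "array"),
            method = "ssgsea_z", genes_used = attr(real, "genes_used"))
}

#' Two-group Wilcoxon comparison of signature scores or cell fractions
#'
#' Per feature (column), a two-sided Wilcoxon rank-sum test between the
#' two groups: exact for small combined n without ties, normal
#' approximation with tie correction otherwise (the `stats::wilcox.test`
#' conventions). Direction is the sign of the median difference
#' (group A - group B). A feature constant across all samples gets p = 1
#' and direction `"none"`.
#'
#' @param scores Samples-by-features numeric matrix (e.g.
#'   `SignatureScores` or a cell-fraction table); rownames are sample ids.
#' @param labels Factor or character vector of group labels, one per row;
#'   exactly two groups each with >= 2 samples.
#' @return A data frame with columns `feature`, `p_value`, `direction`
#'   (`up` = higher in the first group level, `down`, `none`), `median_a`,
#'   `median_b`.
#' @export
compare_groups <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2)
    abort("exactly two groups required")
  labels <- droplevels(labels)
  if (any(table(labels) < 2)) abort("each group needs >= 2 samples")
  if (length(labels) != nrow(scores))
    abort("labels length must match the number of rows")
  a <- levels(labels)[1L]
  res <- lapply(seq_len(ncol(scores)), function(j) {
    xa <- scores[labels == a, j]
    xb <- scores[labels != a, j]
    if (stats::var(c(xa, xb)) == 0)
      return(data.frame(p_value = 1, direction = "none",
                        median_a = stats::median(xa), median_b = stats::median(xb)))
    p <- suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
    md <- stats::median(xa) - stats::median(xb)
    data.frame(p_value = p,
               direction = if (md > 0) "up" else if (md < 0) "down" else "none",
               median_a = stats::median(xa), median_b = stats::median(xb))
  })
  out <- do.call(rbind, res)
  out <- cbind(feature = colnames(scores), out)
  rownames(out) <- NULL
  out
}

#' Validate a 22-cell-type fraction table
#'
#' Accepts an externally produced immune-cell deconvolution table
#' (samples by cell-type fractions) and checks the contract: every entry
#' in \[0, 1\] and every row summing to 1 within 1e-6.
#'
#' @param path Tab-separated file, first column sample ids, remaining
#'   columns cell-type fractions.
#' @return A samples-by-cell-types numeric matrix.
#' @export
read_cell_fractions <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  if (!is.numeric(m)) abort("non-numeric cell fraction values in ", path)
  if (any(m < 0 | m > 1)) abort("cell fractions must lie in [0, 1]")
  bad <- abs(rowSums(m) - 1) > 1e-6
  if (any(bad))
    abort("cell fraction rows must sum to 1: ",
          paste(rownames(m)[bad], collapse = ", "))
  m
}
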