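#' Consensus clustering with CDF / delta-area model selection
#'
#' Subsampled repeated k-means clustering: for each candidate k,
#' `n_reps` replicates each draw `subsample` of the samples, cluster them,
#' and the consensus matrix entry for a sample pair is the fraction of
#' co-sampled replicates in which the pair was co-clustered. The empirical
#' CDF of the consensus entries and the area under it are computed per k;
#' both classical model-selection indicators -- the per-k area and the
#' delta-area (relative area gain) -- are reported. The optimal k itself
#' is chosen from the same CDF by cluster-assignment ambiguity: the
#' proportion of ambiguous consensus entries, PAC = CDF(0.9) - CDF(0.1),
#' is near 0 when k matches real structure (entries pile up at 0 and 1)
#' and large otherwise, so the smallest k with `PAC <= pac_threshold` is
#' selected. The delta-area elbow alone cannot make this call reliably:
#' subsampled k-means keeps inflating the CDF area well past the true k.
#' Final labels come from average-linkage hierarchical clustering of
#' 1 - consensus at the chosen k.
#'
#' On structureless data no k is unambiguous; the rule then falls back to
#' the smallest k in the range and raises `low_confidence` (also raised
#' whenever the chosen k's ambiguous fraction exceeds 0.3).
#'
#' @param data Samples-by-features numeric matrix; features are
#'   standardized internally.
#' @param k_range Candidate cluster numbers, all in `[2, n_samples - 1]`.
#' @param n_reps Subsampling replicates per k (default 1000).
#' @param subsample Fraction of samples drawn per replicate.
#' @param pac_threshold Maximum ambiguous-entry fraction for a k to count
#'   as stable (default 0.1).
#' @param seed RNG seed.
#' @return A list of class `ConsensusResult`: `consensus` (list of
#'   samples-by-samples matrices, one per k), `cdf` (list of sorted
#'   consensus entries per k), `area` and `delta_area` (named numeric),
#'   `chosen_k`, `labels` (named integer vector), `low_confidence`.
#' @export
consensus_cluster <- function(data, k_range = 2:6, n_reps = 1000,
                              subsample = 0.8, pac_threshold = 0.1,
                              seed = NULL) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (is.null(rownames(data))) rownames(data) <- paste0("sample", seq_len(n))
  if (any(k_range < 2) || any(k_range > n - 1))
    abort("k_range must lie within [2, n_samples - 1]")
  k_range <- sort(unique(as.integer(k_range)))
  maybe_seed(seed)

  keep <- apply(data, 2L, stats::sd) > 0
  z <- scale(data[, keep, drop = FALSE])
  m_sub <- max(2L, round(subsample * n))

  consensus <- list()
  area <- numeric(length(k_range))
  names(area) <- as.character(k_range)
  cdfs <- list()
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    together <- matrix(0, n, n)
    cosampled <- matrix(0, n, n)
    for (b in seq_len(n_reps)) {
      idx <- sample.int(n, m_sub)
      cl <- stats::kmeans(z[idx, , drop = FALSE], centers = k,
                          nstart = 1, iter.max = 50)$cluster
      same <- outer(cl, cl, "==")
      cosampled[idx, idx] <- cosampled[idx, idx] + 1
      together[idx, idx] <- together[idx, idx] + same
    }
    cons <- ifelse(cosampled > 0, together / pmax(cosampled, 1), 0)
    diag(cons) <- 1
    dimnames(cons) <- list(rownames(data), rownames(data))
    consensus[[as.character(k)]] <- cons
    entries <- sort(cons[upper.tri(cons)])
    cdfs[[as.character(k)]] <- entries
    # area under the empirical CDF over [0, 1]
    xs <- c(0, entries, 1)
    cdf_vals <- c(0, seq_along(entries) / length(entries))
    area[ki] <- sum(diff(xs) * cdf_vals)
  }

  delta <- numeric(length(k_range))
  names(delta) <- as.character(k_range)
  delta[1L] <- area[1L]
  if (length(k_range) > 1)
    delta[-1L] <- diff(area) / utils::head(area, -1L)

  pac_by_k <- vapply(consensus, function(cons) {
    e <- cons[upper.tri(cons)]
    mean(e > 0.1 & e < 0.9)
  }, numeric(1L))
  stable <- which(pac_by_k <= pac_threshold)
  fallback <- length(stable) == 0L
  chosen_k <- if (fallback) k_range[1L] else k_range[min(stable)]

  cons <- consensus[[as.character(chosen_k)]]
  hc <- stats::hclust(stats::as.dist(1 - cons), method = "average")
  labels <- stats::cutree(hc, k = chosen_k)
  pac <- pac_by_k[[as.character(chosen_k)]]

  structure(list(consensus = consensus, cdf = cdfs, area = area,
                 delta_area = delta, pac = pac_by_k,
                 chosen_k = chosen_k, labels = labels,
                 low_confidence = fallback || pac > 0.3,
                 ambiguous_fraction = pac,
                 k_range = k_range),
            class = "ConsensusResult")
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("ConsensusResult: k in {%s}, chosen k = %d%s\n",
              paste(x$k_range, collapse = ", "), x$chosen_k,
              if (x$low_confidence) " (low confidence)" else ""))
  cat("cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}
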