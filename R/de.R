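#' Two-group differential expression
#'
#' Per-gene log fold change (`mean(group A) - mean(group B)` on the log2
#' scale) with a two-sided p-value from either Welch's unequal-variance t
#' test (default) or a moderated t in which per-gene pooled variances are
#' shrunk toward the grand mean variance with a fixed prior weight
#' (`s2_g~ = (d0*s2_bar + df_g*s2_g) / (d0 + df_g)`, t referred to a t
#' distribution on `d0 + df_g` degrees of freedom) -- a simple
#' empirical-Bayes stabilization in the spirit of moderated-t pipelines.
#' Swapping the two groups negates every logFC and leaves every p-value
#' unchanged.
#'
#' @param expr An `ExpressionMatrix`.
#' @param group_a,group_b Disjoint character vectors of sample ids, each
#'   with at least two samples.
#' @param test `"welch"` or `"moderated"`.
#' @param prior_df Prior degrees of freedom `d0` for the moderated test.
#' @return A data frame with columns `gene`, `logFC`, `p_value`, `fdr`
#'   (Benjamini-Hochberg, informational only -- screening filters on the
#'   raw p-value).
#' @export
compute_de <- function(expr, group_a, group_b, test = c("welch", "moderated"),
                       prior_df = 4) {
  test <- match.arg(test)
  ids <- sample_ids(expr)
  missing <- setdiff(c(group_a, group_b), ids)
  if (length(missing))
    abort("sample(s) not in matrix: ", paste(missing, collapse = ", "))
  if (length(intersect(group_a, group_b)))
    abort("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "))
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) abort("each group needs >= 2 samples")

  xa <- expr$values[, group_a, drop = FALSE]
  xb <- expr$values[, group_b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  lfc <- ma - mb

  if (test == "welch") {
    se2 <- va / na + vb / nb
    tstat <- lfc / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    s2_tilde <- (prior_df * mean(s2) + (na + nb - 2) * s2) / (prior_df + na + nb - 2)
    tstat <- lfc / sqrt(s2_tilde * (1 / na + 1 / nb))
    df <- rep(prior_df + na + nb - 2, length(lfc))
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  # zero variance in both groups: equal means -> no evidence (p = 1);
  # unequal means -> infinitely strong evidence (p = 0)
  degen <- !is.finite(tstat)
  p[degen] <- ifelse(lfc[degen] == 0, 1, 0)

  data.frame(gene = gene_ids(expr), logFC = lfc, p_value = p,
             fdr = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify genes as up, down or not significant
#'
#' @param de Output of [compute_de()].
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 0.585,
#'   i.e. 1.5-fold).
#' @param p_threshold Raw p-value cutoff.
#' @return `de` with a `direction` factor column (`up`/`down`/`ns`).
#' @export
de_direction <- function(de, lfc_threshold = 0.585, p_threshold = 0.05) {
  dir <- rep("ns", nrow(de))
  sig <- de$p_value < p_threshold
  dir[sig & de$logFC > lfc_threshold] <- "up"
  dir[sig & de$logFC < -lfc_threshold] <- "down"
  de$direction <- factor(dir, levels = c("up", "down", "ns"))
  de
}

#' Screen the four resistance/timepoint contrasts
#'
#' Runs differential expression for the four standard contrasts of a
#' resistant-vs-sensitive, pre/post-chemotherapy cohort:
#'
#' * (a) resistant-pre vs sensitive-pre -- survivors are the
#'   potential drug-resistance genes (PDRGs);
#' * (b) resistant-post vs sensitive-post;
#' * (c) resistant pre vs post;
#' * (d) sensitive pre vs post -- survivors are the potential
#'   drug-induced genes (PDIGs).
#'
#' Genes pass a contrast when `|logFC| > lfc_threshold` and raw
#' `p < p_threshold`. A contrast whose arms have fewer than two samples is
#' skipped with a warning. Pre-vs-post contrasts are unpaired.
#'
#' @param expr An `ExpressionMatrix` whose annotations contain `group`
#'   (`resistant`/`sensitive`) and `timepoint` (`pre`/`post`).
#' @param lfc_threshold,p_threshold Screening cutoffs (defaults 0.585 and
#'   0.05).
#' @param test Passed to [compute_de()].
#' @return A list with `results` (per-contrast direction-annotated data
#'   frames), `counts` (data frame contrast/up/down/total), `pdrg` and
#'   `pdig` (character vectors of surviving genes).
#' @export
screen_contrasts <- function(expr, lfc_threshold = 0.585, p_threshold = 0.05,
                             test = c("welch", "moderated")) {
  test <- match.arg(test)
  ann <- expr$samples
  if (is.null(ann) || !all(c("group", "timepoint") %in% names(ann)))
    abort("expr needs `group` and `timepoint` sample annotations")
  arm <- function(g, t) ann$sample_id[ann$group == g & ann$timepoint == t]
  plan <- list(
    resistant_vs_sensitive_pre  = list(a = arm("resistant", "pre"),
                                       b = arm("sensitive", "pre")),
    resistant_vs_sensitive_post = list(a = arm("resistant", "post"),
                                       b = arm("sensitive", "post")),
    resistant_pre_vs_post       = list(a = arm("resistant", "pre"),
                                       b = arm("resistant", "post")),
    sensitive_pre_vs_post       = list(a = arm("sensitive", "pre"),
                                       b = arm("sensitive", "post")))

  results <- list()
  counts <- data.frame(contrast = character(0), up = integer(0),
                       down = integer(0), total = integer(0))
  for (nm in names(plan)) {
    gs <- plan[[nm]]
    if (length(gs$a) < 2 || length(gs$b) < 2) {
      warning("contrast ", nm, " skipped: an arm has < 2 samples", call. = FALSE)
      next
    }
    de <- de_direction(compute_de(expr, gs$a, gs$b, test = test),
                       lfc_threshold, p_threshold)
    results[[nm]] <- de
    tab <- table(de$direction)
    counts <- rbind(counts, data.frame(
      contrast = nm, up = as.integer(tab[["up"]]),
      down = as.integer(tab[["down"]]),
      total = as.integer(tab[["up"]] + tab[["down"]])))
  }
  surviving <- function(nm) {
    if (is.null(results[[nm]])) return(character(0))
    de <- results[[nm]]
    de$gene[de$direction != "ns"]
  }
  list(results = results, counts = counts,
       pdrg = surviving("resistant_vs_sensitive_pre"),
       pdig = surviving("sensitive_pre_vs_post"))
}
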