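#' The default 15-feature panel layout
#'
#' The resistance classifier summarizes each patient by 15 geometric-mean
#' gene-set scores: five drug-resistance pathways (platinum, antifolate
#' and endocrine resistance, ABC transporters, chemical carcinogenesis),
#' seven immune signatures (MHC class I, adhesion molecules, chemokines,
#' cytolytic markers, IFN-gamma signature, immuno-costimulators,
#' immuno-inhibitors), plus curated ABC transporter and cancer-stemness
#' marker lists and the prioritized resistance-gene set from the
#' network-walk stage. The published panel gives only set names, category
#' labels and sizes -- the member genes are not public -- so this helper
#' builds a synthetic stand-in panel with the documented names, categories
#' and sizes by drawing member genes from a supplied universe. It exists
#' for testing and simulation; real analyses should load their own GMT
#' via [read_gene_sets()].
#'
#' @param gene_universe Character vector of gene ids to draw from.
#' @param potential_set Optional character vector used verbatim as the
#'   `Potential_Set` feature (e.g. the [combine_walks()] output); defaults
#'   to a random draw of 3 genes.
#' @param seed RNG seed.
#' @return A `GeneSetCollection` of 15 sets with a `category` attribute.
#' @export
default_feature_panel <- function(gene_universe, potential_set = NULL,
                                  seed = NULL) {
  layout <- data.frame(
    name = c("KEGG_Platinum_drug_resistance", "KEGG_Antifolate_resistance",
             "KEGG_Endocrine_resistance", "KEGG_ABC_transporters",
             "KEGG_Chemical_carcinogenesis",
             "MHC Class-I", "Adhesion Molecules", "Chemokines",
             "Cytolytic Marker", "IFNg Signature", "Immuno-costimulators",
             "Immuno-inhibitors",
             "ABC_Transporters", "Cancer_Stemness", "Potential_Set"),
    category = rep(c("Drug Resistance Pathway", "Immune Signature", "Other"),
                   c(5L, 7L, 3L)),
    size = c(73L, 31L, 98L, 45L, 82L, 7L, 6L, 5L, 4L, 6L, 17L, 12L,
             4L, 13L, 3L),
    stringsAsFactors = FALSE)
  if (length(gene_universe) < max(layout$size))
    abort("gene universe too small for the panel")
  maybe_seed(seed)
  sets <- lapply(layout$size, function(s) sample(gene_universe, s))
  names(sets) <- layout$name
  if (!is.null(potential_set)) sets[["Potential_Set"]] <- potential_set
  gene_set_collection(sets, description = layout$category,
                      category = stats::setNames(layout$category, layout$name))
}

#' Build the per-patient feature matrix
#'
#' One row per sample, one column per gene set, each entry the
#' geometric-mean score of the set ([geometric_mean_score()]); columns
#' follow the input set order. Labels are attached as a factor with
#' `sensitive` as the reference level and `resistant` as the positive
#' class.
#'
#' @param expr An `ExpressionMatrix`.
#' @param feature_sets A `GeneSetCollection` (typically the 15-set panel).
#' @param labels Character/factor of `resistant`/`sensitive` per sample,
#'   or NULL to take the `group` annotation from `expr`.
#' @return A list of class `FeatureMatrix`: `x` (samples x features
#'   matrix), `y` (factor), `category` (per-feature label vector).
#' @export
build_feature_matrix <- function(expr, feature_sets, labels = NULL) {
  absent <- names(feature_sets)[vapply(feature_sets, function(s)
    !any(s %in% gene_ids(expr)), logical(1L))]
  if (length(absent))
    abort("feature set(s) absent from the matrix: ",
          paste(absent, collapse = ", "))
  if (is.null(labels)) {
    if (is.null(expr$samples) || !"group" %in% names(expr$samples))
      abort("no labels supplied and no `group` annotation on expr")
    labels <- expr$samples$group
  }
  y <- factor(labels, levels = c("sensitive", "resistant"))
  if (anyNA(y)) abort("labels must be 'resistant' or 'sensitive'")
  x <- vapply(names(feature_sets), function(nm)
    geometric_mean_score(expr, feature_sets[[nm]], nm),
    numeric(ncol(expr$values)))
  if (ncol(expr$values) == 1L) x <- matrix(x, nrow = 1L,
                                           dimnames = list(sample_ids(expr),
                                                           names(feature_sets)))
  category <- attr(feature_sets, "category")
  if (is.null(category))
    category <- stats::setNames(rep("Other", length(feature_sets)),
                                names(feature_sets))
  structure(list(x = x, y = y, category = category[colnames(x)]),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix: %d samples x %d features (%d resistant / %d sensitive)\n",
              nrow(x$x), ncol(x$x), sum(x$y == "resistant"),
              sum(x$y == "sensitive")))
  invisible(x)
}

#' Class-balanced random forest
#'
#' Trains a random forest in which every tree sees a balanced training
#' set: all samples of the minority class plus an equal-size uniform draw
#' (without replacement) of the majority class. This is the
#' `strata`/`sampsize` mechanism of randomForest with
#' `replace = FALSE`, so per-tree class balance is exact and is asserted
#' on the in-bag matrix of every tree. The resistant class is the
#' positive class.
#'
#' @param features A `FeatureMatrix`.
#' @param n_trees Number of trees (default 1000).
#' @param seed RNG seed.
#' @param ... Further arguments to [randomForest::randomForest()] (e.g.
#'   `mtry`); depth and split defaults are the library's and are recorded
#'   in the returned object.
#' @return A list of class `BalancedForest`: `model` (randomForest fit),
#'   `importance` (named vector, normalized to sum 1), `category`,
#'   `params`.
#' @export
train_balanced_forest <- function(features, n_trees = 1000, seed = NULL, ...) {
  y <- droplevels(features$y)
  if (nlevels(y) < 2) abort("both classes must be present")
  n_min <- min(table(y))
  if (n_min < 2) abort("minority class needs >= 2 samples")
  maybe_seed(seed)
  sampsize <- stats::setNames(rep(n_min, nlevels(y)), levels(y))
  fit <- randomForest::randomForest(
    x = features$x, y = y, ntree = n_trees,
    strata = y, sampsize = sampsize, replace = FALSE,
    importance = TRUE, keep.inbag = TRUE, ...)
  # defining property: every tree is trained on a class-balanced sample
  inbag_by_class <- rowsum(fit$inbag, group = y)
  if (!all(inbag_by_class == n_min))
    abort("internal error: a tree was not class-balanced")  # nocov
  imp <- fit$importance[, "MeanDecreaseGini"]
  structure(list(model = fit,
                 importance = imp / sum(imp),
                 category = features$category,
                 params = list(n_trees = n_trees, sampsize = n_min,
                               mtry = fit$mtry, nodesize = 1L)),
            class = "BalancedForest")
}

#' Predict resistance probability
#'
#' @param object A `BalancedForest`.
#' @param newdata Samples-by-features matrix (same columns as training).
#' @param ... Ignored.
#' @return Numeric vector of predicted resistant-class probabilities.
#' @export
predict.BalancedForest <- function(object, newdata, ...) {
  stats::predict(object$model, newdata, type = "prob")[, "resistant"]
}

#' Area under the precision-recall curve
#'
#' Step interpolation over the ranked predictions: points are swept in
#' decreasing score order and the area accumulates
#' `(recall_i - recall_{i-1}) * precision_i` -- i.e. average precision.
#'
#' @param labels Binary labels (logical, or factor whose second level is
#'   positive).
#' @param scores Numeric prediction scores, larger = more positive.
#' @return AUC-PR in `[0, 1]`.
#' @export
auc_pr <- function(labels, scores) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2L]
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(scores), any(labels))
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab)
  precision <- tp / seq_along(lab)
  recall <- tp / sum(lab)
  sum(diff(c(0, recall)) * precision)
}

# internal: AUC-ROC with resistant/positive as second factor level
auc_roc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = levels(labels), direction = "<", quiet = TRUE)))
}

#' Stratified cross-validated evaluation of the balanced forest
#'
#' Stratified k-fold cross-validation: within each class, samples are
#' randomly partitioned into k folds; each fold is held out once, the
#' balanced forest refit on the rest, and held-out resistant-probabilities
#' collected. AUC-ROC and AUC-PR are reported per fold and pooled over
#' all held-out predictions.
#'
#' @param features A `FeatureMatrix`.
#' @param k Number of folds (default 5); reduced with a warning if the
#'   minority class has fewer than k samples.
#' @param n_trees Trees per fold model.
#' @param seed RNG seed; the whole report is reproducible from it.
#' @return A list of class `ClassifierReport`: `fold_metrics` (data frame
#'   fold/auc_roc/auc_pr), `pooled_auc_roc`, `pooled_auc_pr`, `folds`
#'   (integer assignment per sample), `predictions`, `importance`
#'   (averaged over fold models, normalized), `full_model`
#'   (a `BalancedForest` on all data), `seed`.
#' @export
cross_validate <- function(features, k = 5, n_trees = 1000, seed = NULL) {
  y <- droplevels(features$y)
  if (any(table(y) < 2)) abort("each class needs >= 2 samples")
  n_min <- min(table(y))
  if (n_min < k) {
    warning("minority class smaller than k; using k = ", n_min, call. = FALSE)
    k <- n_min
  }
  maybe_seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }

  preds <- numeric(length(y))
  fold_metrics <- data.frame(fold = seq_len(k), auc_roc = NA_real_,
                             auc_pr = NA_real_)
  imp <- matrix(0, ncol(features$x), k,
                dimnames = list(colnames(features$x), NULL))
  for (f in seq_len(k)) {
    test <- folds == f
    train_features <- structure(
      list(x = features$x[!test, , drop = FALSE], y = y[!test],
           category = features$category),
      class = "FeatureMatrix")
    fit <- train_balanced_forest(train_features, n_trees = n_trees)
    preds[test] <- predict(fit, features$x[test, , drop = FALSE])
    imp[, f] <- fit$importance
    if (nlevels(droplevels(y[test])) == 2) {
      fold_metrics$auc_roc[f] <- auc_roc(y[test], preds[test])
      fold_metrics$auc_pr[f] <- auc_pr(y[test], preds[test])
    }
  }
  full <- train_balanced_forest(features, n_trees = n_trees)
  structure(list(fold_metrics = fold_metrics,
                 pooled_auc_roc = auc_roc(y, preds),
                 pooled_auc_pr = auc_pr(y, preds),
                 folds = folds, predictions = preds,
                 importance = rowMeans(imp),
                 full_model = full, k = k, seed = seed),
            class = "ClassifierReport")
}

#' @export
print.ClassifierReport <- function(x, ...) {
  cat(sprintf("ClassifierReport: %d-fold CV, pooled AUC-ROC = %.3f, AUC-PR = %.3f\n",
              x$k, x$pooled_auc_roc, x$pooled_auc_pr))
  invisible(x)
}

#' Ranked feature-importance table
#'
#' @param model A `BalancedForest` or `ClassifierReport`.
#' @return Data frame with columns `feature`, `category`, `importance`
#'   (normalized to sum 1), sorted by decreasing importance.
#' @export
feature_importance_report <- function(model) {
  if (inherits(model, "ClassifierReport")) {
    imp <- model$importance
    category <- model$full_model$category
  } else if (inherits(model, "BalancedForest")) {
    imp <- model$importance
    category <- model$category
  } else abort("model must be a BalancedForest or ClassifierReport")
  out <- data.frame(feature = names(imp),
                    category = unname(category[names(imp)]),
                    importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  out
}
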