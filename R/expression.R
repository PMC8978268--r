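#' Expression matrix container
#'
#' Light-weight container for a genes-by-samples matrix of log2 expression
#' values together with optional per-sample annotations. Modeled on limma's
#' `EList`: `$values` holds the matrix (rownames = gene ids, colnames =
#' sample ids), `$samples` a data frame with one row per sample and at
#' least a `sample_id` column; `group` (`"resistant"` / `"sensitive"`) and
#' `timepoint` (`"pre"` / `"post"`) columns drive the contrast machinery.
#'
#' @param values Numeric matrix with unique rownames (genes) and colnames
#'   (samples). No missing values are allowed; see `impute`.
#' @param samples Optional data frame of per-sample annotations. Matched to
#'   the matrix columns by its `sample_id` column (or rownames).
#' @param impute Missing-value policy: `"none"` (reject, the default) or
#'   `"row-mean"` (replace each NA with the mean of the gene's observed
#'   values).
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, samples = NULL, impute = c("none", "row-mean")) {
  impute <- match.arg(impute)
  if (!is.matrix(values) || !is.numeric(values))
    abort("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    abort("duplicate gene ids: ",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    abort("duplicate sample ids: ",
          paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) {
    if (impute == "none")
      abort("missing expression values; pass impute = \"row-mean\" to impute")
    rm <- rowMeans(values, na.rm = TRUE)
    idx <- which(is.na(values), arr.ind = TRUE)
    values[idx] <- rm[idx[, 1L]]
    if (anyNA(values)) abort("genes with all values missing cannot be imputed")
  }
  if (!is.null(samples)) {
    samples <- as.data.frame(samples)
    if (!"sample_id" %in% names(samples)) {
      if (is.null(rownames(samples)))
        abort("`samples` needs a sample_id column or rownames")
      samples$sample_id <- rownames(samples)
    }
    miss <- setdiff(colnames(values), samples$sample_id)
    if (length(miss))
      abort("samples missing from annotations: ", paste(miss, collapse = ", "))
    samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
    rownames(samples) <- samples$sample_id
  }
  structure(list(values = values, samples = samples), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$samples)) {
    ann <- setdiff(names(x$samples), "sample_id")
    if (length(ann)) cat("annotations:", paste(ann, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read an expression matrix from TSV or GCT
#'
#' TSV dialect: first column gene ids, header row of sample ids, tab
#' separated. GCT 1.2 dialect: `#1.2` version line, a `rows\tcolumns`
#' dimension line, then a table whose first two columns are NAME and
#' Description. Values are taken as-is (assumed log2 scale).
#'
#' @param path File to read.
#' @param format `"tsv"` or `"gct"`; default guesses from the extension.
#' @param annotations Optional path to a tab-separated annotation table with
#'   columns `sample_id`, `group`, and optionally `timepoint`.
#' @param impute Missing-value policy, see [expression_matrix()].
#' @return An `ExpressionMatrix`.
#' @export
read_expression_matrix <- function(path, format = c("auto", "tsv", "gct"),
                                   annotations = NULL,
                                   impute = c("none", "row-mean")) {
  format <- match.arg(format)
  impute <- match.arg(impute)
  if (!file.exists(path)) abort("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3L || !startsWith(lines[1L], "#1.2"))
      abort("malformed GCT header in ", path, ": expected '#1.2' version line")
    dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]][1:2]))
    if (anyNA(dims)) abort("malformed GCT dimension line in ", path)
    tab <- utils::read.delim(text = lines[-(1:2)], check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (nrow(tab) != dims[1L] || ncol(tab) - 2L != dims[2L])
      abort(sprintf("GCT dimension line says %d x %d but table is %d x %d",
                    dims[1L], dims[2L], nrow(tab), ncol(tab) - 2L))
    ids <- as.character(tab[[1L]])
    vals <- tab[, -(1:2), drop = FALSE]
  } else {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1L]])
    vals <- tab[, -1L, drop = FALSE]
  }
  bad <- which(!vapply(vals, is.numeric, logical(1L)))
  if (length(bad))
    abort("non-numeric expression column(s): ",
          paste(colnames(vals)[bad], collapse = ", "))
  if (anyDuplicated(ids))
    abort("duplicate gene row(s): ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "),
          " -- collapse probe-level data with collapse_probes() first")
  m <- as.matrix(vals)
  rownames(m) <- ids
  ann <- if (!is.null(annotations)) read_sample_annotations(annotations) else NULL
  expression_matrix(m, samples = ann, impute = impute)
}

#' Read a per-sample annotation table
#'
#' Tab-separated with a header; must contain `sample_id` and `group`
#' columns, and usually `timepoint`.
#'
#' @param path File to read.
#' @return A data frame.
#' @export
read_sample_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- setdiff(c("sample_id", "group"), names(ann))
  if (length(need))
    abort("annotation file missing column(s): ", paste(need, collapse = ", "))
  if (anyDuplicated(ann$sample_id))
    abort("duplicate sample_id in annotation file")
  ann
}

#' Write an expression matrix
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output file.
#' @param format `"tsv"` or `"gct"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  m <- x$values
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
    tab <- data.frame(NAME = rownames(m), Description = "na",
                      m, check.names = FALSE)
    utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    tab <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Collapse probe-level values to gene level
#'
#' Microarray platforms measure several probes per gene; the gene's
#' expression is taken as the arithmetic mean of its probes' values on the
#' stored log2 scale. Probes absent from the map (unannotated) are dropped
#' with a message reporting the count.
#'
#' @param probe_values Numeric probes-by-samples matrix with probe rownames.
#' @param probe_map Data frame with columns `probe` and `gene`, or a named
#'   character vector (names = probes, values = genes).
#' @param samples Optional annotations, passed to [expression_matrix()].
#' @return An `ExpressionMatrix` at gene level.
#' @export
collapse_probes <- function(probe_values, probe_map, samples = NULL) {
  if (!is.matrix(probe_values) || is.null(rownames(probe_values)))
    abort("`probe_values` must be a matrix with probe rownames")
  if (is.data.frame(probe_map)) {
    map <- stats::setNames(as.character(probe_map$gene), as.character(probe_map$probe))
  } else {
    map <- probe_map
  }
  genes <- map[rownames(probe_values)]
  keep <- !is.na(genes) & genes != ""
  if (!any(keep)) abort("no probe in `probe_values` maps to a gene")
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " probe(s) without a gene mapping dropped")
  pv <- probe_values[keep, , drop = FALSE]
  genes <- genes[keep]
  collapsed <- rowsum(pv, group = genes, reorder = TRUE) /
    as.vector(table(genes)[sort(unique(genes))])
  expression_matrix(as.matrix(collapsed), samples = samples)
}
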