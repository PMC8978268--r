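#' Gene set collection
#'
#' A named list of character vectors (gene ids) with optional per-set
#' descriptions and categories, as read from GMT files.
#'
#' @param sets Named list of character vectors.
#' @param description Optional character vector of per-set descriptions.
#' @param category Optional character vector of per-set category labels
#'   (used to tag classifier features, e.g. "Immune Signature").
#' @return A `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, description = NULL, category = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == ""))
    abort("`sets` must be a non-empty named list")
  if (anyDuplicated(names(sets)))
    abort("duplicate set names: ",
          paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, as.character)
  if (any(lengths(sets) == 0L))
    abort("empty gene set(s): ",
          paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  dup <- vapply(sets, anyDuplicated, integer(1L)) > 0L
  if (any(dup)) {
    warning("duplicate genes within set(s) ",
            paste(names(sets)[dup], collapse = ", "), "; deduplicated",
            call. = FALSE)
    sets[dup] <- lapply(sets[dup], unique)
  }
  structure(sets, class = "GeneSetCollection",
            description = description, category = category)
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d set(s)\n", length(x)))
  sizes <- lengths(unclass(x))
  for (i in seq_len(min(10L, length(x))))
    cat(sprintf("  %s (%d genes)\n", names(x)[i], sizes[i]))
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' GMT dialect: one set per line, tab separated -- set name, description,
#' then gene ids. Lines with fewer than three fields are rejected with the
#' offending line number; duplicate genes within a set are deduplicated
#' with a warning.
#'
#' @param path File to read.
#' @return A `GeneSetCollection`.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    abort("GMT line ", short[1L], " has fewer than 3 fields in ", path)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1L), 1L)
  desc <- vapply(fields, `[[`, character(1L), 2L)
  gene_set_collection(sets, description = desc)
}

#' Write gene sets to a GMT file
#'
#' @param x A `GeneSetCollection` (or plain named list).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(x, path) {
  desc <- attr(x, "description")
  if (is.null(desc)) desc <- rep("na", length(x))
  lines <- vapply(seq_along(x), function(i) {
    paste(c(names(x)[i], desc[i], x[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
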