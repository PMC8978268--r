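#' Add-one empirical p-value
#'
#' Smoothed tail probability of an observed statistic against a permutation
#' null: `(1 + #(null beyond observed)) / (n + 1)`. The add-one guarantees
#' the p-value is never zero and is the usual convention for Monte-Carlo
#' permutation tests.
#'
#' @param observed Observed statistic (length 1).
#' @param null_values Numeric vector of null statistics.
#' @param direction `"greater"`, `"less"` or `"two.sided"`.
#' @return A p-value in `(0, 1]`; never smaller than `1/(length(null_values)+1)`.
#' @export
empirical_p <- function(observed, null_values,
                        direction = c("greater", "less", "two.sided")) {
  direction <- match.arg(direction)
  stopifnot(length(observed) == 1L, is.numeric(null_values),
            length(null_values) >= 1L)
  n <- length(null_values)
  p_hi <- (1 + sum(null_values >= observed)) / (n + 1)
  p_lo <- (1 + sum(null_values <= observed)) / (n + 1)
  switch(direction,
         greater   = p_hi,
         less      = p_lo,
         two.sided = min(1, 2 * min(p_hi, p_lo)))
}

# internal: stop() with a consistent prefix so callers can grep errors
abort <- function(...) stop(..., call. = FALSE)

# internal: set the RNG seed only when the caller supplied one
maybe_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
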