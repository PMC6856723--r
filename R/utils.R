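#' @keywords internal
"_PACKAGE"

#' Derive a reproducible child seed from a parent seed and a stream label
#'
#' One global seed is split into independent per-module seeds so that every
#' stage of a run is reproducible in isolation. The result is always below
#' 2^31.
#'
#' @param seed parent integer seed.
#' @param stream character label of the consuming stage.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

#' Benjamini-Hochberg q-values with a declared family size
#'
#' Step-up adjusted q-values. Unlike [stats::p.adjust()], the family size `m`
#' may exceed the number of p-values supplied, which is needed when a declared
#' test family includes tests that were skipped (e.g. degenerate pairs in the
#' interaction screen): the correction still accounts for the full family.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param family_size the number of tests in the family; defaults to
#'   `length(p)`.
#' @return numeric vector of q-values, same order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p, family_size = length(p)) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  if (!is_count(family_size) || family_size < length(p))
    stopf("family_size must be an integer >= length(p)")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  # step-up: q_(i) = min_{j >= i} m * p_(j) / j, ranks taken within the family
  q <- pmin(1, cummin(family_size * p[o] / (n - seq_len(n) + 1L)))[ro]
  q
}
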