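# Overrepresentation analysis: upper-tail hypergeometric test of a query gene
# set against an annotation catalog within a universe, with Benjamini-
# Hochberg FDR across terms.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for the overlap X of a random size-`n` draw from a universe of
#' `N` genes of which `K` belong to the term. Evaluated through the
#' log-space-stable distribution function of the hypergeometric family.
#'
#' @param N universe size.
#' @param K term size within the universe.
#' @param n query size within the universe.
#' @param k observed overlap.
#' @return Probability in (0, 1]; `k = 0` gives exactly 1.
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  if (N < 0 || K < 0 || K > N || n < 0 || n > N) {
    stop("require 0 <= K <= N and 0 <= n <= N")
  }
  if (k < 0 || k > min(K, n)) stop("require 0 <= k <= min(K, n)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return Adjusted values, capped at 1, order-preserving.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Overrepresentation analysis of a query set against a catalog
#'
#' Each catalog term is intersected with the universe; terms with no members
#' left are dropped. The query must be contained in the universe. One-sided
#' (overrepresentation only); FDR is computed across the emitted terms.
#'
#' @param query character vector of gene ids, a subset of `universe`.
#' @param universe character vector of gene ids (e.g. all expressed genes).
#' @param catalog an `annotation_catalog` from [read_annotation_gmt()] or
#'   [generate_annotation_catalog()].
#' @return data.frame sorted by p-value: `term`, `N`, `K`, `n`, `k`,
#'   `p_value`, `fdr`.
#' @export
run_ora <- function(query, universe, catalog) {
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    stop("query gene outside the universe: ", outside[1L])
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(catalog$terms), function(term) {
    members <- intersect(catalog$terms[[term]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, query))
    data.frame(term = term, N = N, K = K, n = n, k = k,
               p_value = hypergeometric_tail(N, K, n, k),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(term = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p_value = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
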