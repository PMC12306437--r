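#' Cumulative hypergeometric enrichment of an identified gene set
#'
#' Upper-tail hypergeometric overlap test between an identified gene set
#' (e.g. the lncRNAs of significant synergy pairs) and a functional
#' catalogue, within a common universe:
#' \deqn{P = 1 - \sum_{i=0}^{k-1} \binom{m}{i}\binom{N-m}{n-i} / \binom{N}{n}}
#' with `N` the universe size, `m` the functional-set size, `n` the
#' identified-set size and `k` their overlap. Evaluated in log-space via
#' [stats::phyper()], so catalogue-scale inputs (N ~ 20000) are safe.
#' `k = 0` gives p = 1 (empty sum), and `m = N` gives p = 1 (overlap is
#' certain).
#'
#' @param universe Character vector of all eligible gene ids.
#' @param functional_set,identified_set Character vectors; must be subsets
#'   of `universe`, and `identified_set` must be non-empty.
#' @return One-row tibble with `N`, `m`, `n`, `k` and `p`.
#' @examples
#' hypergeom_enrichment(letters[1:10], letters[1:5], letters[3:6])
#' @export
hypergeom_enrichment <- function(universe, functional_set, identified_set) {
  universe <- unique(universe)
  functional_set <- unique(functional_set)
  identified_set <- unique(identified_set)
  bad <- setdiff(c(functional_set, identified_set), universe)
  if (length(bad)) {
    stop("set members outside the universe: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "", call. = FALSE)
  }
  n <- length(identified_set)
  if (n == 0) stop("identified set is empty", call. = FALSE)
  N <- length(universe)
  m <- length(functional_set)
  k <- length(intersect(functional_set, identified_set))
  p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  tibble::tibble(N = N, m = m, n = n, k = k, p = p)
}
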