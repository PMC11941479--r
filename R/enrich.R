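# Hypergeometric category over-representation testing.

#' Upper-tail hypergeometric enrichment test
#'
#' Exact probability of drawing at least `k` category members when `n`
#' items are selected without replacement from a universe of `N` containing
#' `K` category members — e.g. the chance that at least `k` of `n`
#' dysregulated miRNAs are primate-specific when `K` of the `N` miRNAs
#' tested are. `P(X >= 0) = 1` by construction.
#'
#' @param N Universe size (miRNAs tested).
#' @param K Category size within the universe.
#' @param n Selected set size.
#' @param k Overlap between selection and category.
#' @return The upper-tail p-value `P(X >= k)`.
#' @examples
#' hypergeom_enrichment(10, 5, 4, 4)   # 5/210
#' @export
hypergeom_enrichment <- function(N, K, n, k) {
  check_enrichment_counts(N, K, n, k)
  if (k == 0L) return(1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

check_enrichment_counts <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals != floor(vals)) || any(vals < 0)) {
    stop("counts must be non-negative integers")
  }
  if (K > N || n > N) stop("require K <= N and n <= N")
  if (k > min(K, n)) stop("overlap k exceeds min(K, n)")
  if (k < max(0L, n - (N - K))) {
    stop("overlap k below the feasible minimum max(0, n - (N - K))")
  }
  invisible(TRUE)
}

#' Derive enrichment counts from ID lists
#'
#' Builds the [hypergeom_enrichment()] input from three identifier sets:
#' the universe (e.g. all miRNAs included in differential expression
#' analysis), the category (e.g. primate-specific miRNAs) and the selection
#' (e.g. dysregulated miRNAs). Category and selection are intersected with
#' the universe first.
#'
#' @param universe,category,selected Character vectors of IDs.
#' @return A list with `N`, `K`, `n`, `k` and `p_value`.
#' @export
enrichment_from_lists <- function(universe, category, selected) {
  universe <- unique(universe)
  category <- intersect(unique(category), universe)
  selected <- intersect(unique(selected), universe)
  N <- length(universe); K <- length(category)
  n <- length(selected); k <- length(intersect(selected, category))
  list(N = N, K = K, n = n, k = k,
       p_value = hypergeom_enrichment(N, K, n, k))
}
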