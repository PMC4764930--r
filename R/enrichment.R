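#' Right-tail hypergeometric (Fisher) enrichment p-value
#'
#' Probability of observing at least `k_overlap` catalogue genes in a random
#' query of `n_query` genes drawn from a universe of `N` genes containing
#' `K_assoc` catalogue members:
#' \deqn{p = \sum_{j=k}^{\min(n, K)} \binom{K}{j} \binom{N-K}{n-j} / \binom{N}{n}}
#' evaluated on the log scale for stability. This is the one-sided Fisher
#' exact test used to ask whether a biomarker's regulated genes
#' over-represent a disease gene catalogue.
#'
#' @param N Universe size.
#' @param K_assoc Catalogue genes in the universe.
#' @param n_query Query-set size.
#' @param k_overlap Overlap between query and catalogue.
#' @return The right-tail p-value in `(0, 1]` (vectorized over the inputs).
#' @export
#' @examples
#' hypergeom_pvalue(N = 10, K_assoc = 5, n_query = 5, k_overlap = 5) # 1/252
hypergeom_pvalue <- function(N, K_assoc, n_query, k_overlap) {
  stopifnot(all(k_overlap <= pmin(n_query, K_assoc)),
            all(K_assoc <= N), all(n_query <= N), all(k_overlap >= 0))
  # P(X >= k) with X ~ Hypergeom(N, K, n); phyper works in log space
  stats::phyper(k_overlap - 1, K_assoc, N - K_assoc, n_query,
                lower.tail = FALSE)
}

#' Enrichment of a query gene set against a catalogue
#'
#' Builds the hypergeometric counts by (case-sensitive) set intersection and
#' computes the right-tail p-value. The universe must be stated explicitly:
#' an enrichment value is meaningless without a declared gene space, and the
#' natural choice is the catalogue's full annotation space (e.g. all genes
#' with any curated disease association).
#'
#' @param query Character vector of query gene identifiers (e.g. the
#'   deregulated targets of a biomarker). Must be a subset of `universe`.
#' @param catalogue Character vector of disease-associated gene identifiers.
#' @param universe Character vector defining the gene space.
#' @return A one-row tibble: `N`, `K_assoc`, `n_query`, `k_overlap`,
#'   `p_value`.
#' @export
enrich_from_lists <- function(query, catalogue, universe) {
  query <- unique(as.character(query))
  catalogue <- unique(as.character(catalogue))
  universe <- unique(as.character(universe))
  stray <- setdiff(query, universe)
  if (length(stray) > 0) {
    stop("query gene(s) outside the declared universe: ",
         paste(utils::head(stray, 10), collapse = ", "), call. = FALSE)
  }
  cat_in <- intersect(catalogue, universe)
  k <- length(intersect(query, cat_in))
  tibble::tibble(
    N = length(universe),
    K_assoc = length(cat_in),
    n_query = length(query),
    k_overlap = k,
    p_value = hypergeom_pvalue(length(universe), length(cat_in),
                               length(query), k)
  )
}
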