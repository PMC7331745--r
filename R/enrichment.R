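#' Over-representation analysis against a gene-set collection
#'
#' One-sided hypergeometric enrichment of a query gene list in each set of
#' the collection. With universe size N, annotated query size n, set size K
#' and k query genes in the set: p = P(X >= k), fold enrichment
#' = (k/n) / (K/N). Query genes outside the universe are dropped (with a
#' logged count); q-values are Benjamini-Hochberg over all tested terms.
#'
#' @param query Character vector of gene ids.
#' @param collection A `gene_sets` collection.
#' @param alpha Significance threshold on raw p (default 0.05).
#' @param universe Optional explicit background; defaults to the
#'   collection's universe.
#' @return Data frame sorted by p: `term_id`, `description`, `k`, `n`, `K`,
#'   `N`, `fold_enrichment`, `p_value`, `q_value`, `significant`.
#' @export
enrich <- function(query, collection, alpha = 0.05, universe = NULL) {
  stopifnot(inherits(collection, "gene_sets"))
  universe <- unique(universe %||% NULL)
  if (is.null(universe)) universe <- collection$universe
  query <- unique(query)
  dropped <- sum(!(query %in% universe))
  if (dropped) message(dropped, " query gene(s) outside the universe dropped")
  query <- intersect(query, universe)
  if (!length(query)) {
    warning("empty query after universe restriction", call. = FALSE)
    return(data.frame(term_id = character(0), description = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), fold_enrichment = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(tid) {
    members <- intersect(collection$sets[[tid]], universe)
    K <- length(members)
    k <- length(intersect(query, members))
    data.frame(term_id = tid,
               description = unname(collection$descriptions[tid]),
               k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N),
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
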