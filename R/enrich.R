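# Generic over-representation test for gene sets against a flat,
# user-supplied term annotation (a stand-in for GO/DAVID-style enrichment:
# no ontology structure, just term -> gene sets).

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test per term: with a universe of `N` genes,
#' `K` of them annotated to the term, and a query of `n` genes of which
#' `k` carry the term, `p = P(X >= k)` for `X ~ Hypergeom(N, K, n)`.
#' P-values are adjusted across terms (Benjamini-Hochberg by default).
#' Genes outside the universe are ignored on both sides.
#'
#' @param query character vector of gene ids of interest.
#' @param terms either a data.frame with columns `term_id` and `gene_id`
#'   (optionally `term_name`), or a named list of gene-id vectors.
#' @param universe character vector defining the gene universe (e.g. all
#'   genes on the expression platform present in the annotation).
#' @param adjust multiple-testing method for [stats::p.adjust()].
#' @return data.frame sorted by p: `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `p`, `p_adj`.
#' @export
hypergeom_enrich <- function(query, terms, universe, adjust = "BH") {
  universe <- unique(as.character(universe))
  query <- intersect(unique(as.character(query)), universe)
  if (!length(query)) stop2("query is disjoint from the universe")
  if (is.data.frame(terms)) {
    if (!all(c("term_id", "gene_id") %in% names(terms))) {
      stop2("term table needs columns 'term_id' and 'gene_id'")
    }
    name_map <- if ("term_name" %in% names(terms)) {
      tapply(terms$term_name, terms$term_id, `[`, 1)
    }
    terms <- split(as.character(terms$gene_id), terms$term_id)
  } else {
    name_map <- NULL
  }
  if (!length(terms)) stop2("no terms supplied")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(terms), function(tid) {
    tg <- intersect(unique(as.character(terms[[tid]])), universe)
    K <- length(tg)
    k <- length(intersect(tg, query))
    p <- if (K == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid,
               term_name = if (!is.null(name_map)) unname(name_map[tid]) else tid,
               k = k, K = K, n = n, N = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
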