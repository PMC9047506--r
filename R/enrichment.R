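#' Hypergeometric over-representation analysis
#'
#' One-sided over-representation test of a gene list against flat
#' term-to-gene maps: for each term, p = P(X >= k) with
#' X ~ Hypergeometric(N = universe size, K = term size, n = list size),
#' followed by BH adjustment across terms. A flat stand-in for ontology
#' enrichment: no DAG propagation, no length-bias correction.
#'
#' @param gene_list character vector of genes of interest; genes outside
#'   the universe are dropped with a message.
#' @param term2gene data.frame with columns `term` and `gene` (extra
#'   columns ignored); terms with no member genes in the universe are
#'   dropped.
#' @param universe background gene identifiers.
#' @param descriptions optional data.frame with columns `term`, `description`.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @return data.frame sorted by p: `term`, `description`, `k` (list hits),
#'   `K` (term size), `n` (list size), `N` (universe size), `p`, `padj`,
#'   `significant`.
#' @export
hypergeometric_enrichment <- function(gene_list, term2gene, universe,
                                      descriptions = NULL, alpha = 0.05) {
  if (!length(gene_list)) stopf("empty gene list")
  if (!length(universe)) stopf("empty universe")
  universe <- unique(universe)
  drop <- setdiff(gene_list, universe)
  if (length(drop)) {
    message(sprintf("dropping %d gene(s) not in the universe", length(drop)))
    gene_list <- intersect(gene_list, universe)
  }
  if (!length(gene_list)) stopf("no gene in the list belongs to the universe")
  term2gene <- term2gene[term2gene$gene %in% universe, , drop = FALSE]
  terms <- split(unique(term2gene[, c("term", "gene")])$gene,
                 unique(term2gene[, c("term", "gene")])$term)
  terms <- terms[lengths(terms) > 0]
  if (!length(terms)) stopf("no term has members in the universe")
  N <- length(universe); n <- length(gene_list)
  rows <- lapply(names(terms), function(t) {
    members <- terms[[t]]
    K <- length(members)
    k <- length(intersect(gene_list, members))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = t, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- p.adjust(out$p, method = "BH")
  out$description <- if (!is.null(descriptions))
    descriptions$description[match(out$term, descriptions$term)] else NA_character_
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$term), c("term", "description", "k", "K", "n",
                                       "N", "p", "padj", "significant")]
  rownames(out) <- NULL
  out
}
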