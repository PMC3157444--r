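#' Gene-set over-representation analysis
#'
#' Over-representation of annotation terms in a gene list is scored with the
#' upper-tail hypergeometric probability (one-sided Fisher exact test):
#' with a universe of N genes of which K carry the term, a list of n genes
#' with k term members has p = P(X >= k). Fold enrichment is
#' `(k / n) / (K / N)`. An EASE-style penalized variant (one overlap gene
#' removed before computing the tail) is available behind a flag. No
#' multiple-testing correction is applied; reporting uses raw-p and
#' fold-enrichment cut-offs with ranking by count.
#'
#' @name enrichment
NULL

#' Hypergeometric term enrichment
#'
#' @param gene_list Character vector of genes of interest (must be a subset
#'   of `universe`).
#' @param universe Character vector: the reference gene population (e.g.,
#'   all genes represented on the array).
#' @param annotations Named list of character vectors: term id -> member
#'   genes. Members are harmonized to the universe; terms left empty are
#'   dropped.
#' @param ease If `TRUE`, compute the EASE-penalized tail (count reduced by
#'   one) instead of the plain hypergeometric tail.
#' @return `data.frame` with columns `term`, `count`, `list_size`,
#'   `pop_hits`, `pop_size`, `fold_enrichment`, `p_value`.
#' @export
fisher_enrichment <- function(gene_list, universe, annotations,
                              ease = FALSE) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  if (length(gene_list) == 0 || length(universe) == 0) {
    stop("gene list and universe must be nonempty")
  }
  if (!all(gene_list %in% universe)) {
    stop("gene list contains genes outside the universe")
  }
  harm <- lapply(annotations, intersect, y = universe)
  keep <- lengths(harm) > 0
  if (any(!keep)) {
    message(sum(!keep), " term(s) dropped: no members in universe")
  }
  harm <- harm[keep]
  N <- length(universe)
  n <- length(gene_list)
  res <- lapply(names(harm), function(term) {
    members <- harm[[term]]
    K <- length(members)
    k <- length(intersect(gene_list, members))
    k_eff <- if (ease) max(k - 1L, 0L) else k
    p <- stats::phyper(k_eff - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, count = k, list_size = n, pop_hits = K,
               pop_size = N,
               fold_enrichment = (k / n) / (K / N),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Filter and rank enrichment results
#'
#' Keeps terms with `p < p_cutoff` AND `fold_enrichment > fold_cutoff`
#' (both strict), sorted by descending count; ties broken by ascending p,
#' then term id.
#'
#' @param results Output of [fisher_enrichment()].
#' @param p_cutoff p-value cutoff (default 0.05).
#' @param fold_cutoff Fold-enrichment cutoff (default 2).
#' @return Filtered, ranked `data.frame`.
#' @export
filter_and_rank <- function(results, p_cutoff = 0.05, fold_cutoff = 2) {
  keep <- results$p_value < p_cutoff & results$fold_enrichment > fold_cutoff
  out <- results[keep, , drop = FALSE]
  out <- out[order(-out$count, out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
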