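#' Hypergeometric over-representation analysis
#'
#' Tests a gene list against each gene set: with universe size `N`, set size
#' `K` (after intersecting the set with the universe), list size `n` (after
#' dropping list genes outside the universe, which are reported) and overlap
#' `k`, the p-value is the upper tail `P(X >= k)` of the hypergeometric
#' distribution. P-values are BH-adjusted across all tested sets and results
#' are sorted by adjusted p.
#'
#' The gene-set semantics are deliberately generic: any GMT collection works
#' (GO, pathways, custom panels); no ontology structure or database lookup is
#' involved.
#'
#' @param gene_list character vector of genes of interest.
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param universe character vector: the gene universe (must be supplied
#'   explicitly; typically the expressed genes).
#' @return data.frame of class `ora_result`, one row per non-empty set:
#'   `set`, `overlap_k`, `list_n`, `set_K`, `universe_N`, `p`, `padj`,
#'   `genes` (comma-separated overlap). Attribute `dropped` lists gene-list
#'   entries outside the universe.
#' @export
ora <- function(gene_list, sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  gene_list <- unique(as.character(gene_list))
  dropped <- setdiff(gene_list, universe)
  if (length(dropped))
    message(length(dropped), " gene(s) of the list are outside the universe",
            " and were dropped")
  gl <- intersect(gene_list, universe)
  N <- length(universe)
  n <- length(gl)
  rows <- lapply(names(sets), function(s) {
    set <- intersect(unique(sets[[s]]), universe)
    K <- length(set)
    if (K == 0) return(NULL)
    ov <- intersect(gl, set)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, overlap_k = k, list_n = n, set_K = K, universe_N = N,
               p = p, genes = paste(ov, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    stop("no gene set overlaps the universe")
  res <- do.call(rbind, rows)
  res$padj <- bh_adjust(res$p)
  res <- res[order(res$padj, res$p, res$set),
             c("set", "overlap_k", "list_n", "set_K", "universe_N",
               "p", "padj", "genes")]
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  class(res) <- c("ora_result", "data.frame")
  res
}
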