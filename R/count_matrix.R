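#' Construct a validated count matrix
#'
#' Bundles a genes x samples matrix of non-negative integer read counts with
#' per-gene feature lengths (in bp), as produced by featureCounts-style
#' quantification. Gene ids are taken from the matrix row names and sample ids
#' from the column names; both must be unique.
#'
#' @param counts numeric matrix of non-negative integers with unique row names
#'   (gene ids) and unique column names (sample ids). Fractional values are
#'   rejected, not rounded: the downstream negative-binomial model assumes
#'   counts.
#' @param lengths numeric vector of feature lengths in bp, one per gene
#'   (>= 1). May be named; names must then match the gene ids.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (numeric matrix) and `lengths` (named numeric vector).
#' @examples
#' m <- matrix(c(0, 5, 10, 2, 0, 7), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' cm <- count_matrix(m, lengths = c(1000, 2000, 1500))
#' dim(cm)
#' @export
count_matrix <- function(counts, lengths) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as row names and sample ids as column names")
  gid <- rownames(counts)
  sid <- colnames(counts)
  dup <- unique(gid[duplicated(gid)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  dup <- unique(sid[duplicated(sid)])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite numbers")
  if (any(counts < 0)) {
    bad <- gid[which(rowSums(counts < 0) > 0)[1]]
    stop("negative count found (gene ", bad, ")")
  }
  if (any(counts != round(counts))) {
    bad <- gid[which(rowSums(counts != round(counts)) > 0)[1]]
    stop("non-integer count found (gene ", bad, "); counts are not rounded")
  }
  if (length(lengths) == 1L) lengths <- rep(lengths, nrow(counts))
  if (length(lengths) != nrow(counts))
    stop("lengths must have one entry per gene (missing length)")
  if (!is.null(names(lengths))) {
    if (!setequal(names(lengths), gid))
      stop("names of lengths do not match gene ids (missing length)")
    lengths <- lengths[gid]
  } else {
    names(lengths) <- gid
  }
  if (any(!is.finite(lengths) | lengths < 1))
    stop("feature lengths must be finite and >= 1 bp")
  storage.mode(counts) <- "double"
  structure(list(counts = counts, lengths = lengths), class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$counts)

#' Gene and sample ids of a count matrix
#' @param cm a [count_matrix()]
#' @return character vector of ids.
#' @export
gene_ids <- function(cm) rownames(cm$counts)

#' @rdname gene_ids
#' @export
sample_ids <- function(cm) colnames(cm$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("feature length (bp): ",
      paste(round(stats::quantile(x$lengths, c(0, .5, 1))), collapse = " / "),
      " (min/median/max)\n", sep = "")
  invisible(x)
}

#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  count_matrix(x$counts[i, j, drop = FALSE], x$lengths[i])
}

#' Remove genes with zero reads in all samples
#'
#' Genes whose counts are zero across every sample carry no information and
#' are removed before any normalization or testing. The removed ids are
#' attached as attribute `removed_genes` of the result.
#'
#' @param cm a [count_matrix()]
#' @return A `count_matrix` containing only genes with row sum > 0, with
#'   attribute `removed_genes` (character vector of dropped gene ids). The
#'   operation is idempotent.
#' @export
drop_all_zero_genes <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  keep <- rowSums(cm$counts) > 0
  if (!any(keep))
    stop("all genes have zero counts in all samples; empty matrix")
  removed <- rownames(cm$counts)[!keep]
  out <- cm[which(keep), ]
  attr(out, "removed_genes") <- removed
  out
}

# internal: validate a sample sheet against a count matrix
.check_sheet <- function(sheet, cm = NULL) {
  if (!is.data.frame(sheet))
    stop("sample sheet must be a data.frame")
  need <- c("sample_id", "population")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("sample sheet is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("sample sheet has duplicated sample ids")
  if (!is.null(cm)) {
    miss <- setdiff(sample_ids(cm), sheet$sample_id)
    if (length(miss))
      stop("samples absent from sheet: ", paste(utils::head(miss, 5), collapse = ", "))
    sheet <- sheet[match(sample_ids(cm), sheet$sample_id), , drop = FALSE]
  }
  sheet
}
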