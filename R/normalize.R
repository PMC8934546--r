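#' Normalized expression matrix
#'
#' Lightweight container for a genes x samples matrix of normalized values,
#' remembering which scale it is on and, where applicable, the size factors
#' used.
#'
#' @param values numeric genes x samples matrix.
#' @param scale one of `"tpm"`, `"size_factor_normalized"`,
#'   `"log2_normalized"`, `"log2_batch_adjusted"`.
#' @param size_factors optional named positive numeric vector per sample.
#' @return an object of class `normalized_matrix`.
#' @export
normalized_matrix <- function(values,
                              scale = c("size_factor_normalized", "tpm",
                                        "log2_normalized",
                                        "log2_batch_adjusted"),
                              size_factors = NULL) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (!is.null(size_factors) && any(size_factors <= 0))
    stop("size factors must be strictly positive")
  structure(list(values = values, scale = scale, size_factors = size_factors),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix (%s): %d genes x %d samples\n",
              x$scale, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
as.matrix.normalized_matrix <- function(x, ...) x$values

#' @export
dim.normalized_matrix <- function(x) dim(x$values)

# accept a normalized_matrix or a bare matrix
.values <- function(x) if (inherits(x, "normalized_matrix")) x$values else x

#' Transcripts per million
#'
#' Length-normalized expression: per sample j, `rate_gj = count_gj /
#' length_g` and `tpm_gj = rate_gj / sum_g(rate_gj) * 1e6`, so every column
#' sums to one million.
#'
#' @param cm a [count_matrix()] with feature lengths in bp.
#' @return a [normalized_matrix()] on the `"tpm"` scale.
#' @export
tpm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  zero <- colSums(cm$counts) == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(sample_ids(cm)[zero], collapse = ", "))
  rate <- cm$counts / cm$lengths
  vals <- sweep(rate, 2, colSums(rate), "/") * 1e6
  normalized_matrix(vals, "tpm")
}

#' Median-of-ratios size factors
#'
#' The standard library-size estimate for count data: each sample's factor is
#' the median, over genes with a strictly positive geometric mean across
#' samples, of that sample's count divided by the gene's geometric mean.
#' Genes with a zero count in any sample are excluded from the median but are
#' retained in the matrix.
#'
#' @param cm a [count_matrix()]
#' @return named positive numeric vector, one size factor per sample.
#' @export
size_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  loggeo <- rowMeans(log(cm$counts))
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no gene has positive counts in all samples; consider a ",
         "pseudo-reference fallback on a filtered gene subset")
  sf <- apply(log(cm$counts[use, , drop = FALSE]) - loggeo[use], 2,
              stats::median)
  exp(sf)
}

#' Size-factor-normalized counts
#'
#' Divides each sample's counts by its median-of-ratios size factor.
#'
#' @param cm a [count_matrix()]
#' @param sf optional precomputed size factors (named per sample).
#' @return a [normalized_matrix()] on the `"size_factor_normalized"` scale.
#' @export
normalize_counts <- function(cm, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(cm)
  if (any(sf <= 0)) stop("size factors must be strictly positive")
  normalized_matrix(sweep(cm$counts, 2, sf, "/"),
                    "size_factor_normalized", size_factors = sf)
}

#' Log2 of normalized counts plus a pseudo-count
#'
#' The scale on which batch adjustment, replicate correlation and heatmap
#' z-scores operate. The pseudo-count (default 1) is configurable.
#'
#' @param cm a [count_matrix()] or a `normalized_matrix` of normalized counts.
#' @param pseudo pseudo-count added before taking log2.
#' @param sf optional size factors when `cm` is a `count_matrix`.
#' @return a [normalized_matrix()] on the `"log2_normalized"` scale.
#' @export
log2_normalized <- function(cm, pseudo = 1, sf = NULL) {
  nm <- if (inherits(cm, "count_matrix")) normalize_counts(cm, sf) else cm
  v <- log2(.values(nm) + pseudo)
  normalized_matrix(v, "log2_normalized",
                    size_factors = if (inherits(nm, "normalized_matrix"))
                      nm$size_factors else NULL)
}

#' Remove patient (batch) effects from log expression
#'
#' Per gene, fits a least-squares model of log2 expression on population
#' indicators plus sum-to-zero patient indicators and subtracts the patient
#' contribution, keeping population effects intact (the approach of
#' `limma::removeBatchEffect`, which performs the fit). The adjustment is a
#' linear projection: applying it twice equals applying it once, and planted
#' patient offsets that sum to zero across patients are removed exactly on a
#' balanced design. Intended for visualization-grade matrices (PCA, heatmaps,
#' profiles); differential testing instead models the patient in the count
#' model (see [nb_wald_test()]).
#'
#' @param nm a `normalized_matrix` (or bare matrix) of log2 expression, e.g.
#'   from [log2_normalized()].
#' @param sheet sample sheet with `population` and `patient` columns.
#' @return a [normalized_matrix()] on the `"log2_batch_adjusted"` scale.
#' @export
adjust_for_patient <- function(nm, sheet) {
  v <- .values(nm)
  sheet <- .check_sheet(sheet)
  if (!"patient" %in% names(sheet))
    stop("sample sheet has no patient column")
  sheet <- sheet[match(colnames(v), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id))
    stop("samples absent from sheet: ",
         paste(setdiff(colnames(v), sheet$sample_id), collapse = ", "))
  pop <- factor(sheet$population)
  pat <- factor(sheet$patient)
  design <- stats::model.matrix(~pop)
  cb <- stats::contr.sum(nlevels(pat))
  batch <- cb[as.integer(pat), , drop = FALSE]
  full <- cbind(design, batch)
  qr_full <- qr(full)
  if (qr_full$rank < ncol(full)) {
    aliased <- colnames(full)[qr_full$pivot[-seq_len(qr_full$rank)]]
    stop("design is confounded; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  out <- limma::removeBatchEffect(v, batch = pat, design = design)
  normalized_matrix(out, "log2_batch_adjusted",
                    size_factors = if (inherits(nm, "normalized_matrix"))
                      nm$size_factors else NULL)
}
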