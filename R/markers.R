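#' Sample quantile with linear interpolation
#'
#' The type-7 estimator: the quantile sits at position `(n - 1) * q` (0-based)
#' between order statistics, linearly interpolated. `q = 0` gives the
#' minimum, `q = 1` the maximum.
#'
#' @param values numeric vector (non-empty).
#' @param q quantile fraction in \[0, 1\].
#' @return the quantile, as a bare number.
#' @export
sample_quantile <- function(values, q) {
  if (!length(values)) stop("empty input")
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  unname(stats::quantile(values, probs = q, type = 7, names = FALSE))
}

#' Two-step marker discovery for a focal population
#'
#' Step 1 keeps genes significantly upregulated in the focal population
#' versus *every* other population (`log2fc > lfc_threshold` and
#' `padj < padj_threshold` in each pairwise contrast). Step 2 keeps, of
#' those, only genes whose 10th percentile of normalized expression across
#' the focal population's samples exceeds the 90th percentile across the
#' samples of every other population (quantile non-overlap; levels
#' configurable). Specificity is the gap `p10_focal - max_other p90_other`
#' in expression units, and markers are ranked by specificity (descending,
#' ties broken by gene id).
#'
#' The percentiles here are quantiles across a population's *samples* of one
#' gene's expression - a different object from the gene-rank percentiles of
#' [percentile_profile()].
#'
#' @param nm a `normalized_matrix` of size-factor-normalized counts (or bare
#'   matrix on the scale the quantile gap should be judged on).
#' @param sheet sample sheet.
#' @param focal focal population label.
#' @param de named list of [nb_wald_test()] results, one per non-focal
#'   population (names = population), with the focal population as contrast
#'   `A` (positive log2fc = higher in focal).
#' @param top_k how many markers to return (audit table covers all
#'   candidates). If fewer genes pass, all passing genes are returned with a
#'   warning.
#' @param lfc_threshold,padj_threshold step-1 thresholds.
#' @param q_gap quantile-gap levels `c(low, high)`, default `c(0.1, 0.9)`.
#' @return object of class `marker_report`: list with `markers` (character,
#'   the top-k passing gene ids), `table` (audit data.frame over all step-1
#'   candidates: per-contrast DE pass flags, `p10_focal`, per-population
#'   `p90_*`, `passes_de_vs_all`, `passes_quantile_gap`, `specificity`,
#'   `rank`), and the parameters used.
#' @export
find_markers <- function(nm, sheet, focal, de, top_k = 10,
                         lfc_threshold = 2, padj_threshold = 0.05,
                         q_gap = c(0.1, 0.9)) {
  v <- .values(nm)
  sheet <- .check_sheet(sheet)
  pops <- setdiff(unique(sheet$population), focal)
  miss <- setdiff(pops, names(de))
  if (length(miss))
    stop("missing DE contrast for population(s): ", paste(miss, collapse = ", "))
  samp_of <- function(p) intersect(sheet$sample_id[sheet$population == p],
                                   colnames(v))
  if (length(samp_of(focal)) < 2)
    stop("focal population needs >= 2 samples for sample-level quantiles")

  # step-1 flags per contrast, for every gene
  genes <- rownames(v)
  pass_de <- sapply(pops, function(p) {
    d <- de[[p]]
    ok <- !is.na(d$padj) & d$padj < padj_threshold &
      d$log2fc > lfc_threshold
    ok[match(genes, d$gene_id)]
  })
  if (is.null(dim(pass_de)))
    pass_de <- matrix(pass_de, ncol = length(pops),
                      dimnames = list(NULL, pops))
  pass_de[is.na(pass_de)] <- FALSE
  candidates <- genes[rowSums(pass_de) > 0]
  if (!length(candidates)) {
    warning("no gene is upregulated versus any other population")
    return(structure(list(markers = character(),
                          table = data.frame(),
                          focal = focal, q_gap = q_gap,
                          lfc_threshold = lfc_threshold,
                          padj_threshold = padj_threshold),
                     class = "marker_report"))
  }

  fs <- samp_of(focal)
  p10 <- apply(v[candidates, fs, drop = FALSE], 1, sample_quantile, q = q_gap[1])
  p90 <- sapply(pops, function(p) {
    js <- samp_of(p)
    apply(v[candidates, js, drop = FALSE], 1, sample_quantile, q = q_gap[2])
  })
  if (is.null(dim(p90))) p90 <- matrix(p90, nrow = length(candidates),
                                       dimnames = list(candidates, pops))
  max_p90 <- apply(p90, 1, max)

  tab <- data.frame(gene_id = candidates,
                    p10_focal = p10,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (p in pops) tab[[paste0("p90_", p)]] <- p90[, p]
  for (p in pops) tab[[paste0("de_pass_", p)]] <- pass_de[match(candidates, genes), p]
  tab$passes_de_vs_all <- rowSums(!pass_de[match(candidates, genes), ,
                                           drop = FALSE]) == 0
  tab$passes_quantile_gap <- p10 > max_p90
  tab$specificity <- p10 - max_p90

  pass <- tab$passes_de_vs_all & tab$passes_quantile_gap
  ord <- order(-tab$specificity, tab$gene_id)
  tab <- tab[ord, , drop = FALSE]
  pass <- pass[ord]
  tab$rank <- NA_integer_
  tab$rank[pass] <- seq_len(sum(pass))
  passing <- tab$gene_id[pass]
  if (length(passing) < top_k)
    warning("only ", length(passing), " genes pass both steps (top_k = ",
            top_k, ")")
  structure(list(markers = utils::head(passing, top_k), table = tab,
                 focal = focal, q_gap = q_gap,
                 lfc_threshold = lfc_threshold,
                 padj_threshold = padj_threshold),
            class = "marker_report")
}

#' @export
print.marker_report <- function(x, ...) {
  cat(sprintf("marker_report for %s: %d candidates, %d pass both steps\n",
              x$focal, nrow(x$table), sum(!is.na(x$table$rank))))
  if (length(x$markers))
    cat("top markers: ", paste(x$markers, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# deterministic 1-d 2-means (Lloyd, centers initialised at the extremes)
.kmeans2_1d <- function(x, maxit = 100L) {
  c1 <- min(x); c2 <- max(x)
  cl <- as.integer(abs(x - c2) < abs(x - c1)) + 1L
  for (i in seq_len(maxit)) {
    m1 <- mean(x[cl == 1L]); m2 <- mean(x[cl == 2L])
    new <- as.integer(abs(x - m2) < abs(x - m1)) + 1L
    if (all(new == cl)) break
    cl <- new
  }
  cl
}

#' Score and cluster samples by a marker panel
#'
#' Z-scores each panel gene across samples (on the values given), averages
#' the z-scores over the panel per sample, and partitions samples by 2-means
#' clustering of the panel score. Reports the purity with which
#' focal-labelled samples separate: the fraction of samples on the correct
#' side when the higher-scoring cluster is taken as the focal one.
#' Zero-variance panel genes are dropped with a warning; panel genes absent
#' from the matrix are reported in `missing`.
#'
#' @param nm expression matrix (`normalized_matrix` or bare matrix) of the
#'   validation samples; values are z-scored per gene as given.
#' @param sheet sample sheet of the validation samples.
#' @param panel character vector of marker gene ids (>= 2 must be present).
#' @param focal population label expected to score high.
#' @return list with `score` (named per-sample mean panel z-score),
#'   `cluster` (1/2, cluster 2 = higher mean score), `purity`, `missing`,
#'   `dropped` (constant genes).
#' @export
score_panel <- function(nm, sheet, panel, focal) {
  v <- .values(nm)
  sheet <- .check_sheet(sheet)
  sheet <- sheet[match(colnames(v), sheet$sample_id), , drop = FALSE]
  missing <- setdiff(panel, rownames(v))
  panel2 <- intersect(panel, rownames(v))
  if (length(panel2) < 2)
    stop("fewer than 2 panel genes present in the matrix")
  sub <- v[panel2, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  dropped <- panel2[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warning("constant panel gene(s) dropped: ", paste(dropped, collapse = ", "))
    panel2 <- setdiff(panel2, dropped)
    if (length(panel2) < 2) stop("fewer than 2 usable panel genes")
    sub <- v[panel2, , drop = FALSE]
    sds <- sds[panel2]
  }
  z <- (sub - rowMeans(sub)) / sds
  score <- colMeans(z)
  cl <- .kmeans2_1d(score)
  hi <- if (mean(score[cl == 2L]) >= mean(score[cl == 1L])) 2L else 1L
  is_focal <- sheet$population == focal
  purity <- mean((cl == hi) == is_focal)
  list(score = stats::setNames(score, colnames(v)),
       cluster = stats::setNames(cl, colnames(v)),
       purity = purity, missing = missing, dropped = dropped)
}
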