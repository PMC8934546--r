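#' Percentile profile of a population
#'
#' Ranks a population's genes by mean normalized expression and rescales the
#' ranks to \[0, 100\]: the lowest-expressed gene gets 0, the highest gets
#' 100, and ties receive the average of their ranks
#' (`percentile = (rank - 1) / (G - 1) * 100`). Being rank-based, the profile
#' is invariant to any strictly monotone transform of expression.
#'
#' @param nm a `normalized_matrix` (size-factor-normalized counts by
#'   default in the pipeline) or bare matrix.
#' @param sheet sample sheet.
#' @param population population label to profile.
#' @return object of class `percentile_profile`: list with `population`,
#'   `percentile` (named vector in \[0, 100\]) and `mean_expression`.
#' @export
percentile_profile <- function(nm, sheet, population) {
  v <- .values(nm)
  sheet <- .check_sheet(sheet)
  j <- sheet$sample_id[sheet$population == population]
  j <- intersect(j, colnames(v))
  if (!length(j)) stop("no samples for population ", population)
  if (nrow(v) < 2) stop("need at least 2 genes")
  m <- rowMeans(v[, j, drop = FALSE])
  r <- rank(m, ties.method = "average")
  pct <- (r - 1) / (length(m) - 1) * 100
  structure(list(population = population,
                 percentile = stats::setNames(pct, rownames(v)),
                 mean_expression = m),
            class = "percentile_profile")
}

#' @export
print.percentile_profile <- function(x, ...) {
  cat(sprintf("percentile_profile of %s: %d genes\n",
              x$population, length(x$percentile)))
  invisible(x)
}

#' Percentile-rank similarity between two populations
#'
#' Per gene, similarity is `1 - |delta percentile| / 100` (in \[0, 1\]; 1
#' means the gene occupies the same rank in both transcriptomes). The overall
#' similarity of the two populations is summarised by the squared Pearson
#' correlation R^2 of the percentile vectors, with higher values meaning more
#' similar global expression rankings. Note that R^2 ignores the sign of the
#' correlation: an exactly reversed ranking also yields R^2 = 1 even though
#' per-gene similarities are low - a property of the chosen statistic.
#'
#' @param pa,pb [percentile_profile()]s over the same gene universe.
#' @return object of class `similarity_result`: list with `populations`,
#'   `similarity` (per-gene), `r`, `r_squared`, `p_value` (correlation test).
#'   Symmetric in the pair.
#' @export
pairwise_similarity <- function(pa, pb) {
  stopifnot(inherits(pa, "percentile_profile"),
            inherits(pb, "percentile_profile"))
  ga <- names(pa$percentile); gb <- names(pb$percentile)
  if (!setequal(ga, gb))
    stop("profiles cover different gene universes (symmetric difference ",
         length(union(setdiff(ga, gb), setdiff(gb, ga))), " genes)")
  x <- pa$percentile
  y <- pb$percentile[ga]
  sim <- 1 - abs(x - y) / 100
  ct <- stats::cor.test(x, y)
  structure(list(populations = c(pa$population, pb$population),
                 similarity = sim,
                 r = unname(ct$estimate),
                 r_squared = unname(ct$estimate)^2,
                 p_value = ct$p.value),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("similarity %s vs %s: R^2 = %.3f (p = %.3g), mean per-gene = %.3f\n",
              x$populations[1], x$populations[2], x$r_squared, x$p_value,
              mean(x$similarity)))
  invisible(x)
}

#' @export
plot.similarity_result <- function(x, ...) {
  stop("plotting requires the percentile profiles; use plot(pa, pb) via ",
       "plot_similarity()")
}

#' Scatter plot of two percentile profiles
#'
#' Base-graphics scatter of the two percentile vectors, coloured by per-gene
#' similarity.
#'
#' @param pa,pb [percentile_profile()]s.
#' @param ... passed to [graphics::plot()].
#' @export
plot_similarity <- function(pa, pb, ...) {
  s <- pairwise_similarity(pa, pb)
  cols <- grDevices::colorRampPalette(c("red", "yellow", "darkgreen"))(100)
  idx <- pmax(1, ceiling(s$similarity * 100))
  graphics::plot(pa$percentile, pb$percentile[names(pa$percentile)],
                 col = cols[idx], pch = 16, cex = 0.4,
                 xlab = paste("percentile,", pa$population),
                 ylab = paste("percentile,", pb$population),
                 main = sprintf("R^2 = %.3f", s$r_squared), ...)
  invisible(s)
}

#' Within-population replicate correlations
#'
#' All pairwise Pearson correlations between a population's samples, computed
#' on `log2(normalized + 1)` expression - the standard replicate-quality
#' summary (reported as min / mean / max).
#'
#' @param nm a `normalized_matrix` of normalized counts (values are logged
#'   internally unless the scale already is a log scale) or bare matrix of
#'   normalized counts.
#' @param sheet sample sheet.
#' @param population population label.
#' @return list with `population`, `n_pairs`, `min`, `mean`, `max` and the
#'   full `pairs` data.frame; `NA` summary with a warning when fewer than two
#'   samples are present.
#' @export
replicate_correlations <- function(nm, sheet, population) {
  v <- .values(nm)
  if (!(inherits(nm, "normalized_matrix") && grepl("^log2", nm$scale)))
    v <- log2(v + 1)
  sheet <- .check_sheet(sheet)
  j <- intersect(sheet$sample_id[sheet$population == population], colnames(v))
  if (length(j) < 2) {
    warning("population ", population, " has fewer than 2 samples; ",
            "correlations undefined")
    return(list(population = population, n_pairs = 0L,
                min = NA_real_, mean = NA_real_, max = NA_real_,
                pairs = data.frame()))
  }
  cc <- stats::cor(v[, j, drop = FALSE])
  ut <- which(upper.tri(cc), arr.ind = TRUE)
  pairs <- data.frame(sample_a = j[ut[, 1]], sample_b = j[ut[, 2]],
                      r = cc[ut], stringsAsFactors = FALSE)
  list(population = population, n_pairs = nrow(pairs),
       min = min(pairs$r), mean = mean(pairs$r), max = max(pairs$r),
       pairs = pairs)
}
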