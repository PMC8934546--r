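#' Marker-panel contamination QC
#'
#' Screens every sample against population-specific marker panels to detect
#' cross-population contamination (e.g. a microglia sample carrying a
#' monocyte signature). Two explicit rules generate flags:
#'
#' * `"foreign>own"`: the mean `log2(normalized + 1)` expression of a foreign
#'   population's panel exceeds that of the sample's own panel. This fires
#'   when the foreign signature dominates the sample.
#' * `"foreign-z"`: the sample is an outlier among its population peers on a
#'   foreign panel score. The z-score uses leave-one-out centring (mean of
#'   the same-population peers, the sample excluded) and a pooled
#'   within-population scale (all populations, the sample excluded), which
#'   keeps the null distribution close to normal. `z_threshold` (default 2)
#'   is interpreted as a per-sample familywise level across the foreign
#'   panels examined, via a Sidak adjustment of the per-panel cutoff, so the
#'   expected false-flag rate of a pure sample is about `1 - pnorm(2)`
#'   (2.3%) regardless of how many panels are screened.
#'
#' With `k` same-population samples the leave-one-out centring needs
#' `k >= 3`; panels for populations with fewer samples only participate as
#' foreign signatures.
#'
#' @param nm a `normalized_matrix` of size-factor-normalized counts (logged
#'   internally) or bare matrix.
#' @param sheet sample sheet.
#' @param panels named list (or `gene_set_collection`) mapping population
#'   label to its marker gene ids; every population in `sheet` that should be
#'   screened needs its own panel plus at least one foreign panel.
#' @param z_threshold z cutoff of the `"foreign-z"` rule (default 2).
#' @return object of class `qc_report`: list with `panel_scores` (samples x
#'   panels matrix of mean log2 panel expression), `flags` (data.frame:
#'   `sample_id`, `population`, `foreign_panel`, `rule`, `statistic`),
#'   `flagged` (named logical per sample), and `replicate_correlations`
#'   (per-population min/mean/max summary).
#' @export
qc_samples <- function(nm, sheet, panels, z_threshold = 2) {
  v <- .values(nm)
  if (!(inherits(nm, "normalized_matrix") && grepl("^log2", nm$scale)))
    v <- log2(v + 1)
  sheet <- .check_sheet(sheet)
  sheet <- sheet[match(colnames(v), sheet$sample_id), , drop = FALSE]
  pops <- unique(sheet$population)
  panels <- lapply(panels, intersect, y = rownames(v))
  if (!any(lengths(panels) > 0))
    stop("no panel genes found in the expression matrix")
  panels <- panels[lengths(panels) > 0]
  own_defined <- intersect(pops, names(panels))
  if (!length(own_defined) || length(panels) < 2)
    stop("need an own-population panel and at least one foreign panel")

  S <- sapply(panels, function(g) colMeans(v[g, , drop = FALSE]))
  if (is.null(dim(S)))
    S <- matrix(S, ncol = length(panels),
                dimnames = list(colnames(v), names(panels)))

  flags <- list()
  for (i in seq_len(nrow(sheet))) {
    own <- sheet$population[i]
    if (!own %in% names(panels)) next
    foreign <- setdiff(names(panels), own)
    k <- length(foreign)
    # Sidak: per-panel cutoff giving familywise level 1 - pnorm(z_threshold)
    alpha_fam <- stats::pnorm(z_threshold, lower.tail = FALSE)
    zcut <- stats::qnorm((1 - (1 - alpha_fam)^(1 / k)), lower.tail = FALSE)
    for (p in foreign) {
      if (S[i, p] > S[i, own])
        flags[[length(flags) + 1L]] <-
          data.frame(sample_id = sheet$sample_id[i], population = own,
                     foreign_panel = p, rule = "foreign>own",
                     statistic = S[i, p] - S[i, own],
                     stringsAsFactors = FALSE)
      peers <- which(sheet$population == own)
      peers <- setdiff(peers, i)
      if (length(peers) < 2) next
      ctr <- mean(S[peers, p])
      # pooled within-population variance of this panel score, sample i excluded
      ssq <- 0; df <- 0
      for (q in pops) {
        idx <- setdiff(which(sheet$population == q), i)
        if (length(idx) >= 2) {
          ssq <- ssq + sum((S[idx, p] - mean(S[idx, p]))^2)
          df <- df + length(idx) - 1
        }
      }
      if (df < 1 || ssq <= 0) next
      z <- (S[i, p] - ctr) / sqrt(ssq / df)
      if (z > zcut)
        flags[[length(flags) + 1L]] <-
          data.frame(sample_id = sheet$sample_id[i], population = own,
                     foreign_panel = p, rule = "foreign-z", statistic = z,
                     stringsAsFactors = FALSE)
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(sample_id = character(), population = character(),
               foreign_panel = character(), rule = character(),
               statistic = numeric(), stringsAsFactors = FALSE)
  flagged <- stats::setNames(sheet$sample_id %in% flags$sample_id,
                             sheet$sample_id)
  repcor <- lapply(pops, function(p) {
    rc <- suppressWarnings(replicate_correlations(
      normalized_matrix(v, "log2_normalized"), sheet, p))
    data.frame(population = p, n_pairs = rc$n_pairs, min = rc$min,
               mean = rc$mean, max = rc$max, stringsAsFactors = FALSE)
  })
  structure(list(panel_scores = S, flags = flags, flagged = flagged,
                 replicate_correlations = do.call(rbind, repcor),
                 z_threshold = z_threshold),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d samples, %d flagged\n",
              length(x$flagged), sum(x$flagged)))
  if (nrow(x$flags)) {
    cat("flags:\n")
    print(x$flags, row.names = FALSE)
  }
  invisible(x)
}
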