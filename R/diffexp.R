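#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: with sorted p-values `p_(1) <= ... <=
#' p_(m)`, `q_(i) = min_{k >= i} p_(k) * m / k`, capped at 1 and returned in
#' the input order. `NA` entries are passed through and do not count toward
#' `m`.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values, same length and order; `q >= p` genewise.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Estimate per-gene negative-binomial dispersions
#'
#' A deliberately simple two-stage estimator. Stage 1: a method-of-moments
#' gene-wise estimate on size-factor-normalized counts,
#' \eqn{\hat\alpha_g = \max(0, (s^2_g - \bar\mu_g) / \bar\mu_g^2)}, where
#' \eqn{s^2_g} pools the within-group sample variances and \eqn{\bar\mu_g} is
#' the overall mean. Stage 2: a mean-dispersion trend
#' \eqn{\alpha_{tr}(\mu) = a_0 + a_1/\mu} fitted by robust regression over
#' genes with a positive gene-wise estimate. The final dispersion is a
#' log-scale weighted average of the gene-wise estimate and the trend
#' (weight `trend_weight` on the trend); genes whose moment estimate is
#' non-positive carry no evidence of overdispersion and take the trend value.
#' Everything is floored at 1e-8.
#'
#' This is not a replica of the Cox-Reid adjusted-likelihood machinery of
#' dedicated DE packages; its contract is statistical calibration of the
#' downstream Wald test, checked by simulation.
#'
#' @param cm a [count_matrix()]
#' @param sheet sample sheet; groups are taken from the `population` column.
#' @param sf optional precomputed size factors.
#' @param trend_weight weight of the trend in the log-scale average (default
#'   0.5).
#' @return named numeric vector of dispersions, one per gene; attributes
#'   `trend` (fitted `c(a0, a1)`) and `genewise` (the moment estimates).
#' @export
estimate_dispersions <- function(cm, sheet, sf = NULL, trend_weight = 0.5) {
  stopifnot(inherits(cm, "count_matrix"), trend_weight >= 0, trend_weight <= 1)
  sheet <- .check_sheet(sheet, cm)
  if (is.null(sf)) sf <- size_factors(cm)
  K <- sweep(cm$counts, 2, sf, "/")
  grp <- factor(sheet$population)
  mubar <- rowMeans(K)

  ss <- 0; df <- 0
  for (g in levels(grp)) {
    j <- which(grp == g)
    if (length(j) >= 2) {
      m <- rowMeans(K[, j, drop = FALSE])
      ss <- ss + rowSums((K[, j, drop = FALSE] - m)^2)
      df <- df + (length(j) - 1)
    }
  }
  if (df == 0) stop("need at least one group with >= 2 samples")
  s2 <- ss / df

  raw <- (s2 - mubar) / mubar^2
  raw[!is.finite(raw)] <- 0          # constant all-zero rows etc.
  genewise <- pmax(raw, 0)

  use <- mubar > 0 & genewise > 0
  if (sum(use) < 10) {
    warning("fewer than 10 genes available for trend fitting; ",
            "using gene-wise estimates")
    alpha <- pmax(genewise, 1e-8)
    attr(alpha, "trend") <- c(a0 = NA_real_, a1 = NA_real_)
    attr(alpha, "genewise") <- genewise
    names(alpha) <- gene_ids(cm)
    return(alpha)
  }
  fit <- tryCatch(
    MASS::rlm(genewise[use] ~ I(1 / mubar[use]), maxit = 50),
    error = function(e) stats::lm(genewise[use] ~ I(1 / mubar[use])))
  a0 <- max(stats::coef(fit)[1], 1e-6)
  a1 <- max(stats::coef(fit)[2], 0)
  trend <- a0 + a1 / pmax(mubar, 1e-8)

  alpha <- ifelse(raw > 0,
                  exp((1 - trend_weight) * log(pmax(genewise, 1e-8)) +
                        trend_weight * log(trend)),
                  trend)
  alpha <- pmax(alpha, 1e-8)
  names(alpha) <- gene_ids(cm)
  attr(alpha, "trend") <- c(a0 = a0, a1 = a1)
  attr(alpha, "genewise") <- genewise
  alpha
}

# Vectorized IRLS for per-gene NB log-linear models with fixed dispersion.
# Y: G x n counts; X: n x p design; offset: length-n log offsets;
# alpha: length-G dispersions. Returns coefficients, SEs for column `coef`,
# and convergence flags. The linear predictor is clipped to +-30 to survive
# separation (a group with all-zero counts); such genes end with huge SEs.
.nb_irls <- function(Y, X, offset, alpha, coef = 2L, maxit = 50L, tol = 1e-8) {
  G <- nrow(Y); n <- ncol(Y); p <- ncol(X)
  stopifnot(length(offset) == n, length(alpha) == G, p >= 1)
  offm <- matrix(offset, G, n, byrow = TRUE)
  norm0 <- pmax(rowMeans(sweep(Y, 2, exp(offset), "/")), 1e-8)
  Beta <- matrix(0, G, p)
  Beta[, 1] <- log(norm0)
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  XP <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]
  delta <- rep(Inf, G)
  A <- NULL; Cc <- NULL
  for (it in seq_len(maxit)) {
    Eta <- pmin(pmax(Beta %*% t(X) + offm, -30), 30)
    Mu <- exp(Eta)
    W <- Mu / (1 + Mu * alpha)            # alpha recycles down columns (per gene)
    Z <- (Eta - offm) + (Y - Mu) / Mu
    A <- W %*% XP                          # G x p(p+1)/2 : X'WX entries
    Cc <- (W * Z) %*% X                    # G x p        : X'Wz
    if (p == 2L) {
      a <- A[, 1]; b <- A[, 2]; d <- A[, 3]
      det <- a * d - b * b
      det[det <= 1e-300] <- NA
      New <- cbind((d * Cc[, 1] - b * Cc[, 2]) / det,
                   (a * Cc[, 2] - b * Cc[, 1]) / det)
    } else {
      New <- Beta
      M <- matrix(0, p, p)
      ij <- cbind(pairs[, 1], pairs[, 2])
      for (g in seq_len(G)) {
        M[ij] <- A[g, ]
        M[ij[, 2:1, drop = FALSE]] <- A[g, ]
        bg <- tryCatch(solve(M, Cc[g, ]), error = function(e) rep(NA_real_, p))
        New[g, ] <- bg
      }
    }
    bad <- !stats::complete.cases(New)
    New[bad, ] <- Beta[bad, , drop = FALSE]
    delta <- apply(abs(New - Beta), 1, max)
    delta[bad] <- Inf
    Beta <- New
    if (max(delta) < tol) break
  }
  # SE of requested coefficient from the final X'WX
  se <- rep(NA_real_, G)
  if (p == 2L) {
    a <- A[, 1]; b <- A[, 2]; d <- A[, 3]
    det <- a * d - b * b
    v <- (if (coef == 2L) a else d) / det
    v[det <= 0 | v <= 0] <- NA
    se <- sqrt(v)
  } else {
    M <- matrix(0, p, p)
    ij <- cbind(pairs[, 1], pairs[, 2])
    for (g in seq_len(G)) {
      M[ij] <- A[g, ]
      M[ij[, 2:1, drop = FALSE]] <- A[g, ]
      inv <- tryCatch(solve(M), error = function(e) NULL)
      if (!is.null(inv) && inv[coef, coef] > 0) se[g] <- sqrt(inv[coef, coef])
    }
  }
  list(beta = Beta, se = se, converged = is.finite(delta) & delta < 1e-4)
}

#' Negative-binomial Wald test between two populations
#'
#' Fits, per gene, a log-linear negative-binomial model of counts on a
#' population indicator (optionally plus patient indicators for paired
#' samples), with log size factors as offsets and dispersions held fixed at
#' the [estimate_dispersions()] values. The Wald statistic is the population
#' coefficient over its standard error with a two-sided normal p-value;
#' p-values are BH-adjusted across all converged genes. A gene is flagged as
#' differentially expressed (`is_deg`) when `|log2fc| > lfc_threshold` and
#' `padj < padj_threshold` (defaults 2 and 0.05).
#'
#' Simplifications relative to full-featured DE packages, by design: no
#' Cox-Reid dispersion likelihood, no independent filtering, no outlier
#' (Cook's distance) handling, no fold-change shrinkage. Genes with all-zero
#' counts in both populations are reported with `NA` statistics; genes whose
#' IRLS did not converge are excluded from the BH universe.
#'
#' @param cm a [count_matrix()] (zero-only genes should be removed first).
#' @param sheet sample sheet with `population` (and `patient` if
#'   `include_patient`).
#' @param contrast character vector `c(A, B)`: positive log2 fold change
#'   means higher expression in population `A`.
#' @param include_patient include patient indicators (paired design).
#' @param dispersions optional precomputed dispersions (named per gene);
#'   computed from `cm`/`sheet` across all populations when missing.
#' @param sf optional size factors for all samples of `cm`.
#' @param lfc_threshold,padj_threshold the DEG rule thresholds.
#' @return a data.frame of class `de_result` with columns `gene_id`,
#'   `base_mean`, `log2fc`, `se_log2fc`, `stat`, `wald_p`, `padj`, `is_deg`,
#'   `converged`; attribute `contrast` stores the populations compared and
#'   `n_tested` the BH universe size.
#' @export
nb_wald_test <- function(cm, sheet, contrast, include_patient = FALSE,
                         dispersions = NULL, sf = NULL,
                         lfc_threshold = 2, padj_threshold = 0.05) {
  stopifnot(inherits(cm, "count_matrix"), length(contrast) == 2)
  sheet <- .check_sheet(sheet, cm)
  if (!all(contrast %in% sheet$population))
    stop("contrast population(s) not present: ",
         paste(setdiff(contrast, sheet$population), collapse = ", "))
  keep <- sheet$population %in% contrast
  if (sum(sheet$population == contrast[1]) < 2 ||
      sum(sheet$population == contrast[2]) < 2)
    stop("each contrast population needs >= 2 samples")
  if (is.null(sf)) sf <- size_factors(cm)
  if (is.null(dispersions)) dispersions <- estimate_dispersions(cm, sheet, sf = sf)
  sub <- sheet[keep, , drop = FALSE]
  j <- match(sub$sample_id, sample_ids(cm))
  Y <- cm$counts[, j, drop = FALSE]
  off <- log(sf[j])

  X <- cbind(1, as.numeric(sub$population == contrast[1]))
  colnames(X) <- c("(Intercept)", paste0("pop", contrast[1]))
  if (include_patient) {
    pat <- factor(sub$patient)
    if (nlevels(pat) >= 2) {
      P <- stats::model.matrix(~pat)[, -1, drop = FALSE]
      Xfull <- cbind(X, P)
      qrX <- qr(Xfull)
      if (qrX$rank < ncol(Xfull)) {
        aliased <- colnames(Xfull)[qrX$pivot[-seq_len(qrX$rank)]]
        stop("design is rank deficient; aliased column(s): ",
             paste(aliased, collapse = ", "))
      }
      X <- Xfull
    }
  }

  testable <- rowSums(Y) > 0
  alpha <- if (!is.null(names(dispersions))) dispersions[gene_ids(cm)]
           else dispersions
  if (length(alpha) != nrow(cm$counts) || anyNA(alpha))
    stop("dispersions must cover every gene of the count matrix")
  res <- data.frame(gene_id = gene_ids(cm),
                    base_mean = rowMeans(sweep(Y, 2, exp(off), "/")),
                    log2fc = NA_real_, se_log2fc = NA_real_,
                    stat = NA_real_, wald_p = NA_real_, padj = NA_real_,
                    is_deg = FALSE, converged = NA,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(testable)) {
    fit <- .nb_irls(Y[testable, , drop = FALSE], X, off,
                    alpha[testable], coef = 2L)
    b <- fit$beta[, 2]
    se <- fit$se
    res$log2fc[testable] <- b / log(2)
    res$se_log2fc[testable] <- se / log(2)
    stat <- b / se
    res$stat[testable] <- stat
    p <- 2 * stats::pnorm(-abs(stat))
    p[!fit$converged] <- NA
    res$wald_p[testable] <- p
    res$converged[testable] <- fit$converged
  }
  res$padj <- bh_adjust(res$wald_p)
  res$is_deg <- !is.na(res$padj) & res$padj < padj_threshold &
    abs(res$log2fc) > lfc_threshold
  attr(res, "contrast") <- contrast
  attr(res, "n_tested") <- sum(!is.na(res$wald_p))
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("de_result: %s vs %s, %d genes (%d tested), %d DEGs\n",
              ct[1], ct[2], nrow(x), attr(x, "n_tested"), sum(x$is_deg)))
  NextMethod()
}

#' @export
summary.de_result <- function(object, ...) {
  ct <- attr(object, "contrast")
  up <- sum(object$is_deg & object$log2fc > 0)
  dn <- sum(object$is_deg & object$log2fc < 0)
  cat(sprintf("Contrast %s vs %s\n", ct[1], ct[2]))
  cat(sprintf("  genes: %d; tested: %d; non-converged: %d\n",
              nrow(object), attr(object, "n_tested"),
              sum(!object$converged, na.rm = TRUE)))
  cat(sprintf("  DEGs: %d up in %s, %d down\n", up, ct[1], dn))
  invisible(data.frame(up = up, down = dn,
                       tested = attr(object, "n_tested")))
}
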