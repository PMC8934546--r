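#' Describe a multi-population RNA-seq simulation
#'
#' Defines the generative model used for validation: per-gene negative-binomial
#' counts with mean \eqn{s_i \cdot 2^{\beta_g + \tau_{g,pop} + b_{g,patient}}}
#' and dispersion \eqn{\alpha_g} (variance \eqn{\mu + \alpha\mu^2}).
#' \eqn{\beta_g} is a log2 baseline drawn uniformly from
#' `baseline_log2_range`, \eqn{\tau} carries planted population-specific log2
#' fold changes, \eqn{b} is a per-gene patient (batch) shift shared by all of
#' that patient's samples and centred across patients (a grand-mean patient
#' shift is not identifiable and is absorbed into the baseline), and
#' \eqn{s_i} is a log-normal library-size factor. Dispersions follow the bulk
#' mean-dispersion trend \eqn{\alpha_g = a_0 + a_1/\mu_g} evaluated at the
#' gene's baseline mean. Feature lengths are drawn log-uniformly so that TPM
#' and raw-count rankings differ.
#'
#' @param n_genes number of genes.
#' @param populations named integer vector: samples per population.
#' @param baseline_log2_range range of the uniform log2 baseline means.
#' @param dispersion `c(a0, a1)` of the mean-dispersion trend.
#' @param libsize_sigma sd (log scale) of the log-normal library-size factors.
#' @param batch_sd sd (log2 scale) of patient shifts before centring.
#' @param markers optional data.frame with columns `gene`, `population`,
#'   `log2fc`: planted population-specific genes. Each gene may target exactly
#'   one population.
#' @param contamination optional data.frame with columns `sample`,
#'   `population`, `fraction` (in \[0, 1)): the sample's mean vector is
#'   replaced by `(1 - f) * own + f * admixer` before sampling.
#' @param length_range range (bp) of the log-uniform feature lengths.
#' @param seed integer seed; a fixed seed yields bit-identical output.
#' @return an object of class `simulation_design` (a list of the above).
#' @seealso [simulate_counts()], [default_design()]
#' @export
simulation_design <- function(n_genes = 2000,
                              populations = c(hyalocyte = 5, rMG = 6,
                                              cMono = 6, iMono = 6, ncMono = 6),
                              baseline_log2_range = c(1, 11),
                              dispersion = c(a0 = 0.05, a1 = 5),
                              libsize_sigma = 0.3,
                              batch_sd = 0.25,
                              markers = NULL,
                              contamination = NULL,
                              length_range = c(300, 10000),
                              seed = 0L) {
  stopifnot(n_genes >= 2, length(populations) >= 1, all(populations >= 1),
            length(baseline_log2_range) == 2, length(dispersion) == 2,
            libsize_sigma >= 0, batch_sd >= 0)
  if (is.null(names(populations)))
    names(populations) <- paste0("pop", seq_along(populations))
  if (!is.null(markers)) {
    stopifnot(all(c("gene", "population", "log2fc") %in% names(markers)))
    if (nrow(markers) > n_genes)
      stop("more planted markers than genes")
    if (anyDuplicated(markers$gene))
      stop("each planted gene must target exactly one population")
    if (!all(markers$population %in% names(populations)))
      stop("planted marker targets unknown population")
    if (any(!is.finite(markers$log2fc)))
      stop("planted fold changes must be finite")
  }
  if (!is.null(contamination)) {
    stopifnot(all(c("sample", "population", "fraction") %in% names(contamination)))
    if (any(contamination$fraction < 0 | contamination$fraction >= 1))
      stop("contamination fractions must lie in [0, 1)")
  }
  structure(list(n_genes = as.integer(n_genes), populations = populations,
                 baseline_log2_range = baseline_log2_range,
                 dispersion = stats::setNames(as.numeric(dispersion), c("a0", "a1")),
                 libsize_sigma = libsize_sigma, batch_sd = batch_sd,
                 markers = markers, contamination = contamination,
                 length_range = length_range, seed = as.integer(seed)),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf("simulation_design: %d genes, %d populations (%s), %d samples\n",
              x$n_genes, length(x$populations),
              paste(names(x$populations), collapse = ", "),
              sum(x$populations)))
  cat(sprintf("  planted markers: %d; contaminated samples: %d; seed %d\n",
              if (is.null(x$markers)) 0L else nrow(x$markers),
              if (is.null(x$contamination)) 0L else nrow(x$contamination),
              x$seed))
  invisible(x)
}

#' Default study-shaped simulation design
#'
#' A scaled surrogate for a five-population FACS-sorted immune cell study:
#' hyalocytes (5 samples), retinal microglia and three monocyte subsets (6
#' samples each; 29 samples in total, at most 30), patient labels shared
#' across populations so that donors nest samples, and 2,000 genes. This is a
#' desk-scale stand-in for such a study design, not a reproduction of any real
#' dataset.
#'
#' @param n_markers number of marker genes planted for `focal`.
#' @param marker_log2fc planted log2 fold change of those markers.
#' @param focal population receiving the planted markers.
#' @param seed integer seed (default 0 gives a reproducible fixture).
#' @param ... further arguments passed to [simulation_design()].
#' @return a [simulation_design()].
#' @export
default_design <- function(n_markers = 0, marker_log2fc = 8,
                           focal = "hyalocyte", seed = 0L, ...) {
  pops <- c(hyalocyte = 5L, rMG = 6L, cMono = 6L, iMono = 6L, ncMono = 6L)
  markers <- NULL
  if (n_markers > 0)
    markers <- data.frame(gene = sprintf("gene%04d", seq_len(n_markers)),
                          population = focal, log2fc = marker_log2fc,
                          stringsAsFactors = FALSE)
  simulation_design(n_genes = 2000, populations = pops, markers = markers,
                    seed = seed, ...)
}

#' Add planted marker genes to a design
#'
#' Convenience helper to plant `n` population-specific genes (chosen among
#' genes not yet planted) at a fixed log2 fold change.
#'
#' @param design a [simulation_design()].
#' @param population target population.
#' @param n number of genes to plant.
#' @param log2fc planted log2 fold change.
#' @return the updated design.
#' @export
plant_markers <- function(design, population, n, log2fc) {
  stopifnot(inherits(design, "simulation_design"))
  all_genes <- sprintf("gene%04d", seq_len(design$n_genes))
  used <- if (is.null(design$markers)) character() else design$markers$gene
  free <- setdiff(all_genes, used)
  if (length(free) < n) stop("more planted markers than genes")
  add <- data.frame(gene = free[seq_len(n)], population = population,
                    log2fc = log2fc, stringsAsFactors = FALSE)
  design$markers <- rbind(design$markers, add)
  simulation_design(n_genes = design$n_genes, populations = design$populations,
                    baseline_log2_range = design$baseline_log2_range,
                    dispersion = design$dispersion,
                    libsize_sigma = design$libsize_sigma,
                    batch_sd = design$batch_sd, markers = design$markers,
                    contamination = design$contamination,
                    length_range = design$length_range, seed = design$seed)
}

#' Simulate counts, sample sheet and ground truth from a design
#'
#' Draws negative-binomial counts under the model described in
#' [simulation_design()]. Patient labels are assigned within each population
#' in order (`P1`, `P2`, ...), so populations with equal sample counts share
#' donors, mirroring a paired design. Contaminated samples have their mean
#' vector mixed with the admixing population's mean vector (same patient and
#' library size) before sampling.
#'
#' @param design a [simulation_design()].
#' @param seed optional seed overriding `design$seed`.
#' @return a list with elements `counts` (a [count_matrix()]), `sheet`
#'   (sample sheet data.frame) and `truth` (list: `log2fc` genes x populations
#'   matrix of true planted effects, `markers`, `contamination` named
#'   per-sample fractions, `baseline_log2`, `patient_effects`,
#'   `library_size`).
#' @export
simulate_counts <- function(design, seed = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(if (is.null(seed)) design$seed else seed)
  G <- design$n_genes
  pops <- design$populations
  genes <- sprintf("gene%04d", seq_len(G))

  pop_of <- rep(names(pops), pops)
  pat_of <- unlist(lapply(pops, function(k) paste0("P", seq_len(k))),
                   use.names = FALSE)
  sid <- paste0(pop_of, "_", pat_of)
  n <- length(sid)
  patients <- sort(unique(pat_of))

  # donor-level covariates (plausible for an adult surgical cohort)
  pat_age <- stats::setNames(round(stats::rnorm(length(patients), 70, 15)),
                             patients)
  pat_sex <- stats::setNames(sample(c("F", "M"), length(patients),
                                    replace = TRUE), patients)
  sheet <- data.frame(sample_id = sid, population = pop_of, patient = pat_of,
                      age = unname(pat_age[pat_of]),
                      sex = unname(pat_sex[pat_of]),
                      stringsAsFactors = FALSE)

  beta <- stats::runif(G, design$baseline_log2_range[1],
                       design$baseline_log2_range[2])
  lens <- exp(stats::runif(G, log(design$length_range[1]),
                           log(design$length_range[2])))

  tau <- matrix(0, G, length(pops), dimnames = list(genes, names(pops)))
  if (!is.null(design$markers)) {
    idx <- match(design$markers$gene, genes)
    if (any(is.na(idx))) stop("planted marker gene not in gene universe")
    tau[cbind(idx, match(design$markers$population, names(pops)))] <-
      design$markers$log2fc
  }

  b <- matrix(stats::rnorm(G * length(patients), 0, design$batch_sd),
              G, length(patients), dimnames = list(genes, patients))
  if (design$batch_sd > 0) b <- b - rowMeans(b)

  s <- stats::rlnorm(n, 0, design$libsize_sigma)

  mu0 <- 2^(beta + tau[, pop_of, drop = FALSE] + b[, pat_of, drop = FALSE])
  colnames(mu0) <- sid

  cont <- stats::setNames(numeric(n), sid)
  if (!is.null(design$contamination)) {
    for (k in seq_len(nrow(design$contamination))) {
      cs <- design$contamination$sample[k]
      cp <- design$contamination$population[k]
      f <- design$contamination$fraction[k]
      j <- match(cs, sid)
      if (is.na(j)) stop("contamination names unknown sample: ", cs)
      admix <- 2^(beta + tau[, cp] + b[, pat_of[j]])
      mu0[, j] <- (1 - f) * mu0[, j] + f * admix
      cont[j] <- f
    }
  }

  mu <- sweep(mu0, 2, s, "*")
  alpha <- design$dispersion["a0"] + design$dispersion["a1"] / (2^beta)
  counts <- matrix(stats::rnbinom(G * n, mu = mu, size = rep(1 / alpha, n)),
                   G, n, dimnames = list(genes, sid))

  truth <- list(log2fc = tau,
                markers = design$markers,
                contamination = cont,
                baseline_log2 = stats::setNames(beta, genes),
                patient_effects = b,
                library_size = stats::setNames(s, sid))
  list(counts = count_matrix(counts, round(lens)), sheet = sheet, truth = truth)
}
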