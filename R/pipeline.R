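#' Pipeline configuration
#'
#' Collects everything one end-to-end run needs: either file paths
#' (`counts`, `samples`, optionally `panels` GMT and `gene_sets` GMT) or a
#' [simulation_design()] to generate inputs; the focal population; the DEG
#' thresholds; the quantile-gap levels; `top_k`; and the seed. The
#' configuration round-trips through YAML via [read_pipeline_config()] /
#' [write_pipeline_config()].
#'
#' @param focal focal population label.
#' @param counts,samples,panels,gene_sets optional input file paths (counts
#'   TSV, sample sheet TSV, marker-panel GMT, gene-set GMT for ORA).
#' @param design optional [simulation_design()] used when no count file is
#'   given.
#' @param lfc_threshold,padj_threshold DEG rule thresholds (defaults 2, 0.05).
#' @param q_gap quantile-gap levels (default `c(0.10, 0.90)`).
#' @param top_k number of markers to report (default 10).
#' @param paired `"auto"` (patient term included when the two populations
#'   share at least two patient labels), `TRUE` or `FALSE`.
#' @param seed integer seed for the simulated branch.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(focal = "hyalocyte", counts = NULL, samples = NULL,
                            panels = NULL, gene_sets = NULL, design = NULL,
                            lfc_threshold = 2, padj_threshold = 0.05,
                            q_gap = c(0.10, 0.90), top_k = 10,
                            paired = "auto", seed = 0L) {
  stopifnot(lfc_threshold > 0, padj_threshold > 0, top_k >= 1,
            length(q_gap) == 2, q_gap[1] < q_gap[2])
  if (is.null(counts) && is.null(design))
    design <- default_design(n_markers = 0, seed = seed)
  structure(list(focal = focal, counts = counts, samples = samples,
                 panels = panels, gene_sets = gene_sets, design = design,
                 lfc_threshold = lfc_threshold,
                 padj_threshold = padj_threshold, q_gap = q_gap,
                 top_k = as.integer(top_k), paired = paired,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()] returns a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- NULL
  if (!is.null(y$design)) {
    d <- y$design
    design <- simulation_design(
      n_genes = d$n_genes,
      populations = unlist(d$populations),
      baseline_log2_range = as.numeric(d$baseline_log2_range),
      dispersion = as.numeric(d$dispersion),
      libsize_sigma = d$libsize_sigma, batch_sd = d$batch_sd,
      markers = if (!is.null(d$markers)) as.data.frame(d$markers) else NULL,
      contamination = if (!is.null(d$contamination))
        as.data.frame(d$contamination) else NULL,
      length_range = as.numeric(d$length_range), seed = d$seed)
  }
  pipeline_config(focal = y$focal, counts = y$counts, samples = y$samples,
                  panels = y$panels, gene_sets = y$gene_sets, design = design,
                  lfc_threshold = y$lfc_threshold,
                  padj_threshold = y$padj_threshold,
                  q_gap = as.numeric(y$q_gap), top_k = y$top_k,
                  paired = y$paired, seed = y$seed)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  if (!is.null(y$design)) {
    d <- unclass(y$design)
    d$populations <- as.list(d$populations)
    d$dispersion <- as.numeric(d$dispersion)
    if (!is.null(d$markers)) d$markers <- as.list(d$markers)
    if (!is.null(d$contamination)) d$contamination <- as.list(d$contamination)
    y$design <- d
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

# stable hash of the configuration (md5 of its serialized YAML)
.config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_pipeline_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline
#'
#' Executes the complete analysis: load or simulate counts, drop all-zero
#' genes, normalize (size factors + TPM), QC (when marker panels are
#' available), differential expression of the focal population versus every
#' other population (patient-paired where donors are shared), percentile-rank
#' similarity versus the focal population, two-step marker discovery, and ORA
#' of the marker candidates (when gene sets are supplied). Every stage's
#' table is written to `out_dir` and a machine-readable JSON run summary is
#' produced. Deterministic for a fixed configuration.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return the run summary, invisibly (also written to
#'   `out_dir/summary.json`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("popmarkers_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  res <- tryCatch({
    truth <- NULL
    if (!is.null(config$counts)) {
      cm <- read_counts(config$counts)
      sheet <- read_sample_sheet(config$samples)
    } else {
      sim <- simulate_counts(config$design, seed = config$seed)
      cm <- sim$counts
      sheet <- sim$sheet
      truth <- sim$truth
      write_counts(cm, file.path(out_dir, "counts.tsv"))
      write_sample_sheet(sheet, file.path(out_dir, "samples.tsv"))
    }
    n_input <- nrow(cm)

    stage <- "filter"
    cm <- drop_all_zero_genes(cm)
    removed <- attr(cm, "removed_genes")

    stage <- "normalize"
    sf <- size_factors(cm)
    nm <- normalize_counts(cm, sf)
    tp <- tpm(cm)
    write_results(data.frame(gene_id = gene_ids(cm), tp$values,
                             check.names = FALSE),
                  file.path(out_dir, "tpm.tsv"))

    stage <- "qc"
    qc <- NULL
    panels <- NULL
    if (!is.null(config$panels)) {
      panels <- read_gmt(config$panels)
    } else if (!is.null(truth$markers) && nrow(truth$markers) > 0) {
      panels <- split(truth$markers$gene, truth$markers$population)
    }
    if (!is.null(panels) && length(panels) >= 2) {
      qc <- qc_samples(nm, sheet, panels)
      write_results(qc$flags, file.path(out_dir, "qc_flags.tsv"))
    }

    stage <- "diffexp"
    pops <- setdiff(unique(sheet$population), config$focal)
    disp <- estimate_dispersions(cm, sheet, sf = sf)
    de <- list()
    for (p in pops) {
      shared <- intersect(sheet$patient[sheet$population == config$focal],
                          sheet$patient[sheet$population == p])
      paired <- if (identical(config$paired, "auto"))
        ("patient" %in% names(sheet)) && length(shared) >= 2
      else isTRUE(config$paired)
      de[[p]] <- nb_wald_test(cm, sheet, c(config$focal, p),
                              include_patient = paired,
                              dispersions = disp, sf = sf,
                              lfc_threshold = config$lfc_threshold,
                              padj_threshold = config$padj_threshold)
      write_results(as.data.frame(de[[p]]),
                    file.path(out_dir, paste0("de_", config$focal, "_vs_",
                                              p, ".tsv")))
    }

    stage <- "similarity"
    pf <- percentile_profile(nm, sheet, config$focal)
    sim_r2 <- sapply(pops, function(p) {
      pairwise_similarity(pf, percentile_profile(nm, sheet, p))$r_squared
    })
    write_results(data.frame(population = pops, r_squared = sim_r2),
                  file.path(out_dir, "similarity.tsv"))

    stage <- "markers"
    mk <- find_markers(nm, sheet, config$focal, de, top_k = config$top_k,
                       lfc_threshold = config$lfc_threshold,
                       padj_threshold = config$padj_threshold,
                       q_gap = config$q_gap)
    if (nrow(mk$table))
      write_results(mk$table, file.path(out_dir, "markers.tsv"))

    stage <- "ora"
    ora_res <- NULL
    if (!is.null(config$gene_sets) && length(mk$markers) >= 1) {
      sets <- read_gmt(config$gene_sets)
      ora_res <- ora(mk$markers, sets, universe = gene_ids(cm))
      write_results(as.data.frame(ora_res), file.path(out_dir, "ora.tsv"))
    }

    stage <- "summary"
    deg_tally <- lapply(de, function(d)
      list(up = sum(d$is_deg & d$log2fc > 0),
           down = sum(d$is_deg & d$log2fc < 0),
           tested = attr(d, "n_tested")))
    summary <- list(
      package_version = as.character(utils::packageVersion("popmarkers")),
      config_hash = .config_hash(config),
      focal = config$focal,
      populations = unique(sheet$population),
      n_samples = nrow(sheet),
      genes_input = n_input,
      genes_zero_removed = length(removed),
      genes_analyzed = nrow(cm),
      degs = deg_tally,
      similarity_r2 = as.list(sim_r2),
      markers = mk$markers,
      qc_flagged = if (is.null(qc)) character() else
        names(qc$flagged)[qc$flagged],
      ora_top = if (is.null(ora_res)) NULL else
        utils::head(ora_res$set, 5))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    summary
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
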