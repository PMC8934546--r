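# QC simulation used across tests: five populations, each with a planted
# 40-gene marker panel at log2FC 6 (typical magnitudes for sorted-cell
# marker panels), optional admixture of one rMG sample with cMono profile.
qc_design <- function(f = 0, seed = 0, n_genes = 600) {
  d <- simulation_design(n_genes = n_genes,
                         populations = c(hyalocyte = 6, rMG = 6, cMono = 6,
                                         iMono = 6, ncMono = 6),
                         seed = seed)
  for (p in names(d$populations)) d <- plant_markers(d, p, 40, 6)
  if (f > 0) {
    d <- simulation_design(n_genes = n_genes, populations = d$populations,
                           markers = d$markers,
                           contamination = data.frame(sample = "rMG_P2",
                                                      population = "cMono",
                                                      fraction = f),
                           seed = seed)
  }
  d
}

qc_panels <- function(d) split(d$markers$gene, d$markers$population)

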