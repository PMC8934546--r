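# build a fake DE result list for constructed marker fixtures
fake_de <- function(genes, lfc, padj, pops = names(lfc)) {
  out <- lapply(pops, function(p) {
    d <- data.frame(gene_id = genes, log2fc = lfc[[p]], padj = padj[[p]],
                    stringsAsFactors = FALSE)
    d
  })
  names(out) <- pops
  out
}

test_that("sample_quantile is the type-7 interpolation estimator", {
  expect_equal(sample_quantile(c(1, 2, 3, 4, 5), 0.5), 3)
  expect_equal(sample_quantile(c(10, 20), 0.9), 19)
  x <- c(4, 8, 1, 9, 2)
  expect_equal(sample_quantile(x, 0), min(x))
  expect_equal(sample_quantile(x, 1), max(x))
  expect_error(sample_quantile(numeric(0), 0.5), "empty")
  expect_error(sample_quantile(1:3, 1.5), "\\[0, 1\\]")

  set.seed(55)
  for (i in 1:200) {
    v <- rnorm(sample(2:30, 1))
    q <- runif(1)
    expect_equal(sample_quantile(v, q), quantile_oracle(v, q))
  }
})

test_that("the two-step marker filter applies DE and quantile-gap rules", {
  pops <- c("B", "C")
  genes <- c("m1", "m2", "m3")
  # m1: clean focal marker; m2: also high in B; m3: DE-pass but overlapping
  v <- rbind(m1 = c(20, 25, 30, 0, 0, 0, 1, 0, 1),
             m2 = c(20, 25, 30, 18, 22, 25, 0, 1, 0),
             m3 = c(10, 12, 14, 15, 2, 3, 1, 2, 1))
  colnames(v) <- paste0("s", 1:9)
  sheet <- data.frame(sample_id = colnames(v),
                      population = rep(c("A", "B", "C"), each = 3),
                      stringsAsFactors = FALSE)
  de <- fake_de(genes,
                lfc = list(B = c(8, 0.1, 3), C = c(8, 7, 3)),
                padj = list(B = c(1e-6, 0.9, 1e-4), C = c(1e-6, 1e-6, 1e-4)))
  expect_warning(rep_ <- find_markers(v, sheet, "A", de, top_k = 3),
                 "pass both steps")
  expect_equal(rep_$markers, "m1")
  tab <- rep_$table
  expect_false(tab$passes_de_vs_all[tab$gene_id == "m2"])  # fails step 1 vs B
  expect_true(tab$passes_de_vs_all[tab$gene_id == "m3"])
  expect_false(tab$passes_quantile_gap[tab$gene_id == "m3"]) # p10 < p90 other
  # specificity sign matches the gap rule
  expect_equal(tab$passes_quantile_gap, tab$specificity > 0)
  # planted zero-vs-high gene: p90_other = max of per-population p90s
  expect_equal(tab$p10_focal[tab$gene_id == "m1"],
               sample_quantile(c(20, 25, 30), 0.1))
})

test_that("marker discovery is invariant to relabeling non-focal populations", {
  d <- default_design(n_markers = 10, seed = 6)
  sim <- simulate_counts(d)
  cm <- drop_all_zero_genes(sim$counts)
  sf <- size_factors(cm)
  nm <- normalize_counts(cm, sf)
  disp <- estimate_dispersions(cm, sim$sheet, sf = sf)
  pops <- setdiff(names(d$populations), "hyalocyte")
  de <- lapply(pops, function(p)
    nb_wald_test(cm, sim$sheet, c("hyalocyte", p), dispersions = disp, sf = sf))
  names(de) <- pops
  mk <- find_markers(nm, sim$sheet, "hyalocyte", de, top_k = 10)

  relab <- setNames(paste0("pop_", seq_along(pops)), pops)
  sheet2 <- sim$sheet
  sheet2$population <- ifelse(sheet2$population == "hyalocyte", "hyalocyte",
                              relab[sheet2$population])
  de2 <- de
  names(de2) <- relab[names(de)]
  mk2 <- find_markers(nm, sheet2, "hyalocyte", de2, top_k = 10)
  expect_equal(mk2$markers, mk$markers)
  expect_equal(mk2$table$specificity, mk$table$specificity)

  expect_error(find_markers(nm, sim$sheet, "hyalocyte", de[1:3], top_k = 5),
               "missing DE contrast")
})

test_that("specificity rank never worsens as the planted fold change grows", {
  ranks <- sapply(c(3, 5, 8), function(fc) {
    d <- simulation_design(n_genes = 300,
                           populations = c(A = 5, B = 5, C = 5),
                           baseline_log2_range = c(5, 9), batch_sd = 0,
                           markers = data.frame(gene = "gene0050",
                                                population = "A",
                                                log2fc = fc),
                           seed = 91)
    sim <- simulate_counts(d)
    cm <- drop_all_zero_genes(sim$counts)
    sf <- size_factors(cm)
    nm <- normalize_counts(cm, sf)
    disp <- estimate_dispersions(cm, sim$sheet, sf = sf)
    de <- lapply(c("B", "C"), function(p)
      nb_wald_test(cm, sim$sheet, c("A", p), dispersions = disp, sf = sf))
    names(de) <- c("B", "C")
    mk <- suppressWarnings(find_markers(nm, sim$sheet, "A", de, top_k = 20))
    r <- mk$table$rank[mk$table$gene_id == "gene0050"]
    if (length(r) == 0 || is.na(r)) Inf else r
  })
  expect_true(all(diff(ranks) <= 0))
  expect_equal(ranks[3], 1)
})

test_that("panel scoring separates populations and degrades under shuffling", {
  d <- simulation_design(n_genes = 400, populations = c(A = 6, B = 6),
                         batch_sd = 0, seed = 14)
  d <- plant_markers(d, "A", n = 10, log2fc = 6)
  sim <- simulate_counts(d)
  nm <- normalize_counts(drop_all_zero_genes(sim$counts))
  lv <- log2(nm$values + 1)
  panel <- d$markers$gene
  sp <- score_panel(lv, sim$sheet, panel, "A")
  expect_equal(sp$purity, 1)
  expect_true(all(sp$score[sim$sheet$population == "A"] >
                    max(sp$score[sim$sheet$population == "B"])))

  # shuffled labels: expected purity about 0.5 for balanced groups
  set.seed(33)
  purities <- replicate(40, {
    sh <- sim$sheet
    sh$population <- sample(sh$population)
    score_panel(lv, sh, panel, "A")$purity
  })
  expect_gt(mean(purities), 0.35)
  expect_lt(mean(purities), 0.65)

  # constant genes are dropped with a warning
  lv2 <- lv
  lv2[panel[1], ] <- 5
  expect_warning(sp2 <- score_panel(lv2, sim$sheet, panel, "A"),
                 "constant panel gene")
  expect_equal(sp2$dropped, panel[1])
  # absent genes are reported
  sp3 <- score_panel(lv, sim$sheet, c(panel, "not_a_gene"), "A")
  expect_equal(sp3$missing, "not_a_gene")
  expect_error(score_panel(lv, sim$sheet, c("x", "y"), "A"),
               "fewer than 2")
})
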