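test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1, 0.5)), "\\[0, 1\\]")

  set.seed(101)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
  }
})

test_that("dispersion estimation is calibrated on Poisson and NB data", {
  set.seed(7)
  G <- 500; n <- 12
  sheet <- two_group_sheet(n_per = 6)
  mu <- 2^runif(G, 4, 10)
  # Poisson: true alpha = 0
  Yp <- matrix(rpois(G * n, rep(mu, n)), G, n,
               dimnames = list(paste0("g", 1:G), sheet$sample_id))
  ap <- estimate_dispersions(count_matrix(Yp, 1000), sheet,
                             sf = rep(1, n))
  expect_lt(median(ap), 0.05)

  # NB with uniform alpha = 0.2
  Yn <- matrix(rnbinom(G * n, mu = rep(mu, n), size = 5), G, n,
               dimnames = dimnames(Yp))
  an <- estimate_dispersions(count_matrix(Yn, 1000), sheet,
                             sf = rep(1, n))
  expect_gt(median(an), 0.1)
  expect_lt(median(an), 0.4)

  # constant gene: negative moment estimate handled via the floor/trend
  Yc <- Yn; Yc[1, ] <- 50
  ac <- estimate_dispersions(count_matrix(Yc, 1000), sheet, sf = rep(1, n))
  expect_equal(unname(attr(ac, "genewise")[1]), 0)
  expect_gte(ac[[1]], 1e-8)
  expect_true(all(is.finite(ac)))
})

test_that("Wald log2fc equals the log ratio of normalized group means", {
  set.seed(31)
  G <- 60; n <- 8
  sheet <- two_group_sheet(n_per = 4)
  Y <- matrix(rnbinom(G * n, mu = 200, size = 10) + 1, G, n,
              dimnames = list(paste0("g", 1:G), sheet$sample_id))
  cm <- count_matrix(Y, 500)
  de <- nb_wald_test(cm, sheet, c("A", "B"), sf = rep(1, n),
                     dispersions = rep(0.1, G))
  mA <- rowMeans(Y[, sheet$population == "A"])
  mB <- rowMeans(Y[, sheet$population == "B"])
  expect_equal(de$log2fc, unname(log2(mA / mB)), tolerance = 1e-6)

  # swapping the contrast negates log2fc and keeps p
  sw <- nb_wald_test(cm, sheet, c("B", "A"), sf = rep(1, n),
                     dispersions = rep(0.1, G))
  expect_equal(sw$log2fc, -de$log2fc, tolerance = 1e-8)
  expect_equal(sw$wald_p, de$wald_p, tolerance = 1e-8)
})

test_that("DEG rule and result invariants hold on simulated data", {
  d <- simulation_design(n_genes = 400, populations = c(A = 6, B = 6),
                         batch_sd = 0, seed = 17)
  sim <- simulate_counts(d)
  cm <- drop_all_zero_genes(sim$counts)
  de <- nb_wald_test(cm, sim$sheet, c("A", "B"))
  ok <- !is.na(de$padj)
  expect_true(all(de$padj[ok] >= de$wald_p[ok]))
  expect_true(all(de$wald_p[ok] >= 0 & de$wald_p[ok] <= 1))
  # is_deg requires BOTH conditions: the rule, restated independently
  expect_equal(de$is_deg,
               !is.na(de$padj) & de$padj < 0.05 & abs(de$log2fc) > 2)
  # a significant-but-small fold change is not a DEG, and vice versa
  expect_false(any(de$is_deg & abs(de$log2fc) <= 2))
  expect_false(any(de$is_deg & de$padj >= 0.05))
})

test_that("a planted log2FC=3 marker is detected in nearly all replicates", {
  hits <- 0
  for (r in 1:60) {
    d <- simulation_design(n_genes = 150, populations = c(A = 6, B = 6),
                           baseline_log2_range = c(6, 9), batch_sd = 0,
                           markers = data.frame(gene = "gene0005",
                                                population = "A", log2fc = 3),
                           seed = 400 + r)
    sim <- simulate_counts(d)
    cm <- drop_all_zero_genes(sim$counts)
    de <- nb_wald_test(cm, sim$sheet, c("A", "B"))
    hits <- hits + de$is_deg[de$gene_id == "gene0005"]
  }
  expect_gte(hits / 60, 0.95)
})

test_that("patient-paired designs fit and detect planted effects", {
  d <- simulation_design(n_genes = 200, populations = c(A = 6, B = 6),
                         batch_sd = 0.5,
                         baseline_log2_range = c(5, 9),
                         markers = data.frame(gene = "gene0010",
                                              population = "A", log2fc = 4),
                         seed = 77)
  sim <- simulate_counts(d)
  cm <- drop_all_zero_genes(sim$counts)
  de <- nb_wald_test(cm, sim$sheet, c("A", "B"), include_patient = TRUE)
  expect_true(de$is_deg[de$gene_id == "gene0010"])
  expect_equal(de$log2fc[de$gene_id == "gene0010"], 4, tolerance = 0.2)
  # aliasing guard: population identical to patient split
  bad_sheet <- sim$sheet
  bad_sheet$patient <- bad_sheet$population
  expect_error(nb_wald_test(cm, bad_sheet, c("A", "B"),
                            include_patient = TRUE), "aliased")
})

test_that("contrast populations must exist with enough samples", {
  cm <- tiny_counts(G = 10, n = 6, seed = 1)
  sheet <- two_group_sheet(n_per = 3)
  expect_error(nb_wald_test(cm, sheet, c("A", "C")), "not present")
  sheet2 <- sheet; sheet2$population <- c("A", rep("B", 5))
  expect_error(nb_wald_test(cm, sheet2, c("A", "B")), ">= 2 samples")
})
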