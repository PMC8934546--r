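test_that("simulation is deterministic under a fixed seed", {
  d <- default_design(n_markers = 5, seed = 3)
  a <- simulate_counts(d)
  b <- simulate_counts(d)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$sheet, b$sheet)
  expect_identical(a$truth$log2fc, b$truth$log2fc)
  c2 <- simulate_counts(d, seed = 4)
  expect_false(identical(a$counts$counts, c2$counts$counts))
})

test_that("default design matches the intended study shape", {
  d <- default_design()
  expect_length(d$populations, 5L)
  expect_lte(sum(d$populations), 30L)
  expect_identical(d$seed, 0L)
  sim <- simulate_counts(d)
  expect_equal(nrow(sim$sheet), sum(d$populations))
  # donors are shared across populations (paired design)
  pats <- split(sim$sheet$patient, sim$sheet$population)
  expect_true(length(Reduce(intersect, pats)) >= 5)
})

test_that("null design has no systematic population differences", {
  d <- simulation_design(n_genes = 300, populations = c(A = 30, B = 30),
                         batch_sd = 0, libsize_sigma = 0, seed = 21)
  sim <- simulate_counts(d)
  ma <- rowMeans(sim$counts$counts[, sim$sheet$population == "A"])
  mb <- rowMeans(sim$counts$counts[, sim$sheet$population == "B"])
  lfc <- log2(ma / mb)
  expect_lt(abs(mean(lfc)), 0.1)
  expect_true(all(sim$truth$log2fc == 0))
})

test_that("a planted log2FC is recovered from empirical group means", {
  # oracle: empirical means over 200 simulated samples (100 per group)
  d <- simulation_design(n_genes = 50, populations = c(A = 100, B = 100),
                         batch_sd = 0, libsize_sigma = 0,
                         baseline_log2_range = c(4, 8),
                         markers = data.frame(gene = "gene0007",
                                              population = "A", log2fc = 8),
                         seed = 1)
  sim <- simulate_counts(d)
  ma <- rowMeans(sim$counts$counts[, sim$sheet$population == "A"])
  mb <- rowMeans(sim$counts$counts[, sim$sheet$population == "B"])
  expect_equal(log2(ma["gene0007"] / mb["gene0007"]), 8,
               tolerance = 0.05, ignore_attr = TRUE)
  null_lfc <- log2(ma / mb)[-7]
  expect_lt(max(abs(null_lfc)), 0.5)
})

test_that("simulated counts match negative-binomial moments", {
  d <- simulation_design(n_genes = 20, populations = c(A = 10000),
                         batch_sd = 0, libsize_sigma = 0,
                         baseline_log2_range = c(3, 9), seed = 8)
  sim <- simulate_counts(d)
  mu <- 2^sim$truth$baseline_log2
  alpha <- 0.05 + 5 / mu
  emp_mean <- rowMeans(sim$counts$counts)
  emp_var <- apply(sim$counts$counts, 1, var)
  expected_var <- mu + alpha * mu^2
  expect_equal(unname(emp_mean), unname(mu), tolerance = 0.05)
  ratio <- emp_var / expected_var
  expect_true(all(ratio > 0.85 & ratio < 1.15))
})

test_that("contamination mixes mean vectors: f=0 is a no-op, f near 1 converges", {
  base <- simulation_design(n_genes = 200, populations = c(A = 4, B = 4),
                            batch_sd = 0, libsize_sigma = 0,
                            markers = data.frame(gene = "gene0003",
                                                 population = "B",
                                                 log2fc = 8),
                            seed = 5)
  with0 <- simulation_design(n_genes = 200, populations = c(A = 4, B = 4),
                             batch_sd = 0, libsize_sigma = 0,
                             markers = base$markers,
                             contamination = data.frame(sample = "A_P1",
                                                        population = "B",
                                                        fraction = 0),
                             seed = 5)
  expect_identical(simulate_counts(base)$counts$counts,
                   simulate_counts(with0)$counts$counts)

  near1 <- simulation_design(n_genes = 200, populations = c(A = 4, B = 4),
                             batch_sd = 0, libsize_sigma = 0,
                             markers = base$markers,
                             contamination = data.frame(sample = "A_P1",
                                                        population = "B",
                                                        fraction = 0.99),
                             seed = 5)
  sim <- simulate_counts(near1)
  # the B marker shows up in the contaminated A sample but not in pure ones
  expect_gt(sim$counts$counts["gene0003", "A_P1"],
            50 * max(1, sim$counts$counts["gene0003", "A_P2"]))
  expect_equal(unname(sim$truth$contamination["A_P1"]), 0.99)
})

test_that("invalid designs are rejected", {
  expect_error(simulation_design(n_genes = 2,
                                 markers = data.frame(gene = c("a", "b", "c"),
                                                      population = "hyalocyte",
                                                      log2fc = 2)),
               "more planted markers than genes")
  expect_error(simulation_design(markers = data.frame(gene = c("g", "g"),
                                                      population = "hyalocyte",
                                                      log2fc = 2)),
               "exactly one population")
  expect_error(simulation_design(contamination = data.frame(sample = "x",
                                                            population = "rMG",
                                                            fraction = 1)),
               "\\[0, 1\\)")
})
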