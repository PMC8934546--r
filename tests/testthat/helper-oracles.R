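# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and, where possible, the base
# functions) the package itself uses.

# BH step-up by explicit loops over the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# type-7 quantile by explicit interpolation between order statistics
quantile_oracle <- function(x, q) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * q
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  xs[lo] + (h - floor(h)) * (xs[hi] - xs[lo])
}

# upper-tail hypergeometric by exhaustive enumeration of all n-subsets
ora_oracle <- function(universe, set, gene_list) {
  n <- length(gene_list)
  k <- length(intersect(gene_list, set))
  subs <- utils::combn(length(universe), n)
  inset <- universe %in% set
  hits <- colSums(matrix(inset[subs], nrow = n))
  mean(hits >= k)
}

# percentile profile by pairwise counting (average ranks from first principles)
percentile_oracle <- function(means) {
  G <- length(means)
  sapply(seq_len(G), function(i) {
    less <- sum(means < means[i])
    tied <- sum(means == means[i])
    r <- less + (tied + 1) / 2
    (r - 1) / (G - 1) * 100
  })
}

# median-of-ratios size factors by explicit loops; the median of the ratios
# is taken on the log scale (ties between the two middle order statistics
# average geometrically, the convention of the reference estimator)
size_factor_oracle <- function(counts) {
  geo <- apply(counts, 1, function(x) exp(mean(log(x))))
  use <- apply(counts, 1, function(x) all(x > 0))
  sapply(seq_len(ncol(counts)), function(j) {
    r <- sort(log(counts[use, j] / geo[use]))
    m <- length(r)
    mid <- if (m %% 2 == 1) r[(m + 1) / 2] else (r[m / 2] + r[m / 2 + 1]) / 2
    exp(unname(mid))
  })
}

# small count_matrix fixture with known structure
tiny_counts <- function(G = 6, n = 4, seed = 42, mu = 50) {
  set.seed(seed)
  m <- matrix(rpois(G * n, mu), G, n,
              dimnames = list(paste0("g", seq_len(G)),
                              paste0("s", seq_len(n))))
  count_matrix(m, lengths = sample(300:3000, G))
}

two_group_sheet <- function(n_per = 3, pops = c("A", "B")) {
  data.frame(sample_id = paste0("s", seq_len(n_per * length(pops))),
             population = rep(pops, each = n_per),
             patient = rep(paste0("P", seq_len(n_per)), length(pops)),
             stringsAsFactors = FALSE)
}
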