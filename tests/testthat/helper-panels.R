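# Builders for small random genotype panels used by the oracle tests.

random_pool <- function(name = "P", n_dip = 4, n_sites = 10,
                        miss_prob = 0, chrom = "Chr01") {
  g <- matrix(sample(0:2, n_sites * n_dip, replace = TRUE),
              nrow = n_sites)
  if (miss_prob > 0) {
    g[stats::runif(length(g)) < miss_prob] <- NA
  }
  genotype_pool(name, g, sort(sample(0:999, n_sites)), chrom)
}

whole_interval <- function(len = 1000, chrom = "Chr01") {
  list(chrom = chrom, start = 0, end = len)
}

# One simulated gene as a genotype_pool (n haplotypes -> n/2 diploids).
sim_pool <- function(n_hap = 20, theta = 5, regime = "neutral",
                     len = 2000, name = "P") {
  tr <- apply_regime(simulate_genealogy(n_hap), regime)
  hs <- drop_mutations(tr, theta, length = len)
  genotype_pool(name, pair_diploids(hs), hs$positions)
}

# Literal Tajima constants by direct summation (independent oracle).
oracle_tajima_constants <- function(n) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) {
    a1 <- a1 + 1 / i
    a2 <- a2 + 1 / i^2
  }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}
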