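test_that("Tajima constants match literal summation for many n", {
  expect_equal(tajima_constants(2)$a1, 1.0)
  expect_equal(tajima_constants(4)$a1, 1 + 1 / 2 + 1 / 3)
  for (n in c(4, 5, 10, 23, 40)) {
    got <- tajima_constants(n)
    ora <- oracle_tajima_constants(n)
    for (f in names(ora)) expect_equal(got[[f]], ora[[f]], tolerance = 1e-14)
  }
  expect_error(tajima_constants(1))
})

test_that("segregating sites match a per-column scan on random panels", {
  set.seed(10)
  for (i in 1:100) {
    pool <- random_pool(n_dip = sample(2:6, 1), n_sites = sample(3:20, 1),
                        miss_prob = runif(1, 0, 0.4))
    mm <- runif(1)
    got <- segregating_sites(pool, whole_interval(), mm)
    S <- 0L; nsnp <- 0L
    for (s in seq_len(nrow(pool$genotypes))) {
      g <- pool$genotypes[s, ]
      ok <- !is.na(g)
      if (sum(ok) == 0) next
      j <- sum(g[ok]); m <- 2 * sum(ok)
      if (j > 0 && j < m) {
        S <- S + 1L
        if (mean(!ok) <= mm) nsnp <- nsnp + 1L
      }
    }
    expect_identical(got$S, S)
    expect_identical(got$n_snps, nsnp)
  }
})

test_that("monomorphic and single-site cases behave as defined", {
  g <- matrix(1L, nrow = 3, ncol = 4) # all heterozygous, segregating
  pool <- genotype_pool("P", g, c(1, 5, 9))
  expect_equal(segregating_sites(pool, whole_interval())$S, 3L)

  g2 <- matrix(2L, nrow = 3, ncol = 4) # fixed derived: not segregating
  pool2 <- genotype_pool("P", g2, c(1, 5, 9))
  expect_equal(segregating_sites(pool2, whole_interval())$S, 0L)
  expect_equal(nucleotide_diversity(pool2, whole_interval())$pi_per_bp, 0)

  # one site, genotypes 0/0 and 1/1 -> site pi = 2*2*2/(4*3)
  pool3 <- genotype_pool("P", matrix(c(0L, 2L), 1, 2), 0)
  expect_equal(nucleotide_diversity(pool3, whole_interval(1))$pi_total,
               2 * 2 * 2 / (4 * 3))

  # {0,1,2} at one site: segregating
  pool4 <- genotype_pool("P", matrix(c(0L, 1L, 2L), 1, 3), 7)
  expect_equal(segregating_sites(pool4, whole_interval())$S, 1L)
})

test_that("pi equals brute-force average pairwise difference", {
  set.seed(11)
  for (i in 1:100) {
    pool <- random_pool(n_dip = sample(2:5, 1), n_sites = sample(2:10, 1),
                        miss_prob = if (i %% 3 == 0) 0.2 else 0)
    len <- 500
    got <- nucleotide_diversity(pool, whole_interval(len))
    # oracle: double loop over all allele pairs per site, restricted to
    # the same filtered-SNP site set
    snp <- segregating_sites(pool, whole_interval(len))$snp_index
    tot <- 0
    for (s in snp) {
      g <- pool$genotypes[s, ]
      # expand each diploid call into its two allele copies
      alleles <- unlist(lapply(g[!is.na(g)], function(d) {
        if (d == 0) c(0L, 0L) else if (d == 1) c(0L, 1L) else c(1L, 1L)
      }))
      m <- length(alleles)
      if (m < 2) next
      diff <- 0; npair <- 0
      for (a in 1:(m - 1)) for (b in (a + 1):m) {
        diff <- diff + as.integer(alleles[a] != alleles[b])
        npair <- npair + 1
      }
      tot <- tot + diff / npair
    }
    expect_equal(got$pi_total, tot, tolerance = 1e-10)
    expect_equal(got$pi_per_bp, tot / len, tolerance = 1e-10)
  }
})

test_that("Tajima's D matches an independent literal implementation", {
  set.seed(12)
  for (i in 1:100) {
    pool <- random_pool(n_dip = sample(3:6, 1), n_sites = sample(4:15, 1))
    got <- tajimas_d(pool, whole_interval())
    S <- segregating_sites(pool, whole_interval())$n_snps
    if (S == 0) {
      expect_identical(got$reason, "no_variation")
      next
    }
    n <- 2 * pool$n_diploids
    k <- oracle_tajima_constants(n)
    pi_tot <- 0
    for (s in seq_len(nrow(pool$genotypes))) {
      g <- pool$genotypes[s, ]
      j <- sum(g); m <- 2 * length(g)
      if (j > 0 && j < m) pi_tot <- pi_tot + 2 * j * (m - j) / (m * (m - 1))
    }
    d <- (pi_tot - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
    expect_equal(got$d, d, tolerance = 1e-10)
  }
})

test_that("D is NA with the right reason for degenerate inputs", {
  pool <- genotype_pool("P", matrix(0L, 4, 3), c(1, 5, 9, 12))
  expect_identical(tajimas_d(pool, whole_interval())$reason, "no_variation")
  pool1 <- genotype_pool("solo", matrix(c(0L, 1L), 2, 1), c(1, 5))
  td <- tajimas_d(pool1, whole_interval())
  expect_true(is.na(td$d))
  expect_identical(td$reason, "insufficient_samples")
})

test_that("observed heterozygosity matches brute-force counting", {
  # all diploids 0/1 at one site, gene length L -> 1/L
  pool <- genotype_pool("P", matrix(1L, 1, 5), 3)
  expect_equal(observed_heterozygosity(pool, whole_interval(50))$het_obs_per_bp,
               1 / 50)
  pool0 <- genotype_pool("P", matrix(rep(c(0L, 2L), 4), 2, 4), c(3, 9))
  expect_equal(observed_heterozygosity(pool0, whole_interval(50))$het_obs_per_bp,
               0)
  set.seed(13)
  for (i in 1:50) {
    pool <- random_pool(n_dip = sample(2:6, 1), n_sites = sample(2:12, 1),
                        miss_prob = runif(1, 0, 0.3))
    len <- 300
    got <- observed_heterozygosity(pool, whole_interval(len))
    snp <- segregating_sites(pool, whole_interval(len))$snp_index
    if (length(snp) == 0) next
    nhet <- 0; ncall <- 0
    for (s in snp) for (d in pool$genotypes[s, ]) {
      if (!is.na(d)) {
        ncall <- ncall + 1
        if (d == 1) nhet <- nhet + 1
      }
    }
    expect_equal(got$het_obs_per_bp,
                 (nhet / ncall) * (length(snp) / len), tolerance = 1e-12)
  }
})

test_that("raising max_missing never decreases the SNP count", {
  set.seed(14)
  for (i in 1:20) {
    pool <- random_pool(n_dip = 5, n_sites = 15, miss_prob = 0.3)
    counts <- vapply(seq(0, 1, by = 0.1), function(mm) {
      segregating_sites(pool, whole_interval(), mm)$n_snps
    }, integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("Weir-Cockerham FST matches the literal component oracle", {
  wc_oracle <- function(pools_g) {
    # pools_g: list of genotype vectors (one site), entries 0/1/2
    n_i <- vapply(pools_g, length, numeric(1))
    p_i <- vapply(pools_g, function(g) sum(g) / (2 * length(g)), numeric(1))
    h_i <- vapply(pools_g, function(g) mean(g == 1), numeric(1))
    r <- length(n_i)
    nbar <- sum(n_i) / r
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
           (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
           ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    c(a = a, b = b, c = hbar / 2)
  }
  set.seed(15)
  for (i in 1:100) {
    n_pools <- sample(2:4, 1)
    n_sites <- 5
    pos <- sort(sample(0:99, n_sites))
    pools <- lapply(seq_len(n_pools), function(p) {
      nd <- sample(3:6, 1)
      genotype_pool(paste0("P", p),
                    matrix(sample(0:2, n_sites * nd, replace = TRUE),
                           n_sites), pos)
    })
    got <- fst_multi_pool(pools, whole_interval(100))
    num <- 0; den <- 0
    for (s in seq_len(n_sites)) {
      gs <- lapply(pools, function(p) p$genotypes[s, ])
      tot <- sum(unlist(gs)); m <- 2 * length(unlist(gs))
      if (tot == 0 || tot == m) next
      comp <- wc_oracle(gs)
      num <- num + comp["a"]
      den <- den + sum(comp)
    }
    if (den == 0) {
      expect_true(is.na(got$fst))
    } else {
      expect_equal(got$fst, unname(num / den), tolerance = 1e-10)
    }
  }
})

test_that("FST hits its boundary values", {
  pos <- c(2, 7, 11)
  same <- matrix(sample(0:2, 12, replace = TRUE), 3)
  p1 <- genotype_pool("A", same, pos)
  p2 <- genotype_pool("B", same, pos)
  res <- fst_multi_pool(list(p1, p2), whole_interval(20))
  expect_lte(res$num, 0)
  if (!is.na(res$fst)) expect_lte(res$fst, 0)

  fixed_a <- genotype_pool("A", matrix(0L, 3, 4), pos)
  fixed_b <- genotype_pool("B", matrix(2L, 3, 4), pos)
  expect_equal(fst_multi_pool(list(fixed_a, fixed_b),
                              whole_interval(20))$fst, 1)
  expect_equal(fst_hudson(fixed_a, fixed_b, whole_interval(20))$fst, 1)
})

test_that("Hudson and Weir-Cockerham agree on balanced two-pool panels", {
  set.seed(16)
  for (i in 1:20) {
    pos <- sort(sample(0:99, 8))
    mk <- function(nm) genotype_pool(nm,
      matrix(sample(0:2, 8 * 5, replace = TRUE), 8), pos)
    a <- mk("A"); b <- mk("B")
    wc <- fst_multi_pool(list(a, b), whole_interval(100))$fst
    hu <- fst_hudson(a, b, whole_interval(100))$fst
    if (!is.na(wc) && !is.na(hu)) {
      expect_lt(abs(wc - hu), 0.25) # same estimand, different corrections
    }
  }
})

test_that("stats_table bookkeeping, NA policy and determinism", {
  genes <- demo_gene_table(n_random = 7)[c(1:5, 34:40), ]
  cfg <- sim_config(seed = 3, pools = c(A = 4L, B = 3L, solo = 1L),
                    genes = genes)
  panel <- simulate_panel(cfg)
  st <- stats_table(panel$pools, panel$intervals)
  expect_equal(nrow(st$stats), nrow(genes) * 3)
  expect_equal(nrow(st$fst), nrow(genes))
  solo <- st$stats[st$stats$pool == "solo", ]
  expect_true(all(is.na(solo$tajima_d)))
  expect_true(all(solo$na_reason == "insufficient_samples"))
  st2 <- stats_table(simulate_panel(cfg)$pools, panel$intervals)
  expect_identical(st, st2)
})
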