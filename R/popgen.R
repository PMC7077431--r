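#' Construct a genotype pool
#'
#' A pool is one species group's diploid genotype table over biallelic
#' SNPs: a sites x diploids matrix of derived-allele counts (0, 1, 2 or
#' NA for missing), with 0-based site positions.
#'
#' @param name pool identifier (e.g. `"PWU"` for Persian walnut, US).
#' @param genotypes sites x diploids matrix, entries in \{0, 1, 2, NA\}.
#' @param positions 0-based site coordinates, strictly increasing within
#'   each chromosome.
#' @param chrom chromosome name per site (single string recycled, or a
#'   vector of length `nrow(genotypes)`).
#' @return an object of class `genotype_pool`.
#' @export
genotype_pool <- function(name, genotypes, positions, chrom = "Chr01") {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  stopifnot(is.character(name), length(name) == 1,
            nrow(genotypes) == length(positions))
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("genotypes must be derived-allele counts in {0,1,2} or NA")
  }
  if (length(chrom) == 1) chrom <- rep(chrom, length(positions))
  stopifnot(length(chrom) == length(positions))
  for (cc in unique(chrom)) {
    if (is.unsorted(positions[chrom == cc], strictly = TRUE)) {
      stop("positions must be strictly increasing within a chromosome")
    }
  }
  structure(list(name = name, genotypes = genotypes,
                 positions = as.integer(positions),
                 chrom = as.character(chrom),
                 n_diploids = ncol(genotypes)),
            class = "genotype_pool")
}

#' @export
print.genotype_pool <- function(x, ...) {
  cat("genotype_pool", x$name, ":", nrow(x$genotypes), "sites x",
      x$n_diploids, "diploids,", length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

# Row indices of pool sites inside an interval (0-based half-open).
# interval may be NULL (all sites), a list/one-row data.frame with
# start/end (and optionally chrom).
pool_site_index <- function(pool, interval) {
  if (is.null(interval)) return(seq_along(pool$positions))
  start <- interval$start
  end <- interval$end
  stopifnot(length(start) == 1, length(end) == 1, start < end)
  idx <- which(pool$positions >= start & pool$positions < end)
  if (!is.null(interval$chrom) && !is.na(interval$chrom)) {
    idx <- idx[pool$chrom[idx] == interval$chrom]
  }
  idx
}

interval_length <- function(pool, interval) {
  if (is.null(interval)) {
    if (length(pool$positions) == 0) return(NA_integer_)
    return(max(pool$positions) - min(pool$positions) + 1L)
  }
  as.integer(interval$end - interval$start)
}

# Per-site summaries used by every statistic: non-missing allele count m,
# derived-allele count j, heterozygote count, missing fraction.
site_counts <- function(g) {
  nm <- rowSums(!is.na(g)) # diploids with a call, per site
  list(
    n_dip = nm,
    m = 2L * nm,
    j = rowSums(g, na.rm = TRUE),
    het = rowSums(g == 1L, na.rm = TRUE),
    miss_frac = 1 - nm / ncol(g)
  )
}

# Sites that segregate among non-missing calls (0 < j < m).
is_segregating <- function(sc) sc$m > 0 & sc$j > 0 & sc$j < sc$m

#' Segregating sites and filtered SNP count for a gene
#'
#' `S` counts sites that segregate among the non-missing genotype calls;
#' `n_snps` additionally requires the per-site missing fraction to be at
#' most `max_missing`. All downstream per-gene statistics (pi, Tajima's D,
#' heterozygosity) are computed over the `n_snps` site set.
#'
#' @param pool a `genotype_pool`.
#' @param interval NULL (whole pool) or a list/one-row data.frame with
#'   `start`, `end` (0-based half-open) and optionally `chrom`.
#' @param max_missing maximum tolerated per-site missing fraction in
#'   \[0, 1\] (default 0.5).
#' @return list with `S`, `n_snps` and `snp_index` (row indices of the
#'   filtered sites within the pool).
#' @export
segregating_sites <- function(pool, interval = NULL, max_missing = 0.5) {
  stopifnot(inherits(pool, "genotype_pool"),
            max_missing >= 0, max_missing <= 1)
  idx <- pool_site_index(pool, interval)
  if (length(idx) == 0) {
    return(list(S = 0L, n_snps = 0L, snp_index = integer(0)))
  }
  g <- pool$genotypes[idx, , drop = FALSE]
  sc <- site_counts(g)
  seg <- is_segregating(sc)
  keep <- seg & sc$miss_frac <= max_missing
  list(S = sum(seg), n_snps = sum(keep), snp_index = idx[keep])
}

#' Tajima (1989) normalising constants
#'
#' The eight constants entering Tajima's D for a sample of `n` alleles:
#' a1 = sum_{i=1}^{n-1} 1/i, a2 = sum 1/i^2, b1 = (n+1)/(3(n-1)),
#' b2 = 2(n^2+n+3)/(9n(n-1)), c1 = b1 - 1/a1,
#' c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1, e2 = c2/(a1^2 + a2).
#'
#' @param n number of sampled alleles (>= 2; the variance terms require
#'   n >= 4 to be usable downstream).
#' @return named list with `n, a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 2) {
    stop("tajima_constants requires n >= 2")
  }
  n <- as.integer(n)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
       c1 = c1, c2 = c2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Nucleotide diversity (pi) per bp for a gene
#'
#' Pairwise-difference form: per site with `m` non-missing alleles of
#' which `j` derived, pi_site = 2 j (m - j) / (m (m - 1)); the gene value
#' is the sum over filtered SNP sites divided by the interval length
#' (invariant sites contribute zero implicitly).
#'
#' @inheritParams segregating_sites
#' @return list with `pi_per_bp`, `pi_total` (unscaled sum) and `length`.
#' @export
nucleotide_diversity <- function(pool, interval = NULL, max_missing = 0.5) {
  seg <- segregating_sites(pool, interval, max_missing)
  len <- interval_length(pool, interval)
  if (length(seg$snp_index) == 0) {
    g_all <- pool$genotypes[pool_site_index(pool, interval), , drop = FALSE]
    if (nrow(g_all) > 0 && all(is.na(g_all))) {
      return(list(pi_per_bp = NA_real_, pi_total = NA_real_, length = len))
    }
    return(list(pi_per_bp = 0, pi_total = 0, length = len))
  }
  g <- pool$genotypes[seg$snp_index, , drop = FALSE]
  sc <- site_counts(g)
  usable <- sc$m >= 2
  pi_site <- ifelse(usable,
                    2 * sc$j * (sc$m - sc$j) / (sc$m * (sc$m - 1)), 0)
  pi_total <- sum(pi_site)
  list(pi_per_bp = pi_total / len, pi_total = pi_total, length = len)
}

#' Watterson's theta per bp for a gene
#'
#' theta_W = S / a1(n) over the filtered SNP sites, divided by interval
#' length; `n` is the gene-level usable allele count (median across
#' sites of non-missing allele counts).
#'
#' @inheritParams segregating_sites
#' @return list with `theta_w_per_bp`, `S`, `n_alleles`.
#' @export
watterson_theta <- function(pool, interval = NULL, max_missing = 0.5) {
  seg <- segregating_sites(pool, interval, max_missing)
  len <- interval_length(pool, interval)
  n_alleles <- usable_allele_count(pool, interval, max_missing)
  if (seg$n_snps == 0 || is.na(n_alleles) || n_alleles < 2) {
    return(list(theta_w_per_bp = 0, S = seg$n_snps, n_alleles = n_alleles))
  }
  a1 <- tajima_constants(n_alleles)$a1
  list(theta_w_per_bp = seg$n_snps / a1 / len, S = seg$n_snps,
       n_alleles = n_alleles)
}

# Gene-level usable allele count: the median, across filtered SNP sites,
# of the per-site non-missing allele counts (a single n per gene, as
# window-based implementations use). Falls back to 2 * n_diploids when
# the gene has no SNPs.
usable_allele_count <- function(pool, interval = NULL, max_missing = 0.5) {
  seg <- segregating_sites(pool, interval, max_missing)
  if (length(seg$snp_index) == 0) return(2L * pool$n_diploids)
  g <- pool$genotypes[seg$snp_index, , drop = FALSE]
  m <- site_counts(g)$m
  as.integer(floor(stats::median(m)))
}

#' Tajima's D for a gene within one pool
#'
#' D = (pi_total - S/a1) / sqrt(e1 S + e2 S (S-1)), with the constants of
#' [tajima_constants()] evaluated at the gene-level usable allele count.
#' Returns NA with a reason when it is undefined: `"no_variation"` when
#' S = 0 and `"insufficient_samples"` when fewer than 4 usable alleles.
#'
#' @inheritParams segregating_sites
#' @return list with `d`, `reason` (NA when d is defined), `S`,
#'   `n_alleles`.
#' @export
tajimas_d <- function(pool, interval = NULL, max_missing = 0.5) {
  seg <- segregating_sites(pool, interval, max_missing)
  n_alleles <- usable_allele_count(pool, interval, max_missing)
  if (!is.na(n_alleles) && n_alleles < 4) {
    return(list(d = NA_real_, reason = "insufficient_samples",
                S = seg$n_snps, n_alleles = n_alleles))
  }
  if (seg$n_snps == 0) {
    return(list(d = NA_real_, reason = "no_variation",
                S = 0L, n_alleles = n_alleles))
  }
  S <- seg$n_snps
  tc <- tajima_constants(n_alleles)
  pi_total <- nucleotide_diversity(pool, interval, max_missing)$pi_total
  v <- tc$e1 * S + tc$e2 * S * (S - 1)
  d <- (pi_total - S / tc$a1) / sqrt(v)
  list(d = d, reason = NA_character_, S = S, n_alleles = n_alleles)
}

#' Observed heterozygosity per bp for a gene
#'
#' The fraction of heterozygous calls among non-missing genotype calls at
#' the filtered SNP sites, scaled by SNP density over the interval:
#' (het calls / non-missing calls) x (SNP sites / gene length). A gene
#' with no SNPs has heterozygosity 0; a gene whose calls are all missing
#' returns NA.
#'
#' @inheritParams segregating_sites
#' @return list with `het_obs_per_bp`, `n_het_calls`, `n_calls`.
#' @export
observed_heterozygosity <- function(pool, interval = NULL,
                                    max_missing = 0.5) {
  seg <- segregating_sites(pool, interval, max_missing)
  len <- interval_length(pool, interval)
  idx_all <- pool_site_index(pool, interval)
  g_all <- pool$genotypes[idx_all, , drop = FALSE]
  if (nrow(g_all) > 0 && all(is.na(g_all))) {
    return(list(het_obs_per_bp = NA_real_, n_het_calls = NA_integer_,
                n_calls = 0L))
  }
  if (length(seg$snp_index) == 0) {
    return(list(het_obs_per_bp = 0, n_het_calls = 0L, n_calls = 0L))
  }
  g <- pool$genotypes[seg$snp_index, , drop = FALSE]
  n_het <- sum(g == 1L, na.rm = TRUE)
  n_calls <- sum(!is.na(g))
  het <- (n_het / n_calls) * (length(seg$snp_index) / len)
  list(het_obs_per_bp = het, n_het_calls = n_het, n_calls = n_calls)
}

#' Multi-population Weir-Cockerham FST for a gene
#'
#' The Weir & Cockerham (1984) variance-components estimator generalised
#' to k populations. Per site, the among-population (a), among-individual
#' (b) and within-individual (c) components are computed from allele
#' frequencies, sample sizes and observed heterozygote frequencies of the
#' pools with data; the gene-level estimate is the ratio of summed a
#' components to summed (a+b+c) across segregating sites ("weighted"
#' ratio-of-averages, as VCFtools reports). Slightly negative estimates
#' are reported unclamped.
#'
#' @param pools list of `genotype_pool` objects sharing site coordinates.
#' @param interval NULL or a list/one-row data.frame with `start`/`end`.
#' @param max_missing per-site missing fraction cap applied within each
#'   pool.
#' @return list with `fst` (NA if < 2 informative pools), `num`, `den`,
#'   `n_sites`, `estimator`.
#' @export
fst_multi_pool <- function(pools, interval = NULL, max_missing = 0.5) {
  stopifnot(length(pools) >= 2,
            all(vapply(pools, inherits, TRUE, "genotype_pool")))
  idx <- pool_site_index(pools[[1]], interval)
  key <- paste(pools[[1]]$chrom[idx], pools[[1]]$positions[idx])
  if (length(key) == 0) {
    return(list(fst = NA_real_, num = 0, den = 0, n_sites = 0L,
                estimator = "weir-cockerham"))
  }
  pool_keys <- lapply(pools, function(p) paste(p$chrom, p$positions))
  num <- 0
  den <- 0
  n_used <- 0L
  for (s in seq_along(key)) {
    p_i <- numeric(0)
    n_i <- numeric(0)
    h_i <- numeric(0)
    any_derived <- 0
    total_alleles <- 0
    for (pi_ in seq_along(pools)) {
      pl <- pools[[pi_]]
      k <- match(key[s], pool_keys[[pi_]])
      if (is.na(k)) next
      g <- pl$genotypes[k, ]
      ok <- !is.na(g)
      if (sum(ok) == 0) next
      if (mean(!ok) > max_missing) next
      ni <- sum(ok)
      n_i <- c(n_i, ni)
      p_i <- c(p_i, sum(g[ok]) / (2 * ni))
      h_i <- c(h_i, sum(g[ok] == 1L) / ni)
      any_derived <- any_derived + sum(g[ok])
      total_alleles <- total_alleles + 2 * ni
    }
    r <- length(n_i)
    if (r < 2) next
    if (any_derived == 0 || any_derived == total_alleles) next # monomorphic
    comp <- wc_site_components(n_i, p_i, h_i)
    num <- num + comp$a
    den <- den + comp$a + comp$b + comp$c
    n_used <- n_used + 1L
  }
  fst <- if (n_used == 0L || den == 0) NA_real_ else num / den
  list(fst = fst, num = num, den = den, n_sites = n_used,
       estimator = "weir-cockerham")
}

# Weir & Cockerham (1984) a, b, c components at one site.
# n_i: diploids sampled per population; p_i: derived-allele frequency;
# h_i: observed heterozygote frequency.
wc_site_components <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  if (nbar <= 1 || nc == 0) return(list(a = 0, b = 0, c = hbar / 2))
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

#' Hudson-type FST for two pools (cross-check estimator)
#'
#' Hudson, Slatkin & Maddison style estimator via Bhatia et al.'s
#' ratio-of-averages form: per site N = (p1-p2)^2 - p1(1-p1)/(n1-1) -
#' p2(1-p2)/(n2-1), D = p1(1-p2) + p2(1-p1); FST = sum(N)/sum(D) with
#' allele counts n1, n2.
#'
#' @param pool_a,pool_b `genotype_pool` objects.
#' @inheritParams fst_multi_pool
#' @return list with `fst`, `n_sites`, `estimator`.
#' @export
fst_hudson <- function(pool_a, pool_b, interval = NULL, max_missing = 0.5) {
  idx <- pool_site_index(pool_a, interval)
  key <- paste(pool_a$chrom[idx], pool_a$positions[idx])
  key_a <- paste(pool_a$chrom, pool_a$positions)
  key_b <- paste(pool_b$chrom, pool_b$positions)
  num <- 0
  den <- 0
  n_used <- 0L
  for (s in seq_along(key)) {
    ka <- match(key[s], key_a)
    kb <- match(key[s], key_b)
    if (is.na(ka) || is.na(kb)) next
    ga <- pool_a$genotypes[ka, ]
    gb <- pool_b$genotypes[kb, ]
    ga <- ga[!is.na(ga)]
    gb <- gb[!is.na(gb)]
    n1 <- 2 * length(ga)
    n2 <- 2 * length(gb)
    if (n1 < 2 || n2 < 2) next
    j1 <- sum(ga)
    j2 <- sum(gb)
    if (j1 + j2 == 0 || j1 + j2 == n1 + n2) next
    p1 <- j1 / n1
    p2 <- j2 / n2
    num <- num + (p1 - p2)^2 -
      p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
    n_used <- n_used + 1L
  }
  list(fst = if (n_used == 0L || den == 0) NA_real_ else num / den,
       n_sites = n_used, estimator = "hudson")
}

#' Full per-gene-per-pool statistics table
#'
#' Computes, for every gene interval and every pool, the statistics that
#' characterise a selection signature — segregating sites, filtered SNP
#' count, nucleotide diversity, Watterson's theta, Tajima's D (with NA
#' reason) and observed heterozygosity per bp — plus one across-pool
#' Weir-Cockerham FST per gene.
#'
#' @param pools named list of `genotype_pool` objects.
#' @param intervals data.frame with columns `chrom`, `start`, `end`,
#'   `gene`, `class`, `label` (0-based half-open coordinates).
#' @param max_missing per-site missing fraction cap.
#' @return list with `stats` (one row per gene x pool: chrom, gene,
#'   label, class, pool, S, n_snps, pi_per_bp, theta_w_per_bp, tajima_d,
#'   na_reason, het_obs_per_bp) and `fst` (one row per gene).
#' @export
stats_table <- function(pools, intervals, max_missing = 0.5) {
  stopifnot(is.list(pools), length(pools) >= 1, is.data.frame(intervals))
  req <- c("chrom", "start", "end", "gene", "class", "label")
  stopifnot(all(req %in% names(intervals)))
  pool_names <- vapply(pools, function(p) p$name, character(1))
  rows <- vector("list", nrow(intervals) * length(pools))
  fst_rows <- vector("list", nrow(intervals))
  k <- 0L
  for (gi in seq_len(nrow(intervals))) {
    iv <- intervals[gi, ]
    # restrict FST to pools on the right chromosome
    on_chr <- vapply(pools, function(p) any(p$chrom == iv$chrom), TRUE)
    for (pi_ in seq_along(pools)) {
      pl <- pools[[pi_]]
      k <- k + 1L
      if (!on_chr[pi_]) {
        rows[[k]] <- data.frame(
          chrom = iv$chrom, gene = iv$gene, label = iv$label,
          class = iv$class, pool = pool_names[pi_], S = 0L, n_snps = 0L,
          pi_per_bp = 0, theta_w_per_bp = 0, tajima_d = NA_real_,
          na_reason = "no_variation", het_obs_per_bp = 0,
          stringsAsFactors = FALSE)
        next
      }
      seg <- segregating_sites(pl, iv, max_missing)
      pi_res <- nucleotide_diversity(pl, iv, max_missing)
      th <- watterson_theta(pl, iv, max_missing)
      td <- tajimas_d(pl, iv, max_missing)
      het <- observed_heterozygosity(pl, iv, max_missing)
      rows[[k]] <- data.frame(
        chrom = iv$chrom, gene = iv$gene, label = iv$label,
        class = iv$class, pool = pool_names[pi_],
        S = seg$S, n_snps = seg$n_snps,
        pi_per_bp = pi_res$pi_per_bp, theta_w_per_bp = th$theta_w_per_bp,
        tajima_d = td$d, na_reason = td$reason,
        het_obs_per_bp = het$het_obs_per_bp,
        stringsAsFactors = FALSE)
    }
    fp <- pools[on_chr]
    fst <- if (length(fp) >= 2) {
      fst_multi_pool(fp, iv, max_missing)
    } else {
      list(fst = NA_real_, n_sites = 0L, estimator = "weir-cockerham")
    }
    fst_rows[[gi]] <- data.frame(
      chrom = iv$chrom, gene = iv$gene, class = iv$class,
      fst = fst$fst, n_sites = fst$n_sites, estimator = fst$estimator,
      stringsAsFactors = FALSE)
  }
  list(stats = do.call(rbind, rows), fst = do.call(rbind, fst_rows))
}
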