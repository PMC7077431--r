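#' Configuration for a synthetic pooled genotype panel
#'
#' Defines the study conditions a simulated panel emulates: nine species
#' pools of 1-16 diploids, candidate cold-hardy genes versus random
#' background genes laid out on chromosomes Chr01..Chr14, and a
#' per-gene-per-pool selection regime (`neutral`, `sweep`, `balancing`).
#'
#' @param seed master seed; every random draw descends from it through
#'   [substream_seed()] sub-streams (one per gene x pool), so the output
#'   is byte-identical across runs.
#' @param pools named integer vector: pool name -> number of diploids
#'   (1-16 each).
#' @param genes data.frame with columns `gene`, `chrom`, `length`,
#'   `class` (`"candidate"` or `"random"`), `label` (functional
#'   annotation, e.g. `"DREB3_ARATH"`).
#' @param regimes character matrix (genes x pools, dimnames matching
#'   `genes$gene` and `names(pools)`) of selection regimes; NULL means
#'   all neutral.
#' @param theta scaled mutation rate 4N*mu*L per gene per pool (> 0).
#' @param sweep_scale tree-height compression for the sweep regime,
#'   in (0, 1].
#' @param balancing_boost root-branch stretch for the balancing regime,
#'   >= 1.
#' @param hybrid_mode how a hybrid pool under `balancing` is emulated:
#'   `"balancing"` stretches the basal branches of one genealogy;
#'   `"admixed"` builds each diploid from one haplotype of each of two
#'   diverged source genealogies plus fixed interspecific differences.
#' @param el_noise_sd Gaussian noise sd on simulated conductivities
#'   (same units as the conductivities).
#' @param ct_noise_sd Gaussian noise sd on simulated Ct values (cycles).
#' @param subs_rate_ladder per-branch substitution probabilities used by
#'   [evolve_sequences()] rate-ladder fixtures.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed, pools, genes, regimes = NULL, theta = 5,
                       sweep_scale = 0.1, balancing_boost = 5,
                       hybrid_mode = c("balancing", "admixed"),
                       el_noise_sd = 0.5, ct_noise_sd = 0.2,
                       subs_rate_ladder = c(0.01, 0.02, 0.05, 0.1)) {
  hybrid_mode <- match.arg(hybrid_mode)
  stopifnot(is.numeric(seed), length(seed) == 1)
  stopifnot(is.numeric(pools), length(pools) >= 1, !is.null(names(pools)),
            all(pools >= 1), all(pools <= 16))
  if (anyDuplicated(names(pools))) stop("pool names must be unique")
  stopifnot(is.data.frame(genes),
            all(c("gene", "chrom", "length", "class", "label")
                %in% names(genes)))
  if (anyDuplicated(genes$gene)) stop("gene ids must be unique")
  stopifnot(all(genes$length > 0),
            all(genes$class %in% c("candidate", "random")))
  stopifnot(theta > 0, sweep_scale > 0, sweep_scale <= 1,
            balancing_boost >= 1, el_noise_sd >= 0, ct_noise_sd >= 0,
            all(subs_rate_ladder >= 0), all(subs_rate_ladder < 0.75))
  if (is.null(regimes)) {
    regimes <- matrix("neutral", nrow(genes), length(pools),
                      dimnames = list(genes$gene, names(pools)))
  }
  stopifnot(identical(rownames(regimes), as.character(genes$gene)),
            identical(colnames(regimes), names(pools)),
            all(regimes %in% c("neutral", "sweep", "balancing")))
  structure(list(seed = seed, pools = pools, genes = genes,
                 regimes = regimes, theta = theta,
                 sweep_scale = sweep_scale,
                 balancing_boost = balancing_boost,
                 hybrid_mode = hybrid_mode,
                 el_noise_sd = el_noise_sd, ct_noise_sd = ct_noise_sd,
                 subs_rate_ladder = subs_rate_ladder),
            class = "sim_config")
}

#' Lay out gene intervals on chromosomes
#'
#' Genes on the same chromosome are placed left to right in table order
#' with a fixed 10 kb spacing, giving deterministic 0-based half-open
#' intervals.
#'
#' @param genes the `genes` data.frame of a [sim_config()].
#' @return data.frame with `chrom`, `start`, `end`, `gene`, `class`,
#'   `label`.
#' @export
gene_intervals <- function(genes) {
  spacing <- 10000L
  out <- genes
  out$start <- NA_integer_
  out$end <- NA_integer_
  for (cc in unique(genes$chrom)) {
    i <- which(genes$chrom == cc)
    start <- cumsum(c(0L, genes$length[i][-length(i)] + spacing))
    out$start[i] <- as.integer(start)
    out$end[i] <- as.integer(start + genes$length[i])
  }
  out[, c("chrom", "start", "end", "gene", "class", "label")]
}

# Simulate one gene x pool: returns list(positions (0-based within
# gene), geno (sites x diploids)). All randomness from `seed`.
sim_gene_pool <- function(n_dip, regime, theta, len, sweep_scale,
                          balancing_boost, hybrid_mode, seed) {
  set.seed(seed)
  if (regime == "balancing" && hybrid_mode == "admixed") {
    return(sim_gene_admixed(n_dip, theta, len))
  }
  tree <- simulate_genealogy(2L * n_dip)
  tree <- apply_regime(tree, regime, sweep_scale, balancing_boost)
  hs <- drop_mutations(tree, theta, length = len)
  geno <- pair_diploids(hs)
  list(positions = hs$positions, geno = geno)
}

# Admixed hybrid pool: each diploid carries one haplotype from each of
# two independently coalescing source pools, plus Poisson(theta) fixed
# interspecific differences that render every diploid heterozygous.
sim_gene_admixed <- function(n_dip, theta, len) {
  ha <- drop_mutations(simulate_genealogy(n_dip), theta, length = len)
  hb <- drop_mutations(simulate_genealogy(n_dip), theta, length = len)
  n_fixed <- stats::rpois(1, theta)
  used <- union(ha$positions, hb$positions)
  avail <- setdiff(seq_len(len) - 1L, used)
  n_fixed <- min(n_fixed, length(avail))
  pos_fixed <- sort(sample(avail, n_fixed))
  pos <- sort(unique(c(ha$positions, hb$positions, pos_fixed)))
  geno <- matrix(0L, nrow = length(pos), ncol = n_dip)
  add <- function(hpos, hap) {
    idx <- match(hpos, pos)
    geno[idx, ] <<- geno[idx, ] + t(hap)
  }
  if (length(ha$positions)) add(ha$positions, ha$hap)
  if (length(hb$positions)) add(hb$positions, hb$hap)
  if (n_fixed > 0) geno[match(pos_fixed, pos), ] <- 1L
  list(positions = pos, geno = geno)
}

#' Simulate a full multi-pool genotype panel in memory
#'
#' For every gene x pool a genealogy is simulated under that cell's
#' regime and infinite-sites mutations are dropped; each pool's
#' genotypes are then expanded to the union of segregating sites across
#' pools (pools carry the ancestral genotype at sites that mutated only
#' elsewhere), mirroring a joint multi-sample VCF.
#'
#' @param config a [sim_config()].
#' @return list with `pools` (named list of [genotype_pool()]) and
#'   `intervals` (the [gene_intervals()] table).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  intervals <- gene_intervals(config$genes)
  pool_names <- names(config$pools)
  per_pool_chrom <- stats::setNames(
    rep(list(character(0)), length(pool_names)), pool_names)
  per_pool_pos <- stats::setNames(
    rep(list(integer(0)), length(pool_names)), pool_names)
  per_pool_geno <- stats::setNames(
    rep(list(NULL), length(pool_names)), pool_names)
  for (gi in seq_len(nrow(intervals))) {
    iv <- intervals[gi, ]
    cells <- list()
    for (pn in pool_names) {
      cells[[pn]] <- sim_gene_pool(
        n_dip = config$pools[[pn]],
        regime = config$regimes[as.character(iv$gene), pn],
        theta = config$theta, len = iv$end - iv$start,
        sweep_scale = config$sweep_scale,
        balancing_boost = config$balancing_boost,
        hybrid_mode = config$hybrid_mode,
        seed = substream_seed(config$seed, "gene", gi, "pool", pn))
    }
    upos <- sort(unique(unlist(lapply(cells, `[[`, "positions"))))
    for (pn in pool_names) {
      g <- matrix(0L, nrow = length(upos), ncol = config$pools[[pn]])
      if (length(cells[[pn]]$positions)) {
        g[match(cells[[pn]]$positions, upos), ] <- cells[[pn]]$geno
      }
      per_pool_chrom[[pn]] <- c(per_pool_chrom[[pn]],
                                rep(iv$chrom, length(upos)))
      per_pool_pos[[pn]] <- c(per_pool_pos[[pn]], upos + iv$start)
      per_pool_geno[[pn]] <- rbind(per_pool_geno[[pn]], g)
    }
  }
  pools <- lapply(pool_names, function(pn) {
    g <- per_pool_geno[[pn]]
    if (is.null(g)) g <- matrix(0L, 0, config$pools[[pn]])
    genotype_pool(pn, g, per_pool_pos[[pn]], per_pool_chrom[[pn]])
  })
  names(pools) <- pool_names
  list(pools = pools, intervals = intervals)
}

#' Write a simulated panel as VCF + BED
#'
#' Emits a joint multi-sample VCF v4.2 (biallelic SNPs, GT-only, samples
#' named `<pool>_<i>`, contigs Chr01..Chr14) and a BED 6+2 file whose
#' extra columns carry the gene class and functional label.
#'
#' @param config a [sim_config()].
#' @param vcf_path,bed_path output file paths.
#' @param panel optional precomputed [simulate_panel()] result (to avoid
#'   re-simulation); must come from the same config.
#' @return invisibly, the in-memory panel.
#' @export
emit_panel <- function(config, vcf_path, bed_path, panel = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(panel)) panel <- simulate_panel(config)
  pools <- panel$pools
  sample_names <- unlist(lapply(names(pools), function(pn) {
    paste0(pn, "_", seq_len(pools[[pn]]$n_diploids))
  }))
  # union of (chrom, pos) across pools, in panel order
  key <- paste(pools[[1]]$chrom, pools[[1]]$positions)
  chrom <- pools[[1]]$chrom
  pos <- pools[[1]]$positions
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt_cols <- lapply(pools, function(pl) {
    k <- match(key, paste(pl$chrom, pl$positions))
    g <- pl$genotypes[k, , drop = FALSE]
    m <- matrix("./.", nrow(g), ncol(g))
    ok <- !is.na(g)
    m[ok] <- gt_code[as.character(g[ok])]
    m
  })
  gt <- do.call(cbind, gt_cols)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=coldhardy-simulate_panel",
    paste0("##contig=<ID=Chr", sprintf("%02d", 1:14), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", sample_names), collapse = "\t"))
  body <- paste(chrom, pos + 1L, ".", "A", "G", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)
  iv <- panel$intervals
  bed <- paste(iv$chrom, iv$start, iv$end, iv$gene, 0L, "+",
               iv$class, iv$label, sep = "\t")
  writeLines(bed, bed_path)
  invisible(panel)
}

#' Read a panel from VCF + BED into genotype pools
#'
#' The reader boundary converts VCF 1-based positions to the package's
#' 0-based half-open convention. Samples are assigned to pools either by
#' an explicit `pool_map` or by stripping the trailing `_<i>` from the
#' sample name.
#'
#' @param vcf_path VCF v4.2 file (biallelic SNPs, GT field).
#' @param bed_path BED 6+2 file (chrom, start, end, gene, score, strand,
#'   class, label).
#' @param pool_map optional named list: pool name -> character vector of
#'   sample names.
#' @return list with `pools` (named list of [genotype_pool()]) and
#'   `intervals` data.frame.
#' @export
read_panel <- function(vcf_path, bed_path, pool_map = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  chrom <- vcfR::getCHROM(vcf)
  pos <- vcfR::getPOS(vcf) - 1L # to 0-based
  counts <- matrix(NA_integer_, nrow(gt), ncol(gt),
                   dimnames = dimnames(gt))
  counts[gt %in% c("0/0", "0|0")] <- 0L
  counts[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  counts[gt %in% c("1/1", "1|1")] <- 2L
  samples <- colnames(gt)
  if (is.null(pool_map)) {
    pool_of <- sub("_[0-9]+$", "", samples)
    pool_map <- split(samples, factor(pool_of, unique(pool_of)))
  }
  pools <- lapply(names(pool_map), function(pn) {
    cols <- match(pool_map[[pn]], samples)
    if (anyNA(cols)) stop("samples missing from VCF for pool ", pn)
    genotype_pool(pn, counts[, cols, drop = FALSE], pos, chrom)
  })
  names(pools) <- names(pool_map)
  intervals <- read_bed_intervals(bed_path)
  list(pools = pools, intervals = intervals)
}

#' Read gene intervals from a BED 6+2 file
#' @param bed_path path to the BED file.
#' @return data.frame with `chrom`, `start`, `end`, `gene`, `class`,
#'   `label`.
#' @export
read_bed_intervals <- function(bed_path) {
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 8) stop("expected BED 6+2 with class and label columns")
  names(bed)[1:8] <- c("chrom", "start", "end", "gene", "score",
                       "strand", "class", "label")
  stopifnot(all(bed$start < bed$end))
  bed[, c("chrom", "start", "end", "gene", "class", "label")]
}
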