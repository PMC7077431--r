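#' Demo gene table: candidate cold-hardy genes plus random background
#'
#' The 33 candidate entries mirror the chromosome placement and
#' UniProt-style functional vocabulary of the cold-response regulon
#' (DREB/CBF, ERF, ICE1, ZAT families); background genes carry
#' housekeeping-style labels that match no cold-hardy keyword.
#'
#' @param n_random number of random background genes (default 200).
#' @param gene_length_bp length assigned to every gene (default 2000).
#' @return data.frame with `gene`, `chrom`, `length`, `class`, `label`.
#' @export
demo_gene_table <- function(n_random = 200, gene_length_bp = 2000) {
  cand <- data.frame(
    gene = c("g129", "g251", "g303", "g304", "g308", "g350", "g371",
             "g12997", "g13333", "g18519", "g24025", "g24084", "g24112",
             "g27449", "g33652", "g41530", "g41803", "g41807", "g46244",
             "g49957", "g49981", "g49983", "g49988", "g50022", "g50035",
             "g56121", "g66409", "g66538", "g72786", "g72790", "g72833",
             "g72872", "g72901"),
    chrom = c(rep("Chr01", 7), rep("Chr03", 2), "Chr04", rep("Chr05", 3),
              "Chr06", "Chr07", rep("Chr08", 3), "Chr09",
              rep("Chr10", 6), "Chr11", rep("Chr13", 2),
              rep("Chr14", 5)),
    label = c("DRE1B_ARATH", "DREB3_ARATH", "DREB3_ARATH", "DREB3_ARATH",
              "ERF12_ARATH", "ZAT10_ARATH", "ERF80_ARATH", "DRE1B_ARATH",
              "DRE2D_ARATH", "EF103_ARATH", "DREB3_ARATH", "ZAT10_ARATH",
              "ERF80_ARATH", "ERF80_ARATH", "ERF80_ARATH", "DREB3_ARATH",
              "DREB3_ARATH", "ICE1_ARATH", "DREB3_ARATH", "DREB3_ARATH",
              "DREB3_ARATH", "DREB3_ARATH", "ZAT10_ARATH", "ERF80_ARATH",
              "EF2_ARATH", "ERF80_ARATH", "ZAT10_ARATH", "EF103_ARATH",
              "EF103_ARATH", "DREB3_ARATH", "ZAT10_ARATH", "ZAT4_ARATH",
              "CBF1_ARATH"),
    stringsAsFactors = FALSE)
  cand$class <- "candidate"
  bg_labels <- c("PPO_JUGRE", "ACT7_ARATH", "GAPC1_ARATH", "TUBA1_ARATH",
                 "HSP81_ARATH", "RBCL_JUGRE", "CHS1_JUGNI", "MYB46_ARATH",
                 "LEA14_ARATH", "PAL1_ARATH")
  rnd <- data.frame(
    gene = sprintf("r%04d", seq_len(n_random)),
    chrom = sprintf("Chr%02d", (seq_len(n_random) - 1L) %% 14L + 1L),
    label = bg_labels[(seq_len(n_random) - 1L) %% length(bg_labels) + 1L],
    class = rep("random", n_random),
    stringsAsFactors = FALSE)
  out <- rbind(cand[, c("gene", "chrom", "label", "class")],
               rnd[, c("gene", "chrom", "label", "class")])
  out$length <- as.integer(gene_length_bp)
  out[, c("gene", "chrom", "length", "class", "label")]
}

#' Demo pool definition: the nine study pools
#'
#' Diploid counts follow the species composition of the sequenced
#' panel: Japanese walnut (JW), black walnut (BW), butternut (BN),
#' interspecific F1 hybrids (HY), Arizona walnut (AW), Manchurian
#' walnut (MW), Persian walnut from Asia (PWA) and from the US (PWU),
#' plus a single-genotype Northern California black walnut pool (NCB)
#' that exercises the insufficient-sample statistics path.
#'
#' @return named integer vector of diploids per pool.
#' @export
demo_pools <- function() {
  c(JW = 5L, BW = 6L, BN = 5L, HY = 4L, AW = 3L, MW = 5L,
    PWA = 4L, PWU = 7L, NCB = 1L)
}

#' Default demo simulation config
#'
#' Candidate genes evolve under a selective sweep in the US Persian
#' walnut pool (the domesticated, diversity-depleted pool) and under
#' the balancing/excess-heterozygosity regime in the hybrid pool;
#' everything else is neutral.
#'
#' @param seed master seed.
#' @param n_random number of background genes.
#' @return a [sim_config()].
#' @export
demo_config <- function(seed = 1, n_random = 200) {
  genes <- demo_gene_table(n_random)
  pools <- demo_pools()
  regimes <- matrix("neutral", nrow(genes), length(pools),
                    dimnames = list(genes$gene, names(pools)))
  regimes[genes$class == "candidate", "PWU"] <- "sweep"
  regimes[genes$class == "candidate", "HY"] <- "balancing"
  sim_config(seed = seed, pools = pools, genes = genes,
             regimes = regimes)
}

#' Twelve-taxon discordance fixture for nuclear vs organellar trees
#'
#' Simulates sequence sets for 12 walnut-like taxa in three
#' continent-like clades (North American, East Asian, European) plus a
#' butternut-like focal taxon whose nuclear sequences derive from the
#' East Asian clade but whose organellar sequences derive from the
#' North American clade — the topological discordance the two
#' genome-compartment trees are expected to reveal.
#'
#' @param seed integer seed.
#' @param length sequence length per taxon (default 20000 bp).
#' @param tip_prob,stem_prob per-site substitution probabilities on tip
#'   and clade-stem branches.
#' @return list with `nuclear` and `organellar` named sequence vectors,
#'   `focal` (the focal taxon label) and `clades` (list of label
#'   vectors).
#' @export
simulate_discordance_bundle <- function(seed = 1, length = 20000,
                                        tip_prob = 0.02,
                                        stem_prob = 0.06) {
  clades <- list(
    north_american = c("J_nigra", "J_major", "J_hindsii", "J_microcarpa"),
    east_asian = c("J_ailantifolia", "J_mandshurica", "J_cathayensis"),
    european = c("J_regia_1", "J_regia_2", "J_regia_3", "J_sigillata"))
  focal <- "J_cinerea"
  tp <- format(tip_prob, scientific = FALSE)
  sp <- format(stem_prob, scientific = FALSE)
  clade_nwk <- function(members, with_focal = FALSE) {
    tips <- members
    if (with_focal) tips <- c(tips, focal)
    inner <- paste0(tips, ":", tp, collapse = ",")
    paste0("(", inner, "):", sp)
  }
  nuc <- paste0("(", clade_nwk(clades$north_american), ",",
                clade_nwk(clades$east_asian, with_focal = TRUE), ",",
                clade_nwk(clades$european), ");")
  org <- paste0("(", clade_nwk(clades$north_american, with_focal = TRUE),
                ",", clade_nwk(clades$east_asian), ",",
                clade_nwk(clades$european), ");")
  nuclear <- evolve_sequences(ape::read.tree(text = nuc), length,
                              seed = substream_seed(seed, "nuclear"))
  organellar <- evolve_sequences(ape::read.tree(text = org), length,
                                 seed = substream_seed(seed, "organellar"))
  list(nuclear = nuclear, organellar = organellar, focal = focal,
       clades = clades)
}

#' Generate a complete synthetic input bundle on disk
#'
#' Writes everything the pipeline consumes, shaped like the cold-
#' hardiness study: a 9-pool VCF + BED genotype panel (candidates under
#' sweep/balancing regimes), an electrolyte-leakage table at -10/-20/
#' -30 degrees C, a qPCR Ct table at 4/-10/-20/-30/-38 degrees C, and a
#' directory of per-taxon FASTA files for the nuclear k-mer tree (plus
#' an organellar set for the discordance comparison).
#'
#' @param dir output directory (created if absent).
#' @param seed master seed.
#' @param n_random number of background genes.
#' @param seq_length per-taxon sequence length for the phylogeny
#'   fixtures.
#' @return named list of paths (`vcf`, `bed`, `el_csv`, `ct_csv`,
#'   `fasta_dir`, `fasta_dir_organellar`) plus the `config` used.
#' @export
make_demo <- function(dir, seed = 1, n_random = 200, seq_length = 20000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- demo_config(seed = seed, n_random = n_random)
  paths <- list(
    vcf = file.path(dir, "panel.vcf"),
    bed = file.path(dir, "genes.bed"),
    el_csv = file.path(dir, "el_trial.csv"),
    ct_csv = file.path(dir, "ct_table.csv"),
    fasta_dir = file.path(dir, "fasta_nuclear"),
    fasta_dir_organellar = file.path(dir, "fasta_organellar"))
  emit_panel(config, paths$vcf, paths$bed)

  # EL truth: hardy species suffer little damage, tender species much,
  # with damage increasing as temperature drops
  species <- c(J_cinerea = 10, J_nigra = 12, J_ailantifolia = 25,
               J_mandshurica = 28, HY_intermedia = 35, HY_bixbi = 30,
               J_regia_IN = 55, J_regia_CA = 80, J_major = 70)
  el_truth <- do.call(rbind, lapply(names(species), function(sp) {
    base <- species[[sp]]
    # three field genotypes per species so species can be compared
    do.call(rbind, lapply(1:3, function(g) {
      data.frame(genotype = paste0(sp, "_", g), species = sp,
                 temperature = c(-10, -20, -30),
                 true_di = pmin(100, base * c(0.4, 0.8, 1.2)),
                 stringsAsFactors = FALSE)
    }))
  }))
  el <- simulate_el_table(el_truth, el_noise_sd = config$el_noise_sd,
                          replicates = 3,
                          seed = substream_seed(seed, "el"))
  utils::write.csv(el, paths$el_csv, row.names = FALSE)

  # qPCR truth: hardy species keep induction at deep frost, tender
  # species induce early then collapse
  ct_truth <- do.call(rbind, lapply(names(species), function(sp) {
    hardy <- species[[sp]] <= 30
    folds <- if (hardy) c(4, 8, 10, 8) else c(6, 8, 2, 0.5)
    data.frame(sample = sp, condition = c(-10, -20, -30, -38),
               true_fold = folds, stringsAsFactors = FALSE)
  }))
  ct <- simulate_ct_table(ct_truth, ct_noise_sd = config$ct_noise_sd,
                          seed = substream_seed(seed, "ct"))
  utils::write.csv(ct, paths$ct_csv, row.names = FALSE)

  bundle <- simulate_discordance_bundle(seed = seed, length = seq_length)
  for (fd in c("fasta_dir", "fasta_dir_organellar")) {
    dir.create(paths[[fd]], showWarnings = FALSE)
  }
  for (nm in names(bundle$nuclear)) {
    write_fasta(bundle$nuclear[nm],
                file.path(paths$fasta_dir, paste0(nm, ".fasta")))
    write_fasta(bundle$organellar[nm],
                file.path(paths$fasta_dir_organellar,
                          paste0(nm, ".fasta")))
  }
  c(paths, list(config = config))
}

# Serialize Tajima's D with its two NA spellings: "nan" when a gene has
# no variation, "NA" when the pool has too few usable alleles.
format_tajima_column <- function(stats) {
  out <- ifelse(is.na(stats$tajima_d),
                ifelse(stats$na_reason == "no_variation", "nan", "NA"),
                format(stats$tajima_d, digits = 15, trim = TRUE))
  out
}

#' Run the full cold-hardiness pipeline
#'
#' Orchestrates all stages on the given inputs and writes one CSV (or
#' Newick) artifact per stage plus a JSON run manifest. Stages whose
#' input path is NULL are skipped with a message; outputs are
#' deterministic given inputs, thresholds and seed.
#'
#' @param vcf,bed genotype panel paths (required).
#' @param el_csv,ct_csv optional electrolyte-leakage and Ct tables.
#' @param fasta_dir optional directory of per-taxon FASTA files for the
#'   k-mer tree.
#' @param similarity_csv optional similarity matrix (header row + first
#'   column = labels) for the matrix-based tree.
#' @param out_dir output directory.
#' @param pool_map optional sample-to-pool map (see [read_panel()]).
#' @param keywords candidate keywords.
#' @param max_missing,d_threshold,percentile_threshold,alpha thresholds
#'   passed to the respective stages.
#' @param control_condition qPCR calibrator condition.
#' @param k k-mer size for the phylogeny stage.
#' @param seed recorded in the manifest (the analysis stages themselves
#'   are deterministic).
#' @return named list of output paths, invisibly.
#' @export
run_all <- function(vcf, bed, el_csv = NULL, ct_csv = NULL,
                    fasta_dir = NULL, similarity_csv = NULL,
                    out_dir, pool_map = NULL,
                    keywords = cold_hardy_keywords(),
                    max_missing = 0.5, d_threshold = 0,
                    percentile_threshold = 0.10, alpha = 0.05,
                    control_condition = 4, k = 25, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  counts <- list()

  panel <- read_panel(vcf, bed, pool_map)
  st <- stats_table(panel$pools, panel$intervals, max_missing)
  stats_out <- st$stats
  stats_out$tajima_d <- format_tajima_column(stats_out)
  out$stats <- file.path(out_dir, "gene_pool_stats.csv")
  utils::write.csv(stats_out, out$stats, row.names = FALSE)
  out$fst <- file.path(out_dir, "gene_fst.csv")
  utils::write.csv(st$fst, out$fst, row.names = FALSE)
  counts$stats <- nrow(st$stats)
  counts$fst <- nrow(st$fst)

  cand_iv <- filter_candidates(panel$intervals, keywords)
  screen_stats <- st$stats
  screen_stats$class <- ifelse(screen_stats$gene %in% cand_iv$gene,
                               "candidate", "random")
  calls <- call_sweeps(screen_stats, d_threshold, percentile_threshold)
  out$calls <- file.path(out_dir, "sweep_calls.csv")
  utils::write.csv(calls, out$calls, row.names = FALSE)
  summ <- summarize_pools(screen_stats, calls)
  out$pool_summary <- file.path(out_dir, "pool_summary.csv")
  utils::write.csv(summ$pool_summary, out$pool_summary, row.names = FALSE)
  out$contrast <- file.path(out_dir, "candidate_contrast.csv")
  utils::write.csv(summ$contrast, out$contrast, row.names = FALSE)
  counts$calls <- nrow(calls)

  if (!is.null(el_csv)) {
    trial <- utils::read.csv(el_csv, stringsAsFactors = FALSE)
    di <- damage_index_table(trial)
    out$damage_index <- file.path(out_dir, "damage_index.csv")
    utils::write.csv(di, out$damage_index, row.names = FALSE)
    grp <- group_summary(di, value = "d_i")
    out$el_groups <- file.path(out_dir, "el_group_summary.csv")
    utils::write.csv(grp, out$el_groups, row.names = FALSE)
    an_rows <- do.call(rbind, lapply(unique(di$temperature), function(tt) {
      sub <- di[di$temperature == tt, ]
      if (length(unique(sub$species)) < 2 || nrow(sub) < 4) return(NULL)
      a <- anova_lsd(sub$d_i, sub$species, alpha)
      data.frame(temperature = tt, f = a$f, p = a$p,
                 protected = a$protected, lsd = a$lsd,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(an_rows)) {
      out$el_anova <- file.path(out_dir, "el_anova.csv")
      utils::write.csv(an_rows, out$el_anova, row.names = FALSE)
    }
    counts$damage_index <- nrow(di)
  } else {
    message("el-index stage skipped: no electrolyte-leakage table")
  }

  if (!is.null(ct_csv)) {
    ct <- utils::read.csv(ct_csv, stringsAsFactors = FALSE)
    prof <- expression_profile(ct, control_condition)
    out$fold_change <- file.path(out_dir, "fold_change.csv")
    utils::write.csv(prof, out$fold_change, row.names = FALSE)
    counts$fold_change <- nrow(prof)
  } else {
    message("qpcr stage skipped: no Ct table")
  }

  if (!is.null(fasta_dir)) {
    files <- sort(list.files(fasta_dir, pattern = "\\.(fa|fasta|fna)$",
                             full.names = TRUE))
    if (length(files) >= 3) {
      profiles <- lapply(files, kmer_profile, k = k)
      d <- aaf_distance_matrix(profiles)
      out$kmer_distances <- file.path(out_dir, "kmer_distances.csv")
      utils::write.csv(d, out$kmer_distances)
      tr <- neighbor_joining(d)
      out$kmer_tree <- file.path(out_dir, "kmer_tree.nwk")
      ape::write.tree(tr, out$kmer_tree)
      counts$kmer_taxa <- length(files)
    } else {
      message("phylo stage skipped: fewer than 3 FASTA files")
    }
  }
  if (!is.null(similarity_csv)) {
    s <- as.matrix(utils::read.csv(similarity_csv, row.names = 1,
                                   check.names = FALSE))
    d <- similarity_to_distance(s)
    tr <- neighbor_joining(d)
    out$matrix_tree <- file.path(out_dir, "matrix_tree.nwk")
    ape::write.tree(tr, out$matrix_tree)
  }

  cfg <- list(vcf = basename(vcf), bed = basename(bed),
              max_missing = max_missing, d_threshold = d_threshold,
              percentile_threshold = percentile_threshold,
              alpha = alpha, control_condition = control_condition,
              k = k, seed = seed, keywords = keywords)
  cfg_file <- tempfile()
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(config = cfg,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   package_version =
                     as.character(utils::packageVersion("coldhardy")),
                   row_counts = counts,
                   outputs = lapply(out, basename))
  unlink(cfg_file)
  out$manifest <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, out$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out)
}
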