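#' Default cold-hardy annotation keywords
#'
#' Substrings of UniProt-style functional labels that mark the
#' cold-response transcription-factor families used to nominate
#' candidate cold-hardy genes (DREB/CBF dehydration-responsive
#' element-binding factors, ethylene-response factors, the ICE1
#' activator and ZAT zinc fingers).
#'
#' @return character vector of keywords (matched case-insensitively).
#' @export
cold_hardy_keywords <- function() {
  c("DREB", "DRE1", "DRE2", "ERF", "EF1", "EF2", "EF103",
    "ICE1", "ZAT", "CBF")
}

#' Filter gene intervals down to annotated candidates
#'
#' A gene is a candidate iff its functional label contains any keyword
#' as a case-insensitive substring; all other genes form the random
#' background.
#'
#' @param intervals data.frame with at least `gene` and `label` columns.
#' @param keywords character vector of keywords; default
#'   [cold_hardy_keywords()].
#' @return the candidate subset of `intervals` (warns if empty).
#' @export
filter_candidates <- function(intervals, keywords = cold_hardy_keywords()) {
  stopifnot(is.data.frame(intervals), "label" %in% names(intervals),
            length(keywords) >= 1)
  hit <- Reduce(`|`, lapply(keywords, function(k) {
    grepl(k, intervals$label, ignore.case = TRUE, fixed = FALSE)
  }))
  out <- intervals[hit, , drop = FALSE]
  if (nrow(out) == 0) warning("no gene label matched any keyword")
  out
}

#' Call per-gene-per-pool selective sweeps
#'
#' Implements the selection-signature evidence rule: a candidate gene is
#' flagged in a pool iff its Tajima's D is negative (below `d_threshold`)
#' AND both its nucleotide diversity and observed heterozygosity fall at
#' or below the `percentile_threshold` quantile of the random-gene
#' background distribution in the same pool. Genes with NA statistics
#' are never flagged.
#'
#' @param stats a per-gene-per-pool stats data.frame (the `stats`
#'   element of [stats_table()]), containing both candidate and
#'   background rows (column `class`).
#' @param d_threshold Tajima's D cut-off (default 0: strictly negative
#'   D required).
#' @param percentile_threshold background quantile for "low" diversity
#'   and heterozygosity, in (0, 1). The default 0.10 (lowest decile)
#'   keeps the screen's flag rate on fully neutral genes below 10%
#'   while retaining high power against sweep-shaped genes; see the
#'   methods vignette for the calibration rationale.
#' @return data.frame with one row per candidate gene x pool: `gene`,
#'   `pool`, `flag`, `tajima_d`, `pi_pctile`, `het_pctile` (percentile
#'   ranks of the candidate within the pool's background).
#' @export
call_sweeps <- function(stats, d_threshold = 0,
                        percentile_threshold = 0.10) {
  stopifnot(is.data.frame(stats),
            all(c("gene", "pool", "class", "tajima_d", "pi_per_bp",
                  "het_obs_per_bp") %in% names(stats)))
  bg <- stats[stats$class == "random", , drop = FALSE]
  cand <- stats[stats$class == "candidate", , drop = FALSE]
  if (nrow(bg) == 0) stop("no background distribution")
  if (length(unique(bg$gene)) < 20) {
    warning("background has < 20 genes; percentile estimates are coarse")
  }
  rows <- lapply(unique(cand$pool), function(pn) {
    cp <- cand[cand$pool == pn, , drop = FALSE]
    bp <- bg[bg$pool == pn, , drop = FALSE]
    pi_ecdf <- stats::ecdf(bp$pi_per_bp[!is.na(bp$pi_per_bp)])
    het_ecdf <- stats::ecdf(bp$het_obs_per_bp[!is.na(bp$het_obs_per_bp)])
    pi_p <- pi_ecdf(cp$pi_per_bp)
    het_p <- het_ecdf(cp$het_obs_per_bp)
    flag <- !is.na(cp$tajima_d) & cp$tajima_d < d_threshold &
      !is.na(cp$pi_per_bp) & pi_p <= percentile_threshold &
      !is.na(cp$het_obs_per_bp) & het_p <= percentile_threshold
    data.frame(gene = cp$gene, pool = pn, flag = flag,
               tajima_d = cp$tajima_d, pi_pctile = pi_p,
               het_pctile = het_p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pool-level summaries and candidate-vs-background contrast
#'
#' Per pool: mean Tajima's D and mean heterozygosity over candidate
#' genes (non-NA entries only), total SNPs, and the count of candidate
#' genes with D >= 1 (the hybrid-pool signature). The contrast compares
#' candidate against background distributions of D, pi and Het within
#' each pool by a two-sided Mann-Whitney U test, with Benjamini-Hochberg
#' correction across all pool x statistic tests. Descriptive screens of
#' this kind often report no formal test for the contrast; the
#' Mann-Whitney + BH choice is this package's and is recorded in the
#' `method` column.
#'
#' @param stats per-gene-per-pool stats data.frame (see [call_sweeps()]).
#' @param calls optional [call_sweeps()] output; if given, the summary
#'   also reports per-pool flag counts.
#' @return list with `pool_summary` and `contrast` data.frames.
#' @export
summarize_pools <- function(stats, calls = NULL) {
  stopifnot(is.data.frame(stats))
  cand <- stats[stats$class == "candidate", , drop = FALSE]
  bg <- stats[stats$class == "random", , drop = FALSE]
  pools <- unique(stats$pool)
  pool_summary <- do.call(rbind, lapply(pools, function(pn) {
    cp <- cand[cand$pool == pn, , drop = FALSE]
    if (all(is.na(cp$tajima_d))) {
      warning("pool ", pn, ": all candidate Tajima's D are NA")
    }
    data.frame(
      pool = pn,
      mean_tajima_d = mean(cp$tajima_d, na.rm = TRUE),
      mean_het = mean(cp$het_obs_per_bp, na.rm = TRUE),
      mean_pi = mean(cp$pi_per_bp, na.rm = TRUE),
      total_snps = sum(cp$n_snps),
      n_d_ge_1 = sum(cp$tajima_d >= 1, na.rm = TRUE),
      n_genes = nrow(cp),
      n_flagged = if (is.null(calls)) NA_integer_ else {
        sum(calls$flag[calls$pool == pn])
      },
      stringsAsFactors = FALSE)
  }))
  stat_cols <- c(tajima_d = "tajima_d", pi = "pi_per_bp",
                 het = "het_obs_per_bp")
  contrast <- do.call(rbind, lapply(pools, function(pn) {
    do.call(rbind, lapply(names(stat_cols), function(sn) {
      x <- cand[cand$pool == pn, stat_cols[[sn]]]
      y <- bg[bg$pool == pn, stat_cols[[sn]]]
      x <- x[!is.na(x)]
      y <- y[!is.na(y)]
      p <- if (length(x) >= 1 && length(y) >= 1) {
        suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
      } else NA_real_
      data.frame(pool = pn, statistic = sn,
                 cand_mean = mean(x), bg_mean = mean(y),
                 n_cand = length(x), n_bg = length(y), p_value = p,
                 method = "mann-whitney-two-sided",
                 stringsAsFactors = FALSE)
    }))
  }))
  contrast$p_adjusted <- stats::p.adjust(contrast$p_value, method = "BH")
  list(pool_summary = pool_summary, contrast = contrast)
}
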