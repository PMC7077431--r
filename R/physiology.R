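#' Electrolyte-leakage frost damage index
#'
#' The relative frost damage index for one genotype at one test
#' temperature: D_I = 100 (R_t - R_o) / (1 - R_o), where R_t is the mean
#' initial/final conductivity ratio EC_i/EC_f of frozen replicates and
#' R_o the mean ratio of unfrozen controls. Ratios are averaged across
#' replicates (the formula is defined on per-sample ratios, not on raw
#' conductivities). Measurement noise can push D_I slightly below 0;
#' the raw value is reported unclamped alongside a clamped convenience
#' value.
#'
#' @param frozen data.frame with columns `ec_i`, `ec_f` for frozen
#'   replicates (conductivities, any common units, all > 0, ec_i <=
#'   ec_f).
#' @param control data.frame with the same columns for unfrozen
#'   controls.
#' @return list with `d_i` (unclamped), `d_i_clamped` (to \[0, 100\]),
#'   `r_t`, `r_o`.
#' @export
damage_index <- function(frozen, control) {
  for (d in list(frozen, control)) {
    stopifnot(is.data.frame(d), nrow(d) >= 1,
              all(c("ec_i", "ec_f") %in% names(d)))
    if (any(d$ec_i <= 0) || any(d$ec_f <= 0)) {
      stop("conductivities must be positive")
    }
  }
  r_t <- mean(frozen$ec_i / frozen$ec_f)
  r_o <- mean(control$ec_i / control$ec_f)
  if (r_o >= 1) stop("control fully leaked: R_o >= 1")
  d_i <- 100 * (r_t - r_o) / (1 - r_o)
  list(d_i = d_i, d_i_clamped = min(100, max(0, d_i)),
       r_t = r_t, r_o = r_o)
}

#' Damage index table from a freeze-trial CSV
#'
#' Computes [damage_index()] for every genotype x temperature cell of a
#' long-format freeze-trial table (see [simulate_el_table()] for the
#' schema): frozen replicates of a cell are paired with the control
#' (`condition == "control"`) replicates of the same genotype.
#'
#' @param trial data.frame with columns `genotype`, `species`,
#'   `temperature`, `condition` (`"frozen"`/`"control"`), `replicate`,
#'   `ec_i`, `ec_f`.
#' @return data.frame: one row per genotype x frozen temperature with
#'   `d_i`, `d_i_clamped`, `r_t`, `r_o`.
#' @export
damage_index_table <- function(trial) {
  req <- c("genotype", "species", "temperature", "condition",
           "replicate", "ec_i", "ec_f")
  stopifnot(is.data.frame(trial), all(req %in% names(trial)))
  frozen <- trial[trial$condition == "frozen", , drop = FALSE]
  cells <- unique(frozen[, c("genotype", "species", "temperature")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ce <- cells[i, ]
    fr <- frozen[frozen$genotype == ce$genotype &
                   frozen$temperature == ce$temperature, , drop = FALSE]
    ct <- trial[trial$condition == "control" &
                  trial$genotype == ce$genotype, , drop = FALSE]
    if (nrow(ct) == 0) stop("no control replicates for ", ce$genotype)
    di <- damage_index(fr, ct)
    data.frame(genotype = ce$genotype, species = ce$species,
               temperature = ce$temperature, d_i = di$d_i,
               d_i_clamped = di$d_i_clamped, r_t = di$r_t, r_o = di$r_o,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ordinal winterkill rating from percent twig damage
#'
#' Maps percent damage to the 1-5 field rating scale: 1 = no visible
#' damage, 2 = minimal twig damage (5-20%), 3 = moderate (20-50%),
#' 4 = severe dieback to ground with resprouting (50-90%), 5 = mortal
#' injury without resprouting (90-100%). Bands are left-closed,
#' right-open; in the >= 90% zone the resprout flag decides between 4
#' and 5.
#'
#' @param percent_damage numeric in \[0, 100\] (vectorised).
#' @param resprouted logical (recycled).
#' @return integer rating(s) in 1..5.
#' @export
winterkill_rating <- function(percent_damage, resprouted) {
  if (any(percent_damage < 0 | percent_damage > 100, na.rm = TRUE)) {
    stop("percent_damage must lie in [0, 100]")
  }
  n <- max(length(percent_damage), length(resprouted))
  p <- rep_len(percent_damage, n)
  rs <- rep_len(as.logical(resprouted), n)
  r <- integer(n)
  r[p < 5] <- 1L
  r[p >= 5 & p < 20] <- 2L
  r[p >= 20 & p < 50] <- 3L
  r[p >= 50 & p < 90] <- 4L
  r[p >= 90] <- ifelse(rs[p >= 90], 4L, 5L)
  r
}

#' One-way ANOVA with protected Fisher's LSD
#'
#' Fixed-effects one-way ANOVA followed, only when the omnibus test is
#' significant at `alpha` (the "protection"), by all pairwise Fisher
#' least-significant-difference comparisons using the pooled error mean
#' square, summarised as a compact letter display (groups sharing a
#' letter are not significantly different).
#'
#' @param values numeric response vector.
#' @param groups factor/character of group membership (>= 2 groups).
#' @param alpha significance level for both the omnibus test and the
#'   pairwise comparisons (default 0.05).
#' @return list with `f`, `p`, `df`, `mse`, `protected` (was LSD run),
#'   `lsd` (the LSD critical difference at the mean group size, NA when
#'   not protected), `means` (data.frame group/mean/n/letters) and
#'   `pairs` (pairwise differences and p-values; NULL when not
#'   protected).
#' @export
anova_lsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2)
  n_i <- tabulate(groups)
  if (any(n_i < 1)) stop("every group needs at least one observation")
  df_err <- length(values) - nlevels(groups)
  if (df_err < 2) stop("need at least 2 residual degrees of freedom")
  fit <- stats::aov(values ~ groups)
  an <- stats::anova(fit)
  f <- an$`F value`[1]
  p <- an$`Pr(>F)`[1]
  mse <- an$`Mean Sq`[2]
  means <- tapply(values, groups, mean)
  lev <- levels(groups)
  degenerate <- mse == 0
  protected <- degenerate && length(unique(means)) > 1 ||
    (!degenerate && !is.na(p) && p <= alpha)
  pairs <- NULL
  sig <- matrix(FALSE, nlevels(groups), nlevels(groups),
                dimnames = list(lev, lev))
  lsd_val <- NA_real_
  if (protected) {
    tcrit <- stats::qt(1 - alpha / 2, df_err)
    lsd_val <- tcrit * sqrt(mse * 2 / mean(n_i))
    cmb <- utils::combn(nlevels(groups), 2)
    pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
      i <- cmb[1, k]; j <- cmb[2, k]
      diff <- means[i] - means[j]
      if (degenerate) {
        pp <- if (diff != 0) 0 else 1
      } else {
        se <- sqrt(mse * (1 / n_i[i] + 1 / n_i[j]))
        pp <- 2 * stats::pt(-abs(diff / se), df_err)
      }
      data.frame(group1 = lev[i], group2 = lev[j], diff = unname(diff),
                 p_value = pp, stringsAsFactors = FALSE)
    }))
    for (k in seq_len(nrow(pairs))) {
      if (pairs$p_value[k] <= alpha) {
        sig[pairs$group1[k], pairs$group2[k]] <- TRUE
        sig[pairs$group2[k], pairs$group1[k]] <- TRUE
      }
    }
  }
  letters_out <- cld_letters(means, sig)
  means_df <- data.frame(group = lev, mean = as.numeric(means[lev]),
                         n = n_i, letters = letters_out[lev],
                         stringsAsFactors = FALSE)
  list(f = f, p = p, df = c(nlevels(groups) - 1L, df_err), mse = mse,
       protected = protected, lsd = lsd_val, means = means_df,
       pairs = pairs)
}

# Compact letter display by the insert-and-absorb sweep: order groups by
# decreasing mean; for each group extend a run downward until a
# significant difference is met; drop runs contained in others; assign
# letters in mean order.
cld_letters <- function(means, sig) {
  lev <- names(means)
  ord <- order(-means)
  runs <- list()
  for (s in seq_along(ord)) {
    e <- s
    while (e < length(ord) && !sig[lev[ord[s]], lev[ord[e + 1]]]) {
      e <- e + 1
    }
    runs[[length(runs) + 1]] <- ord[s:e]
  }
  keep <- rep(TRUE, length(runs))
  for (i in seq_along(runs)) {
    for (j in seq_along(runs)) {
      if (i != j && keep[j] && all(runs[[i]] %in% runs[[j]]) &&
          length(runs[[i]]) < length(runs[[j]])) {
        keep[i] <- FALSE
      }
    }
  }
  runs <- unique(runs[keep])
  out <- stats::setNames(rep("", length(lev)), lev)
  for (k in seq_along(runs)) {
    out[lev[runs[[k]]]] <- paste0(out[lev[runs[[k]]]], letters[k])
  }
  out
}

#' Mean and standard error per species x temperature cell
#'
#' @param records data.frame with a numeric `value` column and grouping
#'   columns `species` and `temperature` (defaults; override with
#'   `by`).
#' @param value name of the response column.
#' @param by character vector of grouping column names.
#' @return data.frame with group columns, `mean`, `se` (NA for a single
#'   record), `n`.
#' @export
group_summary <- function(records, value = "value",
                          by = c("species", "temperature")) {
  stopifnot(is.data.frame(records), value %in% names(records),
            all(by %in% names(records)))
  keys <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(keys), function(k) {
    sub <- records[keys == k, , drop = FALSE]
    v <- sub[[value]]
    out <- sub[1, by, drop = FALSE]
    out$mean <- mean(v)
    out$se <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    out$n <- length(v)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
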