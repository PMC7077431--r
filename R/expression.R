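#' Delta-delta-Ct relative expression for one sample x condition
#'
#' Livak-style relative quantification against an internal reference
#' gene (actin): technical replicates are averaged within each
#' biological replicate; per biological replicate
#' delta-Ct = Ct_target - Ct_reference; delta-delta-Ct is the mean
#' delta-Ct at the treatment condition minus the mean at the control
#' condition, and fold change = 2^(-delta-delta-Ct) (amplification
#' efficiency fixed at perfect doubling). The fold-change standard error
#' is propagated from the biological-replicate variance of delta-Ct:
#' se_fold = fold * ln(2) * se(ddCt).
#'
#' @param ct_table long data.frame with columns `sample`, `condition`,
#'   `role` (`"target"`/`"reference"`), `bio_rep`, `tech_rep`, `ct`
#'   (> 0).
#' @param sample sample id to quantify.
#' @param condition treatment condition (matched against the
#'   `condition` column, e.g. a temperature).
#' @param control_condition calibrator condition (default `4`, the
#'   unfrozen control temperature in degrees C).
#' @return list with `ddct`, `fold`, `se_fold`, `se_ddct`.
#' @export
delta_delta_ct <- function(ct_table, sample, condition,
                           control_condition = 4) {
  req <- c("sample", "condition", "role", "bio_rep", "tech_rep", "ct")
  stopifnot(is.data.frame(ct_table), all(req %in% names(ct_table)))
  if (any(ct_table$ct <= 0)) stop("Ct values must be positive")
  dct <- function(cond) {
    sub <- ct_table[ct_table$sample == sample &
                      ct_table$condition == cond, , drop = FALSE]
    for (role in c("target", "reference")) {
      if (!any(sub$role == role)) {
        stop("missing cell: sample=", sample, " condition=", cond,
             " role=", role)
      }
    }
    # mean Ct per role within each biological replicate (tech reps first)
    per_bio <- tapply(sub$ct, list(sub$bio_rep, sub$role), mean)
    if (anyNA(per_bio[, c("target", "reference")])) {
      stop("missing cell: sample=", sample, " condition=", cond,
           " (incomplete biological replicate)")
    }
    per_bio[, "target"] - per_bio[, "reference"]
  }
  d_trt <- dct(condition)
  d_ctl <- dct(control_condition)
  ddct <- mean(d_trt) - mean(d_ctl)
  var_ddct <- 0
  if (length(d_trt) > 1) var_ddct <- var_ddct +
      stats::var(d_trt) / length(d_trt)
  if (length(d_ctl) > 1) var_ddct <- var_ddct +
      stats::var(d_ctl) / length(d_ctl)
  se_ddct <- sqrt(var_ddct)
  fold <- 2^(-ddct)
  list(ddct = ddct, fold = fold, se_fold = fold * log(2) * se_ddct,
       se_ddct = se_ddct)
}

#' Fold-change profile across samples and conditions
#'
#' Applies [delta_delta_ct()] to every sample x condition cell of a Ct
#' table, calibrating each sample against its own control condition
#' (the control rows therefore have fold = 1 by construction). Samples
#' lacking the control condition are skipped with a warning.
#'
#' @inheritParams delta_delta_ct
#' @return data.frame with `sample`, `condition`, `ddct`, `fold`,
#'   `se_fold`, rows ordered by sample then condition.
#' @export
expression_profile <- function(ct_table, control_condition = 4) {
  stopifnot(is.data.frame(ct_table))
  samples <- sort(unique(ct_table$sample))
  rows <- list()
  for (smp in samples) {
    conds <- ct_table$condition[ct_table$sample == smp]
    if (!any(conds == control_condition)) {
      warning("sample ", smp, " lacks control condition ",
              control_condition, "; skipped")
      next
    }
    for (cond in sort(unique(conds))) {
      fc <- delta_delta_ct(ct_table, smp, cond, control_condition)
      rows[[length(rows) + 1]] <- data.frame(
        sample = smp, condition = cond, ddct = fc$ddct, fold = fc$fold,
        se_fold = fc$se_fold, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
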