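#' Simulate an electrolyte-leakage freeze-trial table
#'
#' Inverse of the frost damage index: for each genotype a control
#' conductivity ratio R_o is drawn Uniform(0.05, 0.25); for each test
#' temperature the frozen ratio is solved from the target index,
#' R_t = R_o + (D_I/100)(1 - R_o); final conductivities EC_f are drawn
#' Uniform(80, 120) (arbitrary common units) and EC_i = R * EC_f, after
#' which independent Gaussian noise of sd `el_noise_sd` is added to
#' every conductivity. With zero noise, [damage_index_table()] recovers
#' the target indices exactly.
#'
#' @param truth data.frame with columns `genotype`, `species`,
#'   `temperature`, `true_di` (target damage index in \[0, 100\]).
#' @param el_noise_sd Gaussian noise sd on conductivities (>= 0).
#' @param replicates replicates per cell (frozen and control).
#' @param seed optional integer seed.
#' @param control_temperature temperature recorded for control rows
#'   (default 4 degrees C).
#' @return long data.frame with columns `genotype`, `species`,
#'   `temperature`, `condition`, `replicate`, `ec_i`, `ec_f`.
#' @export
simulate_el_table <- function(truth, el_noise_sd = 0.5, replicates = 3,
                              seed = NULL, control_temperature = 4) {
  req <- c("genotype", "species", "temperature", "true_di")
  stopifnot(is.data.frame(truth), all(req %in% names(truth)),
            el_noise_sd >= 0, replicates >= 1)
  if (any(truth$true_di < 0 | truth$true_di > 100)) {
    stop("true_di must lie in [0, 100]")
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (gt in unique(truth$genotype)) {
    sub <- truth[truth$genotype == gt, , drop = FALSE]
    r_o <- stats::runif(1, 0.05, 0.25)
    ec_f <- stats::runif(replicates, 80, 120)
    rows[[length(rows) + 1]] <- data.frame(
      genotype = gt, species = sub$species[1],
      temperature = control_temperature, condition = "control",
      replicate = seq_len(replicates),
      ec_i = r_o * ec_f + stats::rnorm(replicates, 0, el_noise_sd),
      ec_f = ec_f + stats::rnorm(replicates, 0, el_noise_sd),
      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(sub))) {
      r_t <- r_o + sub$true_di[i] / 100 * (1 - r_o)
      ec_f <- stats::runif(replicates, 80, 120)
      rows[[length(rows) + 1]] <- data.frame(
        genotype = gt, species = sub$species[1],
        temperature = sub$temperature[i], condition = "frozen",
        replicate = seq_len(replicates),
        ec_i = r_t * ec_f + stats::rnorm(replicates, 0, el_noise_sd),
        ec_f = ec_f + stats::rnorm(replicates, 0, el_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Inverse of the delta-delta-Ct method: the reference gene (actin) has
#' a flat baseline Ct of 20 cycles everywhere, the target gene a control
#' Ct of 25; under each treatment condition the target Ct is shifted by
#' delta-delta-Ct = -log2(true_fold). Independent N(0, ct_noise_sd)
#' noise is added to every technical-replicate measurement. With zero
#' noise, [delta_delta_ct()] recovers the target folds exactly.
#'
#' @param truth data.frame with columns `sample`, `condition`,
#'   `true_fold` (> 0); the control condition need not be listed (its
#'   fold is 1 by definition).
#' @param ct_noise_sd Gaussian noise sd on Ct values (cycles, >= 0).
#' @param bio_reps,tech_reps biological and technical replicates
#'   (defaults 3 x 3).
#' @param seed optional integer seed.
#' @param control_condition calibrator condition (default 4).
#' @return long data.frame with columns `sample`, `condition`, `role`,
#'   `bio_rep`, `tech_rep`, `ct`.
#' @export
simulate_ct_table <- function(truth, ct_noise_sd = 0.2, bio_reps = 3,
                              tech_reps = 3, seed = NULL,
                              control_condition = 4) {
  req <- c("sample", "condition", "true_fold")
  stopifnot(is.data.frame(truth), all(req %in% names(truth)),
            ct_noise_sd >= 0, bio_reps >= 1, tech_reps >= 1)
  if (any(truth$true_fold <= 0)) stop("true_fold must be positive")
  if (!is.null(seed)) set.seed(seed)
  base_ref <- 20
  base_tgt <- 25
  rows <- list()
  emit <- function(smp, cond, role, base) {
    for (b in seq_len(bio_reps)) {
      rows[[length(rows) + 1]] <<- data.frame(
        sample = smp, condition = cond, role = role, bio_rep = b,
        tech_rep = seq_len(tech_reps),
        ct = base + stats::rnorm(tech_reps, 0, ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  for (smp in unique(truth$sample)) {
    sub <- truth[truth$sample == smp, , drop = FALSE]
    emit(smp, control_condition, "reference", base_ref)
    emit(smp, control_condition, "target", base_tgt)
    for (i in seq_len(nrow(sub))) {
      if (sub$condition[i] == control_condition) next
      ddct <- -log2(sub$true_fold[i])
      emit(smp, sub$condition[i], "reference", base_ref)
      emit(smp, sub$condition[i], "target", base_tgt + ddct)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
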