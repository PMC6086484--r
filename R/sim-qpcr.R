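#' Generative truth for a synthetic single-cell qPCR experiment
#'
#' Describes a multiplex qPCR run on a microfluidic array: per-assay
#' amplification efficiency and intercept, group-level log2 expression for
#' handpicked supporting cells, converted hair cells and outer hair cells,
#' per-cell biological spread, technical Cq noise, and a probability of
#' multi-peak melt curves (non-specific amplification).
#'
#' The dilution series implied by the truth is a threefold series of 15
#' concentrations per assay; an assay's LOD-Ct (limit-of-detection threshold
#' cycle) is the Ct of its most dilute point.
#'
#' @param assays assay (gene) names; default 48 synthetic TF assays.
#' @param cell_types,cells_per_type handpicked cell groups and sizes.
#' @param group_log2expr optional assays x cell-types matrix of true log2
#'   expression (relative units); generated when `NULL`. Supplying the group
#'   means of a [bulk_sim_truth()] subset yields paired cross-platform data
#'   with shared truth.
#' @param efficiency_range per-assay amplification efficiency is drawn
#'   uniformly from this interval (fraction per cycle; 1 = perfect doubling).
#' @param intercept_range per-assay Ct at the top dilution-series
#'   concentration.
#' @param cell_sd per-cell biological spread of log2 expression.
#' @param cq_noise_sd technical Cq noise (cycles).
#' @param multi_peak_prob probability that a chamber's melt curve has 2 peaks.
#' @param seed integer seed.
#' @return class `qpcr_sim_truth`.
#' @export
qpcr_sim_truth <- function(assays = sprintf("qTF_%02d", 1:48),
                           cell_types = c("SC", "cHC", "OHC"),
                           cells_per_type = c(SC = 27, cHC = 25, OHC = 16),
                           group_log2expr = NULL,
                           efficiency_range = c(0.85, 1.05),
                           intercept_range = c(8, 14),
                           cell_sd = 0.5,
                           cq_noise_sd = 0.12,
                           multi_peak_prob = 0.05,
                           seed = 1) {
  stopifnot(efficiency_range[1] > 0.7, efficiency_range[2] <= 1.1)
  with_seed(derive_seed(seed, "qpcr"), {
    if (is.null(group_log2expr)) {
      base <- runif(length(assays), 2, 8)
      group_log2expr <- vapply(cell_types, function(ct)
        base + rnorm(length(assays), 0, 1.5), numeric(length(assays)))
      group_log2expr <- matrix(group_log2expr, nrow = length(assays),
                               dimnames = list(assays, cell_types))
    } else {
      assays <- rownames(group_log2expr)
      cell_types <- colnames(group_log2expr)
    }
    eff <- runif(length(assays), efficiency_range[1], efficiency_range[2])
    intercept <- runif(length(assays), intercept_range[1], intercept_range[2])
    structure(list(assays = assays,
                   cell_types = cell_types,
                   cells_per_type = cells_per_type,
                   group_log2expr = group_log2expr,
                   efficiency = setNames(eff, assays),
                   intercept = setNames(intercept, assays),
                   cell_sd = cell_sd,
                   cq_noise_sd = cq_noise_sd,
                   multi_peak_prob = multi_peak_prob,
                   n_dilutions = 15L,
                   dilution_factor = 3),
              class = "qpcr_sim_truth")
  })
}

## Cq from relative expression under the standard exponential-amplification
## model: Cq = intercept - log2(expr) / log2(1 + efficiency); the intercept is
## the Ct at relative expression 1 (the top of the dilution series).
.cq_model <- function(expr, intercept, efficiency) {
  intercept - log2(expr) / log2(1 + efficiency)
}

#' Generate a synthetic qPCR plate and its dilution-series table
#'
#' Draws per-chamber Cq values from the truth's amplification model with
#' technical noise. Chambers whose Cq would fall beyond the assay's
#' limit of detection (the most dilute point of the threefold x 15 series),
#' and chambers with zero expression, fail to amplify and report a missing
#' Cq. A configurable fraction of chambers carries a 2-peak melt curve.
#'
#' @param truth a [qpcr_sim_truth()].
#' @param seed integer seed.
#' @return a list of class `qpcr_plate_sim`: `plate` (long `data.frame` with
#'   `assay`, `chamber`, `cell_id`, `cell_type`, `Cq`, `melt_peaks`),
#'   `dilution_series` (`assay`, `step`, `rel_conc`, `Ct`), and `truth`.
#' @export
gen_qpcr_plate <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "qpcr_sim_truth"))
  with_seed(derive_seed(seed, "qpcr"), {
    n_dil <- truth$n_dilutions
    dil <- expand.grid(assay = truth$assays, step = seq_len(n_dil),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    dil$rel_conc <- truth$dilution_factor^(-(dil$step - 1))
    dil$Ct <- .cq_model(dil$rel_conc, truth$intercept[dil$assay],
                        truth$efficiency[dil$assay]) +
      rnorm(nrow(dil), 0, truth$cq_noise_sd)
    ## noiseless LOD: Ct of the most dilute standard
    lod_true <- .cq_model(truth$dilution_factor^(-(n_dil - 1)),
                          truth$intercept, truth$efficiency)

    cts <- rep(truth$cell_types, times = truth$cells_per_type[truth$cell_types])
    cell_ids <- sprintf("%s_c%02d", cts,
                        unlist(lapply(truth$cells_per_type[truth$cell_types],
                                      seq_len)))
    plate <- expand.grid(assay = truth$assays, cell_id = cell_ids,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    plate$cell_type <- setNames(cts, cell_ids)[plate$cell_id]
    l2e <- truth$group_log2expr[cbind(plate$assay, plate$cell_type)] +
      rnorm(nrow(plate), 0, truth$cell_sd)
    expr <- 2^l2e
    cq <- .cq_model(expr, truth$intercept[plate$assay],
                    truth$efficiency[plate$assay]) +
      rnorm(nrow(plate), 0, truth$cq_noise_sd)
    cq[expr <= 0 | cq > lod_true[plate$assay]] <- NA_real_
    plate$Cq <- cq
    plate$melt_peaks <- 1L + rbinom(nrow(plate), 1L, truth$multi_peak_prob)
    plate$chamber <- sprintf("A%02d.C%03d",
                             match(plate$assay, truth$assays),
                             match(plate$cell_id, cell_ids))
    plate <- plate[, c("assay", "chamber", "cell_id", "cell_type",
                       "Cq", "melt_peaks")]
    list_out <- list(plate = plate,
                     dilution_series = dil[, c("assay", "step", "rel_conc", "Ct")],
                     truth = truth,
                     lod_true = lod_true)
    structure(list_out, class = "qpcr_plate_sim")
  })
}
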