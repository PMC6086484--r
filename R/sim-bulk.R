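#' Generative truth for synthetic bulk RNA-seq of sorted cochlear cell types
#'
#' Builds per-gene group means for five isolated cell types (mature supporting
#' cells, converted hair cells, neonatal and mature outer hair cells, inner
#' hair cells), sequenced in biological duplicate. Differential structure is
#' placed on a random gene subset through independent log2 effect vectors; the
#' converted-hair-cell profile is a convex combination of the supporting-cell
#' and neonatal-hair-cell effects (`mix_alpha` toward OHC_P7), so cHCs sit
#' closest to neonatal hair cells under any reasonable distance.
#'
#' A block of the differential genes is labelled as transcription factors
#' (plus `Isl1` and other named hair-cell TFs) and recorded in `tf_genes`
#' together with non-differential TFs, emulating a genome TF list restricted
#' to desk scale.
#'
#' @param n_genes total genes; `n_de` of them carry differential effects.
#' @param cell_types names of the five sorted populations.
#' @param n_replicates biological replicates per cell type.
#' @param n_de number of differential genes.
#' @param de_log2_sd standard deviation of the log2 effect vectors.
#' @param mix_alpha weight of the neonatal-OHC effect in the cHC profile.
#' @param n_tf,n_tf_de size of the TF list and how many of them are
#'   differential.
#' @param gene_length_lognormal `c(meanlog, sdlog)` of transcript lengths (bp).
#' @param seed integer seed.
#' @return an object of class `bulk_sim_truth` with `group_log2means`
#'   (genes x cell types), `gene_lengths`, `de_genes`, `tf_genes`,
#'   `sample_info`.
#' @export
bulk_sim_truth <- function(n_genes = 2000,
                           cell_types = c("SC_P26", "cHC_P33", "OHC_P7",
                                          "OHC_P22", "IHC_P74"),
                           n_replicates = 2,
                           n_de = 300,
                           de_log2_sd = 1.5,
                           mix_alpha = 0.75,
                           n_tf = 150,
                           n_tf_de = 90,
                           gene_length_lognormal = c(log(2000), 0.5),
                           seed = 1) {
  stopifnot(n_de <= n_genes, n_tf_de <= n_de, n_tf_de <= n_tf)
  with_seed(derive_seed(seed, "bulk"), {
    named_tfs <- head(c("Isl1", "Pou4f3", "Barhl1", "Lhx3", "Ikzf2", "Sall1"),
                      n_tf_de)
    gene_names <- sprintf("bgene_%04d", seq_len(n_genes))
    de_idx <- seq_len(n_de)
    tf_de_idx <- de_idx[seq_len(n_tf_de)]
    n_extra <- max(0, n_tf_de - length(named_tfs))
    gene_names[tf_de_idx] <- c(named_tfs, sprintf("TFde_%03d", seq_len(n_extra)))
    n_tf_null <- n_tf - n_tf_de
    null_tf_idx <- (n_de + 1):(n_de + n_tf_null)
    gene_names[null_tf_idx] <- sprintf("TFnull_%03d", seq_len(n_tf_null))

    base <- rnorm(n_genes, mean = 5, sd = 2)
    eff <- function() {
      v <- numeric(n_genes)
      v[de_idx] <- rnorm(n_de, 0, de_log2_sd)
      v
    }
    dS <- eff(); dH <- eff(); dM <- eff(); dI <- eff()
    G <- cbind(SC = base + dS,
               cHC = base + mix_alpha * dH + (1 - mix_alpha) * dS,
               OHC_P7 = base + dH,
               OHC_P22 = base + dH + dM,
               IHC = base + dH + dI)
    colnames(G) <- cell_types
    rownames(G) <- gene_names

    lengths <- round(rlnorm(n_genes, gene_length_lognormal[1],
                            gene_length_lognormal[2]))
    lengths <- pmax(lengths, 200L)

    sample_info <- data.frame(
      sample = paste(rep(cell_types, each = n_replicates),
                     rep(seq_len(n_replicates), length(cell_types)), sep = "_r"),
      cell_type = rep(cell_types, each = n_replicates),
      replicate = rep(seq_len(n_replicates), length(cell_types)),
      stringsAsFactors = FALSE)

    structure(list(group_log2means = G,
                   gene_lengths = setNames(lengths, gene_names),
                   de_genes = gene_names[de_idx],
                   tf_genes = gene_names[c(tf_de_idx, null_tf_idx)],
                   de_tf_genes = gene_names[tf_de_idx],
                   sample_info = sample_info,
                   seed = seed),
              class = "bulk_sim_truth")
  })
}

#' Generate a synthetic bulk RNA-seq count table
#'
#' Draws negative-binomial counts for each replicate around the group means of
#' a [bulk_sim_truth()]; replicates of a cell type share the group mean.
#'
#' @param truth a [bulk_sim_truth()].
#' @param seed integer seed.
#' @param library_size expected total counted fragments per sample (default 10M).
#' @param nb_dispersion negative-binomial size `theta` (default CV 10%); `Inf` gives the
#'   noiseless limit (counts are the rounded means).
#' @return class `bulk_dataset`: `counts` (genes x samples integer matrix),
#'   `gene_lengths`, `sample_info`, `truth`.
#' @export
gen_bulk_dataset <- function(truth, seed = 1, library_size = 1e7,
                             nb_dispersion = 100) {
  stopifnot(inherits(truth, "bulk_sim_truth"))
  if (is.null(truth$gene_lengths) || any(is.na(truth$gene_lengths)))
    stop("gene lengths are missing from the truth object")
  with_seed(derive_seed(seed, "bulk"), {
    G <- truth$group_log2means
    si <- truth$sample_info
    rel <- 2^G
    frac <- sweep(rel, 2, colSums(rel), "/")
    mu <- frac[, si$cell_type, drop = FALSE] * library_size
    colnames(mu) <- si$sample
    if (is.infinite(nb_dispersion)) {
      counts <- round(mu)
    } else {
      counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                               size = nb_dispersion),
                       nrow = nrow(mu), dimnames = dimnames(mu))
    }
    storage.mode(counts) <- "integer"
    structure(list(counts = counts,
                   gene_lengths = truth$gene_lengths,
                   sample_info = si,
                   truth = truth),
              class = "bulk_dataset")
  })
}

#' Generate imaging-style conversion count tables
#'
#' Emulates per-sample immunofluorescence quantification: each sample
#' contributes a number of reporter-positive (transfected or induced) cells,
#' of which a binomial number are double-positive for the hair-cell marker.
#'
#' @param rates named vector of true conversion rates per condition.
#' @param n_cells reporter-positive cells counted per sample (scalar or one
#'   per sample, recycled within condition).
#' @param n_samples samples per condition (scalar or named like `rates`).
#' @param dislodged_rate expected fraction of double-positive calls that are
#'   dislodged endogenous hair cells (excluded downstream).
#' @param seed integer seed.
#' @return a `data.frame` with columns `sample`, `condition`,
#'   `n_reporter_pos`, `n_double_pos`, `n_excluded_dislodged`.
#' @export
gen_count_table <- function(rates, n_cells = 150, n_samples = 8,
                            dislodged_rate = 0, seed = 1) {
  stopifnot(!is.null(names(rates)), all(rates >= 0), all(rates <= 1))
  ns <- if (length(n_samples) == 1) setNames(rep(n_samples, length(rates)),
                                             names(rates))
        else n_samples[names(rates)]
  with_seed(derive_seed(seed, "counts"), {
    rows <- lapply(names(rates), function(cond) {
      k <- ns[[cond]]
      nrep <- rep_len(n_cells, k)
      dbl <- rbinom(k, nrep, rates[[cond]])
      dis <- rbinom(k, dbl, dislodged_rate)
      data.frame(sample = paste(cond, seq_len(k), sep = "_s"),
                 condition = cond,
                 n_reporter_pos = nrep,
                 n_double_pos = dbl,
                 n_excluded_dislodged = dis,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
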