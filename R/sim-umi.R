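#' Simulation configuration for the synthetic cochlear UMI dataset
#'
#' Describes the generative model used by [gen_umi_dataset()]: a set of cell
#' populations along (and off) a latent conversion coordinate `s` in `[0, 1]`,
#' population-specific marker programs, two transgene features (the HA-tagged
#' Atoh1 transgene and a tdTomato lineage reporter) plus endogenous Atoh1
#' co-driven by the shared latent coordinate, negative-binomial UMI counts
#' with log-normal library sizes, and replicate batch labels.
#'
#' The default preset emulates the cell types of the organ of Corti during
#' Atoh1-mediated conversion: two supporting-cell states (SC1, SC2), three
#' converted-hair-cell states (cHC1-cHC3) forming a continuum with SC1, and
#' endogenous outer/inner hair cells (OHC, IHC). Continuum populations occupy
#' consecutive equal-width sub-intervals of `[0, 1]` in the stated order, so
#' the latent coordinate is monotone across SC1 -> cHC1 -> cHC2 -> cHC3.
#'
#' @param n_genes number of background + marker genes (special features are
#'   appended on top of these).
#' @param population_names names of the simulated populations.
#' @param cells_per_population integer scalar or vector (recycled / matched by
#'   name); a population given 0 cells is absent from the output.
#' @param n_marker_genes_per_population exclusive marker genes per population.
#' @param marker_log2fc log2 elevation of a marker in its own population.
#' @param continuum_populations ordered subset of `population_names` placed on
#'   the latent conversion coordinate.
#' @param continuum_gap fraction of each population's latent sub-interval
#'   trimmed symmetrically, so consecutive conversion states are ordered but
#'   not touching (discrete clusters along a continuum); 0 tiles `[0, 1]`
#'   exactly.
#' @param marker_bump_width for markers of continuum populations, the log2
#'   elevation decays linearly from full strength at the population's
#'   sub-interval midpoint to zero at this latent distance, so expression
#'   profiles vary continuously along the conversion path (adjacent states
#'   resemble each other more than distant ones, as in the real continuum).
#' @param latent_loading_endoAtoh1,latent_loading_Atoh1HA non-negative slopes
#'   of the log2 mean of endogenous Atoh1 / the Atoh1-HA transgene on `s`.
#' @param latent_base_log2 log2 mean of the Atoh1 features at `s = 0`
#'   (the transgene and autoregulated endogenous locus are appreciably
#'   expressed even in early states).
#' @param latent_noise_sd per-cell Gaussian noise (log2 scale, > 0) added to
#'   the two Atoh1 features independently.
#' @param special_dispersion negative-binomial size for the latent-driven
#'   features (Atoh1, Atoh1-HA, reporter, TF stand-ins), tighter than the
#'   background so the latent signal is legible at realistic depths.
#' @param latent_tf_genes symbols of hair-cell TF stand-ins whose log2 means
#'   are also driven by `s` (an Atoh1-centred co-expression module).
#' @param latent_loading_tf,latent_tf_base_log2,latent_tf_noise_sd slope,
#'   baseline and (larger) private noise of the TF stand-ins; the larger
#'   noise makes Atoh1 the central node of the module.
#' @param library_size_lognormal `c(meanlog, sdlog)` of per-cell total UMIs.
#' @param nb_dispersion negative-binomial size parameter `theta`
#'   (variance `mu + mu^2 / theta`).
#' @param batch_labels replicate labels combined with each population's
#'   condition to form sample names.
#' @param seed master seed; fully determines the output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1500,
                       population_names = c("SC1", "SC2", "cHC1", "cHC2",
                                            "cHC3", "OHC", "IHC"),
                       cells_per_population = 100,
                       n_marker_genes_per_population = 25,
                       marker_log2fc = 4,
                       marker_bump_width = 0.25,
                       continuum_gap = 0.5,
                       continuum_populations = c("SC1", "cHC1", "cHC2", "cHC3"),
                       latent_loading_endoAtoh1 = 4.0,
                       latent_loading_Atoh1HA = 4.0,
                       latent_base_log2 = 6,
                       latent_noise_sd = 0.25,
                       latent_tf_genes = c("Barhl1", "Lhx3", "Gata3",
                                           "Hes6", "Neurod6"),
                       latent_loading_tf = 3.4,
                       latent_tf_base_log2 = 5.5,
                       latent_tf_noise_sd = 0.85,
                       library_size_lognormal = c(meanlog = log(2500), sdlog = 0.35),
                       nb_dispersion = 2,
                       special_dispersion = 50,
                       batch_labels = c("rep1", "rep2"),
                       seed = 1) {
  if (latent_loading_endoAtoh1 < 0 || latent_loading_Atoh1HA < 0 ||
      latent_loading_tf < 0)
    stop("latent loadings must be non-negative")
  if (latent_noise_sd <= 0 || latent_tf_noise_sd <= 0)
    stop("latent noise standard deviations must be > 0")
  if (n_genes < 1 || n_marker_genes_per_population < 0)
    stop("counts must be positive")
  if (!all(continuum_populations %in% population_names))
    stop("continuum_populations must be a subset of population_names")
  if (n_marker_genes_per_population * length(population_names) > n_genes)
    stop("marker programs exceed the gene budget (n_genes)")
  ncell <- rep_len(as.integer(cells_per_population), length(population_names))
  if (!is.null(names(cells_per_population)))
    ncell <- as.integer(cells_per_population[population_names])
  if (any(is.na(ncell)) || any(ncell < 0))
    stop("cells_per_population must be non-negative and cover all populations")
  structure(list(
    n_genes = as.integer(n_genes),
    population_names = population_names,
    cells_per_population = setNames(ncell, population_names),
    n_marker_genes_per_population = as.integer(n_marker_genes_per_population),
    marker_log2fc = marker_log2fc,
    marker_bump_width = marker_bump_width,
    continuum_gap = continuum_gap,
    continuum_populations = continuum_populations,
    latent_loading_endoAtoh1 = latent_loading_endoAtoh1,
    latent_loading_Atoh1HA = latent_loading_Atoh1HA,
    latent_base_log2 = latent_base_log2,
    latent_noise_sd = latent_noise_sd,
    latent_tf_genes = latent_tf_genes,
    latent_loading_tf = latent_loading_tf,
    latent_tf_base_log2 = latent_tf_base_log2,
    latent_tf_noise_sd = latent_tf_noise_sd,
    library_size_lognormal = library_size_lognormal,
    nb_dispersion = nb_dispersion,
    special_dispersion = special_dispersion,
    batch_labels = batch_labels,
    seed = as.integer(seed)
  ), class = "sim_config")
}

## condition assigned to each population, mirroring the harvest design:
## uninduced P12 supporting cells, tamoxifen-induced P26/P33 cochleae, and
## uninduced mature hair cells.
.population_condition <- function(pop) {
  map <- c(SC1 = "Coch_P12", SC2 = "Coch_Tmx_P26", cHC1 = "Coch_Tmx_P26",
           cHC2 = "Coch_Tmx_P33", cHC3 = "Coch_Tmx_P33",
           OHC = "Coch_P33", IHC = "Coch_P33")
  out <- map[pop]
  out[is.na(out)] <- "Coch_other"
  unname(out)
}

#' Generate a synthetic gene-by-cell UMI dataset
#'
#' Draws negative-binomial UMI counts for the populations described by a
#' [sim_config()]. Each population has an exclusive marker program; cells of
#' continuum populations additionally carry a latent conversion coordinate
#' `s` that co-drives endogenous Atoh1, the Atoh1-HA transgene and a module
#' of hair-cell TF stand-ins on the log2 scale. The tdTomato reporter marks
#' the Cre lineage (continuum populations and SC2).
#'
#' @param config a [sim_config()].
#' @return an object of class `umi_dataset`: a list with `counts` (integer
#'   genes x cells matrix), `cell_meta` (`sample`, `condition`,
#'   `true_population`, `true_latent`), `special_features` (named gene ids for
#'   endogenous Atoh1, Atoh1-HA and tdTomato) and `truth` (per-cell expected
#'   counts, marker map, latent log2 means of the Atoh1 features).
#' @export
gen_umi_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(derive_seed(cfg$seed, "umi"), {
    pops <- cfg$population_names[cfg$cells_per_population[cfg$population_names] > 0]
    ncell <- cfg$cells_per_population[pops]
    n_cells <- sum(ncell)
    if (n_cells == 0) stop("no cells requested")

    nmk <- cfg$n_marker_genes_per_population
    npop_all <- length(cfg$population_names)
    gene_names <- character(cfg$n_genes)
    marker_of <- rep(NA_character_, cfg$n_genes)
    idx <- 0
    for (p in cfg$population_names) {
      if (nmk > 0) {
        gene_names[idx + seq_len(nmk)] <- sprintf("%s_mk%02d", p, seq_len(nmk))
        marker_of[idx + seq_len(nmk)] <- p
        idx <- idx + nmk
      }
    }
    n_bg <- cfg$n_genes - idx
    gene_names[idx + seq_len(n_bg)] <- sprintf("gene_%04d", seq_len(n_bg))

    specials <- c("Atoh1", "Atoh1-HA", "tdTomato", cfg$latent_tf_genes)
    gene_names <- c(gene_names, specials)
    n_genes <- length(gene_names)

    ## per-population linear mean profile (relative units)
    base_log2 <- stats::rexp(cfg$n_genes, rate = 1)
    M <- matrix(2^base_log2, nrow = cfg$n_genes, ncol = length(pops),
                dimnames = list(gene_names[seq_len(cfg$n_genes)], pops))
    for (j in seq_along(pops)) {
      own <- which(marker_of == pops[j])
      if (length(own)) M[own, j] <- 2^(base_log2[own] + cfg$marker_log2fc)
    }
    ## special features start at zero and are filled in per cell below
    M <- rbind(M, matrix(0, nrow = length(specials), ncol = length(pops),
                         dimnames = list(specials, pops)))

    pop_of_cell <- rep(pops, times = ncell)
    cell_ids <- sprintf("cell_%04d", seq_len(n_cells))

    ## latent conversion coordinate: consecutive equal sub-intervals of [0,1]
    cont <- cfg$continuum_populations
    s <- rep(NA_real_, n_cells)
    gap <- cfg$continuum_gap %||% 0
    for (k in seq_along(cont)) {
      i <- which(pop_of_cell == cont[k])
      w0 <- 1 / length(cont)
      lo <- (k - 1) * w0 + gap * w0 / 2; hi <- k * w0 - gap * w0 / 2
      if (length(i)) s[i] <- runif(length(i), lo, hi)
    }

    lib <- rlnorm(n_cells, meanlog = cfg$library_size_lognormal[[1]],
                  sdlog = cfg$library_size_lognormal[[2]])

    W <- M[, pop_of_cell, drop = FALSE]
    colnames(W) <- cell_ids
    on_cont <- !is.na(s)
    ## markers of continuum populations vary continuously with s: the log2
    ## elevation is a triangular bump centred on the population's
    ## sub-interval midpoint, so adjacent conversion states share partial
    ## marker expression and the continuum is a 1-D path in expression space
    if (any(on_cont) && cfg$marker_bump_width > 0) {
      for (k in seq_along(cont)) {
        if (!(cont[k] %in% pops)) next
        own <- which(marker_of == cont[k])
        if (!length(own)) next
        ctr <- (k - 0.5) / length(cont)
        f <- pmax(0, 1 - abs(s[on_cont] - ctr) / cfg$marker_bump_width)
        W[own, on_cont] <- 2^(outer(base_log2[own],
                                    cfg$marker_log2fc * f, `+`))
      }
    }
    ## endogenous Atoh1 and the transgene share s; independent log2 noise
    atoh1_mu <- matrix(0, n_cells, 2,
                       dimnames = list(cell_ids, c("Atoh1", "Atoh1-HA")))
    if (any(on_cont)) {
      nz <- sum(on_cont)
      e1 <- rnorm(nz, 0, cfg$latent_noise_sd)
      e2 <- rnorm(nz, 0, cfg$latent_noise_sd)
      atoh1_mu[on_cont, 1] <- cfg$latent_base_log2 +
        cfg$latent_loading_endoAtoh1 * s[on_cont] + e1
      atoh1_mu[on_cont, 2] <- cfg$latent_base_log2 +
        cfg$latent_loading_Atoh1HA * s[on_cont] + e2
      W["Atoh1", on_cont] <- 2^atoh1_mu[on_cont, 1]
      W["Atoh1-HA", on_cont] <- 2^atoh1_mu[on_cont, 2]
      ## hair-cell TF module: same latent drive, more private noise, so the
      ## shared coordinate (read out through Atoh1) is the hub
      for (g in cfg$latent_tf_genes) {
        eg <- rnorm(nz, 0, cfg$latent_tf_noise_sd)
        W[g, on_cont] <- 2^(cfg$latent_tf_base_log2 +
                              cfg$latent_loading_tf * s[on_cont] + eg)
      }
    }
    ## mature hair cells express the HC TF module constitutively
    hc_pops <- intersect(c("OHC", "IHC"), pops)
    i_hc <- pop_of_cell %in% hc_pops
    if (any(i_hc) && length(cfg$latent_tf_genes)) {
      for (g in cfg$latent_tf_genes) {
        eg <- rnorm(sum(i_hc), 0, cfg$latent_tf_noise_sd)
        W[g, i_hc] <- 2^(cfg$latent_tf_base_log2 + cfg$latent_loading_tf + eg)
      }
    }
    ## tdTomato marks the Cre lineage (continuum populations and SC2)
    lineage <- on_cont | pop_of_cell %in% intersect("SC2", pops)
    W["tdTomato", lineage] <- 2^5

    frac <- sweep(W, 2, colSums(W), "/")
    mu <- sweep(frac, 2, lib, "*")
    theta <- rep(cfg$nb_dispersion, n_genes)
    theta[rownames(W) %in% specials] <- cfg$special_dispersion
    counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                             size = rep(theta, n_cells)),
                     nrow = n_genes, dimnames = dimnames(mu))
    storage.mode(counts) <- "integer"

    rep_lab <- rep_len(cfg$batch_labels, n_cells)
    cond <- .population_condition(pop_of_cell)
    meta <- data.frame(cell_id = cell_ids,
                       sample = paste(cond, rep_lab, sep = "."),
                       condition = cond,
                       true_population = pop_of_cell,
                       true_latent = s,
                       stringsAsFactors = FALSE)
    rownames(meta) <- cell_ids

    structure(list(
      counts = counts,
      gene_names = gene_names,
      cell_ids = cell_ids,
      cell_meta = meta,
      special_features = c(atoh1_endogenous = "Atoh1",
                           atoh1_ha = "Atoh1-HA",
                           tdtomato = "tdTomato"),
      truth = list(expected = mu,
                   population_means = M,
                   marker_of = setNames(marker_of,
                                        gene_names[seq_len(cfg$n_genes)]),
                   atoh1_log2mean = atoh1_mu,
                   library_sizes = setNames(lib, cell_ids)),
      config = cfg
    ), class = "umi_dataset")
  })
}

#' @export
print.umi_dataset <- function(x, ...) {
  cat("umi_dataset:", nrow(x$counts), "genes x", ncol(x$counts), "cells\n")
  cat("populations:",
      paste(names(table(x$cell_meta$true_population)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a UMI dataset by genes and/or cells
#'
#' Rebuilds a `umi_dataset` around a gene/cell subset (indices, names or
#' logical), keeping counts and cell metadata aligned. Also used internally
#' by the preprocessing steps.
#'
#' @param dataset a `umi_dataset`.
#' @param genes,cells subsets to keep (default all).
#' @param counts optional replacement count matrix.
#' @return the subset `umi_dataset`.
#' @export
umi_subset <- function(dataset, genes = NULL, cells = NULL, counts = NULL) {
  counts <- counts %||% dataset$counts
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (!is.null(cells)) counts <- counts[, cells, drop = FALSE]
  out <- dataset
  out$counts <- counts
  out$gene_names <- rownames(counts)
  out$cell_ids <- colnames(counts)
  out$cell_meta <- dataset$cell_meta[colnames(counts), , drop = FALSE]
  out
}
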