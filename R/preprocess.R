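#' Filter cells by library size, per sample
#'
#' Removes cells whose total UMI count falls outside the stated quantile band
#' of their own sample's library-size distribution, so potential doublets
#' (large libraries) and low-quality cells (small libraries) are removed
#' relative to each dataset rather than globally.
#'
#' @param dataset a `umi_dataset`.
#' @param low,high quantile bounds in `[0, 1]` (`low < high`); defaults keep
#'   the central 96% of each sample. Quantiles use the linear-interpolation
#'   convention (`type = 7`).
#' @return the filtered `umi_dataset`; removed cell ids are recorded in
#'   `removed_cells`.
#' @export
filter_cells_by_library_size <- function(dataset, low = 0.02, high = 0.98) {
  stopifnot(inherits(dataset, "umi_dataset"), low >= 0, high <= 1, low < high)
  totals <- colSums(dataset$counts)
  samples <- dataset$cell_meta$sample
  keep <- logical(length(totals))
  for (s in unique(samples)) {
    i <- which(samples == s)
    q <- quantile(totals[i], c(low, high), type = 7, names = FALSE)
    keep_i <- totals[i] >= q[1] & totals[i] <= q[2]
    if (!any(keep_i))
      stop("library-size filter removed every cell of sample '", s, "'")
    keep[i] <- keep_i
  }
  out <- umi_subset(dataset, cells = which(keep))
  out$removed_cells <- c(dataset$removed_cells,
                         dataset$cell_ids[!keep])
  out
}

#' Harmonize sequencing depth by binomial downsampling
#'
#' Replaces each cell's counts by draws from independent binomials with size
#' equal to the minimum per-cell total UMI count among retained cells and
#' probability equal to the gene's fraction of that cell's library
#' (`Binomial(min_c T_c, x_gc / T_c)` per gene). Zero counts stay zero and
#' each cell's expected new total equals the reference depth, removing
#' library-size batch effects before clustering.
#'
#' Because the per-gene binomials are independent, realized totals vary
#' around the reference depth; `mode = "multinomial"` instead draws a single
#' multinomial of exactly the reference depth per cell (a documented
#' deviation that fixes the totals).
#'
#' @param dataset a `umi_dataset` with all cell totals > 0.
#' @param seed integer seed.
#' @param mode `"binomial"` (default) or `"multinomial"`.
#' @return the `umi_dataset` with downsampled (expected) counts and a
#'   `reference_depth` field.
#' @export
downsample_to_reference_depth <- function(dataset, seed = 1,
                                          mode = c("binomial", "multinomial")) {
  stopifnot(inherits(dataset, "umi_dataset"))
  mode <- match.arg(mode)
  totals <- colSums(dataset$counts)
  if (any(totals <= 0)) stop("all cell totals must be > 0 before downsampling")
  ref <- min(totals)
  with_seed(seed, {
    counts <- dataset$counts
    new <- counts
    for (j in seq_len(ncol(counts))) {
      p <- counts[, j] / totals[j]
      nz <- which(p > 0)
      if (mode == "binomial") {
        new[nz, j] <- rbinom(length(nz), size = ref, prob = p[nz])
      } else {
        new[nz, j] <- as.integer(stats::rmultinom(1, size = ref, prob = p[nz]))
      }
      new[-nz, j] <- 0L
    }
    storage.mode(new) <- "integer"
    out <- umi_subset(dataset, counts = new)
    out$reference_depth <- as.integer(ref)
    out
  })
}

## read one-symbol-per-line blacklist files (cell cycle, apoptosis,
## ribosomal protein genes); comments after '#' and blank lines ignored
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Remove blacklisted genes
#'
#' Drops genes whose symbols appear on any supplied blacklist (case-
#' insensitive exact match), preserving the order of the remaining genes.
#'
#' @param dataset a `umi_dataset`.
#' @param blacklists character vector of symbols, a list of such vectors,
#'   and/or paths to one-symbol-per-line files.
#' @return the filtered `umi_dataset`; removed symbols are recorded in
#'   `removed_genes`.
#' @export
remove_blacklisted_genes <- function(dataset, blacklists) {
  stopifnot(inherits(dataset, "umi_dataset"))
  if (!is.list(blacklists)) blacklists <- list(blacklists)
  symbols <- unlist(lapply(blacklists, function(b) {
    if (length(b) == 1 && is.character(b) && file.exists(b)) read_gene_list(b)
    else b
  }))
  symbols <- unique(tolower(symbols))
  if (!length(symbols)) return(dataset)
  hit <- tolower(rownames(dataset$counts)) %in% symbols
  if (!any(hit)) {
    warning("no blacklisted symbols found among the dataset's genes")
    return(dataset)
  }
  out <- umi_subset(dataset, genes = which(!hit))
  out$removed_genes <- c(dataset$removed_genes, rownames(dataset$counts)[hit])
  out
}

#' Select highly variable genes by binned mean-dispersion z-scores
#'
#' On `log2(expected count + 1)` values, computes each gene's mean and
#' dispersion (variance / mean), bins genes into equal-frequency bins of the
#' mean, z-scores dispersion within each bin, and selects genes with
#' `z >= z_min`. Genes with zero mean are never selected; bins left with
#' fewer than 2 genes are merged with the neighboring bin (with a warning).
#'
#' @param dataset a `umi_dataset`.
#' @param n_bins number of equal-frequency mean bins.
#' @param z_min dispersion z-score threshold.
#' @return a list with `genes` (selected symbols) and `stats` (per-gene
#'   `mean`, `dispersion`, `bin`, `z`).
#' @export
select_hvg <- function(dataset, n_bins = 20, z_min = 1) {
  stopifnot(inherits(dataset, "umi_dataset"), n_bins >= 1)
  x <- log2p1(dataset$counts)
  mu <- rowMeans(x)
  v <- apply(x, 1, var)
  disp <- ifelse(mu > 0, v / mu, NA_real_)
  ok <- which(mu > 0)
  if (length(ok) < n_bins)
    stop("fewer genes with nonzero mean than bins")
  br <- unique(quantile(mu[ok], probs = seq(0, 1, length.out = n_bins + 1),
                        type = 7, names = FALSE))
  bin <- rep(NA_integer_, length(mu))
  bin[ok] <- cut(mu[ok], breaks = br, include.lowest = TRUE, labels = FALSE)
  ## merge undersized bins into their lower neighbor
  repeat {
    tab <- table(bin)
    small <- names(tab)[tab < 2]
    if (!length(small)) break
    b <- as.integer(small[1])
    tgt <- if (b > 1) b - 1L else b + 1L
    warning("merging mean bin ", b, " (<2 genes) into bin ", tgt)
    bin[!is.na(bin) & bin == b] <- tgt
  }
  z <- rep(NA_real_, length(mu))
  for (b in unique(stats::na.omit(bin))) {
    i <- which(!is.na(bin) & bin == b)
    s <- sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  sel <- which(!is.na(z) & z >= z_min)
  list(genes = rownames(dataset$counts)[sel],
       stats = data.frame(gene = rownames(dataset$counts),
                          mean = mu, dispersion = disp, bin = bin, z = z,
                          row.names = NULL, stringsAsFactors = FALSE))
}
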