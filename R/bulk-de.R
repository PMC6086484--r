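#' TMM normalization factors
#'
#' Weighted trimmed mean of M-values (30% trim on log-ratios, 5% on average
#' log-abundance, inverse-variance weights) of each library against a
#' reference sample, rescaled to geometric mean 1. Delegates to the standard
#' edgeR implementation.
#'
#' @param counts genes x samples count matrix.
#' @param ref_sample reference column name or index; `NULL` picks the sample
#'   whose upper quartile is closest to the mean upper quartile.
#' @return named vector of normalization factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, ref_sample = NULL) {
  stop_if_not_counts(as.matrix(counts))
  ref <- if (is.null(ref_sample)) NULL
         else if (is.character(ref_sample)) match(ref_sample, colnames(counts))
         else ref_sample
  f <- edgeR::calcNormFactors(as.matrix(counts), method = "TMM",
                              refColumn = ref)
  setNames(as.numeric(f), colnames(counts))
}

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = count / library_total * 1e6 / (length_bp / 1000)`.
#'
#' @param counts genes x samples count matrix.
#' @param lengths transcript lengths in bp (one per gene).
#' @param norm_factors optional per-sample scaling of the library totals
#'   (e.g. TMM factors) giving TMM-normalized FPKM.
#' @return FPKM matrix.
#' @export
compute_fpkm <- function(counts, lengths, norm_factors = NULL) {
  stopifnot(nrow(counts) == length(lengths), all(lengths > 0))
  tot <- colSums(counts)
  if (!is.null(norm_factors)) tot <- tot * norm_factors
  sweep(counts, 2, tot, "/") * 1e6 / (lengths / 1000)
}

#' Differential expression with voom precision weights and moderated t
#'
#' log2-CPM with TMM-normalized library sizes, lowess mean-variance trend and
#' observation precision weights (voom), gene-wise weighted least squares and
#' empirical-Bayes moderated t statistics, with Benjamini-Hochberg FDR per
#' contrast. Delegates to limma, the standard implementation of this model.
#'
#' @param bulk a `bulk_dataset` (or list with `counts` and `sample_info`).
#' @param contrasts character vector like `"cHC-SC"`; defaults to all
#'   pairwise contrasts between cell types.
#' @param min_cpm,min_samples low-expression trimming: keep genes with CPM
#'   above `min_cpm` in at least `min_samples` samples.
#' @return class `de_result`: list of per-contrast `data.frame`s (`gene`,
#'   `log2FC`, `t`, `p`, `FDR`) plus `genes_tested`.
#' @export
differential_expression <- function(bulk, contrasts = NULL,
                                    min_cpm = 1, min_samples = 2) {
  counts <- bulk$counts
  si <- bulk$sample_info
  groups <- factor(si$cell_type)
  if (any(table(groups) < 2))
    stop("each group needs at least 2 replicates")
  keep <- rowSums(edgeR::cpm(counts) > min_cpm) >= min_samples
  dge <- edgeR::DGEList(counts = counts[keep, , drop = FALSE], group = groups)
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  design <- stats::model.matrix(~ 0 + groups)
  colnames(design) <- levels(groups)
  v <- limma::voom(dge, design)
  fit <- limma::lmFit(v, design)
  if (is.null(contrasts)) {
    lv <- levels(groups)
    cmb <- utils::combn(lv, 2)
    contrasts <- paste(cmb[2, ], cmb[1, ], sep = "-")
  }
  cm <- limma::makeContrasts(contrasts = contrasts, levels = design)
  fit2 <- limma::eBayes(limma::contrasts.fit(fit, cm))
  tables <- lapply(colnames(cm), function(cn) {
    tt <- limma::topTable(fit2, coef = cn, number = Inf, sort.by = "none")
    data.frame(gene = rownames(tt), log2FC = tt$logFC, t = tt$t,
               p = tt$P.Value, FDR = tt$adj.P.Val,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  names(tables) <- colnames(cm)
  structure(list(tables = tables, genes_tested = rownames(dge)),
            class = "de_result")
}

#' Differentially expressed transcription factors
#'
#' Intersects the genes significant in any contrast (FDR below the cutoff)
#' with a TF list.
#'
#' @param de a [differential_expression()] result.
#' @param tf_list TF symbols (or a one-symbol-per-line file path).
#' @param fdr FDR cutoff.
#' @return `data.frame` of TF genes with their smallest FDR and the contrast
#'   attaining it.
#' @export
subset_tf_de <- function(de, tf_list, fdr = 0.05) {
  if (length(tf_list) == 1 && file.exists(tf_list))
    tf_list <- read_gene_list(tf_list)
  if (!length(tf_list))
    return(data.frame(gene = character(), min_FDR = numeric(),
                      contrast = character()))
  sig <- lapply(names(de$tables), function(cn) {
    t <- de$tables[[cn]]
    t$contrast <- cn
    t[t$FDR < fdr, c("gene", "FDR", "contrast")]
  })
  sig <- do.call(rbind, sig)
  sig <- sig[tolower(sig$gene) %in% tolower(tf_list), , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(gene = character(), min_FDR = numeric(),
                      contrast = character()))
  best <- do.call(rbind, lapply(split(sig, sig$gene), function(d)
    d[which.min(d$FDR), ]))
  rownames(best) <- NULL
  names(best)[names(best) == "FDR"] <- "min_FDR"
  best[order(best$min_FDR), ]
}

#' Spearman correlation matrix across bulk samples
#'
#' Rank correlations of expression profiles between all sample pairs
#' (invariant to per-sample monotone transforms); used to check concordance
#' of biological duplicates.
#'
#' @param bulk a `bulk_dataset`.
#' @return samples x samples Spearman correlation matrix.
#' @export
replicate_concordance <- function(bulk) {
  cor(bulk$counts, method = "spearman")
}

#' Six cell-type distance metrics
#'
#' Distances between cell-type mean expression profiles under six metrics:
#' `Spearman_all` and `Spearman_TF` (1 - rank correlation on all genes / TF
#' genes) and Euclidean distances in PC space of four gene subsets
#' (`PCA_all`, `PCA_TF`, `PCA_MAD`: top `mad_top` genes by median absolute
#' deviation, `PCA_4fold`: genes with at least `fold_min`-fold change between
#' some pair of cell types). Genes with zero expression in every cell type
#' are removed before PCA; profiles are TMM-normalized FPKM on the log2
#' scale.
#'
#' @param bulk a `bulk_dataset`.
#' @param tf_list TF symbols.
#' @param pairs list of 2-vectors of cell types; default: every pair
#'   involving the converted-hair-cell type.
#' @param mad_top,fold_min subset parameters.
#' @return `data.frame` with one row per pair and one column per metric.
#' @export
distance_suite <- function(bulk, tf_list, pairs = NULL,
                           mad_top = 200, fold_min = 4) {
  f <- tmm_factors(bulk$counts)
  fpkm <- compute_fpkm(bulk$counts, bulk$gene_lengths[rownames(bulk$counts)],
                       norm_factors = f)
  ct <- bulk$sample_info$cell_type
  types <- unique(ct)
  prof <- sapply(types, function(x)
    rowMeans(fpkm[, ct == x, drop = FALSE]))
  nz <- rowSums(prof) > 0
  prof <- prof[nz, , drop = FALSE]
  lp <- log2p1(prof)
  tf_rows <- tolower(rownames(prof)) %in% tolower(tf_list)

  if (is.null(pairs)) {
    chc <- grep("cHC", types, value = TRUE)[1]
    pairs <- lapply(setdiff(types, chc), function(o) c(chc, o))
  }

  pc_dist <- function(sub) {
    m <- lp[sub, , drop = FALSE]
    p <- prcomp(t(m), center = TRUE, scale. = FALSE)
    as.matrix(dist(p$x))
  }
  d_sp_all <- 1 - cor(lp, method = "spearman")
  d_sp_tf <- 1 - cor(lp[tf_rows, , drop = FALSE], method = "spearman")
  d_pca_all <- pc_dist(rep(TRUE, nrow(lp)))
  d_pca_tf <- pc_dist(tf_rows)
  mads <- apply(lp, 1, stats::mad)
  d_pca_mad <- pc_dist(rank(-mads, ties.method = "first") <= mad_top)
  fold <- apply(prof, 1, function(r) (max(r) + 1) / (min(r) + 1))
  d_pca_fold <- pc_dist(fold >= fold_min)

  out <- do.call(rbind, lapply(pairs, function(p) {
    data.frame(from = p[1], to = p[2],
               Spearman_all = d_sp_all[p[1], p[2]],
               Spearman_TF = d_sp_tf[p[1], p[2]],
               PCA_all = d_pca_all[p[1], p[2]],
               PCA_TF = d_pca_tf[p[1], p[2]],
               PCA_MAD = d_pca_mad[p[1], p[2]],
               PCA_4fold = d_pca_fold[p[1], p[2]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
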