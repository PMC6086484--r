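#' Principal component analysis of a log-expression matrix
#'
#' Gene-centered PCA of `log2(expected count + 1)` values; cells are
#' observations.
#'
#' @param x genes x cells matrix of log-scale expression.
#' @param n_components number of components (at most `min(genes, cells)`).
#' @return list with `scores` (cells x components), `loadings`
#'   (genes x components) and `variance_explained` (component variances).
#' @export
pca_embed <- function(x, n_components = 30) {
  stopifnot(is.matrix(x))
  n_components <- min(n_components, nrow(x), ncol(x))
  p <- prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  list(scores = p$x[, k, drop = FALSE],
       loadings = p$rotation[, k, drop = FALSE],
       variance_explained = p$sdev^2,
       total_variance = sum(p$sdev^2))
}

#' Two-dimensional t-SNE embedding of PC scores
#'
#' @param pc_scores cells x components matrix.
#' @param perplexity t-SNE perplexity; must be below `(cells - 1) / 3`.
#' @param seed integer seed; the embedding is deterministic under it.
#' @param ... passed to [Rtsne::Rtsne()].
#' @return cells x 2 coordinate matrix.
#' @export
tsne_embed <- function(pc_scores, perplexity = 30, seed = 1, ...) {
  n <- nrow(pc_scores)
  if (perplexity >= (n - 1) / 3)
    stop("perplexity too large: must be < (cells - 1) / 3 = ", (n - 1) / 3)
  with_seed(derive_seed(seed, "tsne"), {
    fit <- Rtsne::Rtsne(pc_scores, dims = 2, perplexity = perplexity,
                        pca = FALSE, check_duplicates = FALSE, ...)
    out <- fit$Y
    rownames(out) <- rownames(pc_scores)
    colnames(out) <- c("tsne1", "tsne2")
    out
  })
}

#' Shared-nearest-neighbor graph in PC space
#'
#' Each cell's neighbor set holds the cell itself plus its `k` nearest
#' neighbors (Euclidean distance in PC space, ties broken toward the lower
#' cell index); edge weights are the Jaccard overlap
#' `|N_k(i) intersect N_k(j)| / |N_k(i) union N_k(j)|`. Edges below the
#' pruning threshold are dropped.
#'
#' @param pc_scores cells x components matrix.
#' @param k neighborhood size.
#' @param prune minimum retained Jaccard weight (default 1/15).
#' @return class `snn_graph`: `edges` (`i`, `j`, `w` with `i < j`), `n`, `k`,
#'   `cell_ids`.
#' @export
build_snn_graph <- function(pc_scores, k = 20, prune = 1 / 15) {
  n <- nrow(pc_scores)
  stopifnot(k >= 1, k <= n - 1)
  d <- as.matrix(dist(pc_scores))
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    dv <- d[i, ]
    dv[i] <- Inf
    nb <- order(dv, seq_len(n))[seq_len(k)]
    A[i, c(i, nb)] <- 1L
  }
  M <- A %*% t(A)                     # |N(i) intersect N(j)|
  W <- M / (2 * (k + 1) - M)          # Jaccard, |union| = 2(k+1) - |intersect|
  W[W < prune] <- 0
  diag(W) <- 0
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2], w = W[idx])
  structure(list(edges = edges, n = n, k = k,
                 cell_ids = rownames(pc_scores) %||% as.character(seq_len(n))),
            class = "snn_graph")
}

#' Cluster a weighted graph by modularity maximization
#'
#' Louvain-style greedy modularity optimization with a fixed node-visit order
#' and deterministic tie-breaking (graphs of at most `exact_max` nodes are
#' instead solved exactly by enumeration), followed by evaluation of the
#' modularity Q of the returned partition with [modularity_q()].
#'
#' @param graph an `snn_graph` (or any list with `edges` and `n`).
#' @param exact_max largest node count solved by exhaustive enumeration.
#' @return class `cluster_result`: `labels` (integer per node, named by cell
#'   id), `n_clusters`, `Q`, and the `graph`.
#' @export
cluster_modularity <- function(graph, exact_max = 8) {
  if (is.null(graph$n) || graph$n == 0) stop("empty graph")
  if (is.null(graph$edges) || nrow(graph$edges) == 0) {
    labels <- seq_len(graph$n)
  } else {
    labels <- .maximize_modularity(graph$edges, graph$n, exact_max)
  }
  names(labels) <- graph$cell_ids %||% as.character(seq_len(graph$n))
  structure(list(labels = labels,
                 n_clusters = length(unique(labels)),
                 Q = modularity_q(graph$edges, labels, graph$n),
                 graph = graph),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", x$n_clusters, "clusters over",
      length(x$labels), "cells; Q =", round(x$Q, 4), "\n")
  print(table(x$labels))
  invisible(x)
}

#' One-vs-rest cluster marker detection
#'
#' For each cluster, genes are tested against all remaining cells with a
#' two-sided Wilcoxon rank-sum test on `log2(expected count + 1)` values.
#' Only genes with a log2 mean difference of at least `log2fc_min` and
#' detection in at least `min_pct` of the in-cluster cells are tested;
#' Benjamini-Hochberg FDR is computed across all performed tests.
#'
#' @param dataset a `umi_dataset`.
#' @param labels cluster label per cell.
#' @param log2fc_min minimum in-vs-out difference of mean log2 expression.
#' @param min_pct minimum in-cluster detection fraction.
#' @return `data.frame` with `gene`, `cluster`, `log2FC`, `p`, `FDR`,
#'   `pct_in`, `pct_out`, ordered by cluster then p.
#' @export
find_markers <- function(dataset, labels, log2fc_min = 0.25, min_pct = 0.10) {
  stopifnot(inherits(dataset, "umi_dataset"),
            length(labels) == ncol(dataset$counts))
  x <- log2p1(dataset$counts)
  res <- list()
  for (cl in sort(unique(labels))) {
    inc <- labels == cl
    if (!any(inc) || all(inc)) next
    m_in <- rowMeans(x[, inc, drop = FALSE])
    m_out <- rowMeans(x[, !inc, drop = FALSE])
    pct_in <- rowMeans(dataset$counts[, inc, drop = FALSE] > 0)
    pct_out <- rowMeans(dataset$counts[, !inc, drop = FALSE] > 0)
    lfc <- m_in - m_out
    pass <- which(lfc >= log2fc_min & pct_in >= min_pct)
    if (!length(pass)) next
    p <- vapply(pass, function(g)
      wilcox.test(x[g, inc], x[g, !inc], exact = FALSE)$p.value, 0)
    res[[as.character(cl)]] <- data.frame(
      gene = rownames(x)[pass], cluster = cl, log2FC = lfc[pass],
      p = p, pct_in = pct_in[pass], pct_out = pct_out[pass],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(gene = character(), cluster = integer(),
                      log2FC = numeric(), p = numeric(), FDR = numeric(),
                      pct_in = numeric(), pct_out = numeric()))
  out$FDR <- p.adjust(out$p, method = "BH")
  out <- out[order(out$cluster, out$p), c("gene", "cluster", "log2FC", "p",
                                          "FDR", "pct_in", "pct_out")]
  rownames(out) <- NULL
  out
}

#' Per-sample cluster composition
#'
#' The proportion of each cluster within each sample (cluster cell count
#' divided by the sample's total); rows sum to 1.
#'
#' @param labels cluster label per cell.
#' @param cell_meta `data.frame` with a `sample` column, rows aligned with
#'   `labels`.
#' @return samples x clusters proportion matrix.
#' @export
cluster_composition <- function(labels, cell_meta) {
  stopifnot(length(labels) == nrow(cell_meta))
  tab <- table(cell_meta$sample, labels)
  prop <- sweep(tab, 1, rowSums(tab), "/")
  as.matrix(prop)
}

#' Cluster-level mean expression, optionally min-max scaled per gene
#'
#' Means of `log2(expected count + 1)` per cluster, the quantity displayed in
#' cluster heatmaps. With `scale = TRUE` each gene's row is mapped to
#' `[0, 1]` (max -> 1, min -> 0; constant genes -> 0).
#'
#' @param dataset a `umi_dataset`.
#' @param labels cluster label per cell.
#' @param genes gene subset (default all).
#' @param scale min-max scale each gene across clusters.
#' @return genes x clusters matrix.
#' @export
summarize_cluster_means <- function(dataset, labels, genes = NULL,
                                    scale = FALSE) {
  x <- log2p1(dataset$counts)
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  cls <- sort(unique(labels))
  m <- sapply(cls, function(cl) rowMeans(x[, labels == cl, drop = FALSE]))
  colnames(m) <- as.character(cls)
  if (scale) {
    rng <- t(apply(m, 1, range))
    span <- rng[, 2] - rng[, 1]
    m <- (m - rng[, 1]) / ifelse(span > 0, span, 1)
  }
  m
}
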