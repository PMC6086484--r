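#' Filter transcription-factor genes for network analysis
#'
#' Keeps genes that appear on the TF list, are detected (nonzero) in at least
#' `min_cells` cells, and have variance of `log2(expected count + 1)` above
#' `min_variance` — removing noisy, rarely detected and flat genes before
#' correlation analysis.
#'
#' @param dataset a `umi_dataset`.
#' @param tf_list character vector of TF symbols or a path to a
#'   one-symbol-per-line file; matching is case-insensitive.
#' @param min_cells minimum number of cells with nonzero counts.
#' @param min_variance minimum log2-scale variance.
#' @param cells optional cell subset (indices, ids or logical) on which the
#'   filters and downstream correlations are evaluated, e.g. the
#'   conversion-continuum cells.
#' @return character vector of retained TF genes.
#' @export
filter_tf_genes <- function(dataset, tf_list, min_cells = 10,
                            min_variance = 0.4, cells = NULL) {
  if (length(tf_list) == 1 && file.exists(tf_list))
    tf_list <- read_gene_list(tf_list)
  counts <- dataset$counts
  if (!is.null(cells)) counts <- counts[, cells, drop = FALSE]
  on_list <- tolower(rownames(counts)) %in% tolower(tf_list)
  detected <- rowSums(counts > 0) >= min_cells
  v <- apply(log2p1(counts), 1, var)
  rownames(counts)[on_list & detected & v > min_variance]
}

#' Pairwise Pearson correlation network over TF genes
#'
#' Computes Pearson correlations of `log2(expected count + 1)` between all
#' pairs of node genes and connects pairs whose squared correlation exceeds
#' the threshold; the sign of r is retained on the edge.
#'
#' @param dataset a `umi_dataset`.
#' @param nodes node gene symbols (see [filter_tf_genes()]).
#' @param r2_threshold minimum squared Pearson correlation for an edge.
#' @param cells optional cell subset.
#' @return class `tf_network`: `nodes`, `edges` (`gene_i`, `gene_j`, `r`,
#'   `r2`), `r2_threshold`, and the full correlation matrix `cor_matrix`.
#' @export
correlation_network <- function(dataset, nodes, r2_threshold = 0.25,
                                cells = NULL) {
  counts <- dataset$counts
  if (!is.null(cells)) counts <- counts[, cells, drop = FALSE]
  x <- t(log2p1(counts[nodes, , drop = FALSE]))
  R <- cor(x)
  idx <- which(upper.tri(R) & R^2 > r2_threshold, arr.ind = TRUE)
  edges <- data.frame(gene_i = nodes[idx[, 1]], gene_j = nodes[idx[, 2]],
                      r = R[idx], r2 = R[idx]^2,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 r2_threshold = r2_threshold, cor_matrix = R),
            class = "tf_network")
}

#' @export
print.tf_network <- function(x, ...) {
  cat("tf_network:", length(x$nodes), "TF nodes,", nrow(x$edges),
      "edges (r^2 >", x$r2_threshold, ")\n")
  invisible(x)
}

#' Detect communities in a TF network by modularity maximization
#'
#' Runs the package's deterministic Louvain engine on the unweighted edge
#' set, reports the modularity Q of the partition, and names the top-degree
#' hub gene(s) of each community.
#'
#' @param network a [correlation_network()] result.
#' @return the network with added `communities` (named membership vector),
#'   `Q`, `degree`, and `hubs` (one top-degree gene per community).
#' @export
detect_communities <- function(network) {
  nodes <- network$nodes
  ei <- match(network$edges$gene_i, nodes)
  ej <- match(network$edges$gene_j, nodes)
  edges <- data.frame(i = ei, j = ej, w = rep(1, length(ei)))
  memb <- if (nrow(edges)) .maximize_modularity(edges, length(nodes))
          else seq_along(nodes)
  names(memb) <- nodes
  deg <- setNames(numeric(length(nodes)), nodes)
  for (k in seq_len(nrow(edges))) {
    deg[ei[k]] <- deg[ei[k]] + 1
    deg[ej[k]] <- deg[ej[k]] + 1
  }
  hubs <- vapply(sort(unique(memb)), function(cm) {
    g <- nodes[memb == cm]
    g[order(-deg[g], g)][1]
  }, "")
  network$communities <- memb
  network$Q <- modularity_q(edges, memb, length(nodes))
  network$degree <- deg
  network$hubs <- hubs
  network
}
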