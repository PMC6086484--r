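#' Select ordering genes for trajectory inference
#'
#' Keeps genes whose mean expected count (after censoring values below the
#' detection limit) is at least `min_mean` and whose empirical dispersion
#' (variance / mean) is at least `min_dispersion`.
#'
#' @param dataset a `umi_dataset`.
#' @param min_mean minimum mean expected count.
#' @param min_dispersion minimum variance/mean ratio.
#' @param lower_detection_limit expression values below this are treated as 0.
#' @return character vector of ordering genes.
#' @export
select_ordering_genes <- function(dataset, min_mean = 0.1,
                                  min_dispersion = 1.0,
                                  lower_detection_limit = 0.5) {
  x <- dataset$counts
  x[x < lower_detection_limit] <- 0
  mu <- rowMeans(x)
  v <- apply(x, 1, var)
  disp <- ifelse(mu > 0, v / mu, 0)
  rownames(x)[mu >= min_mean & disp >= min_dispersion]
}

#' Fit a principal tree to cells in ordering-gene PC space
#'
#' A documented simplification of reversed-graph-embedding trajectory
#' methods: k-means centroids in the PC space of the ordering genes are
#' joined by a minimum spanning tree, and every cell is projected
#' orthogonally onto its nearest tree edge. The result supports geodesic
#' pseudotime from any root.
#'
#' @param dataset a `umi_dataset`.
#' @param ordering_genes genes used for the embedding
#'   (see [select_ordering_genes()]).
#' @param n_centroids number of k-means centroids (>= 2).
#' @param n_pcs PCs of the ordering-gene matrix to use.
#' @param seed integer seed (k-means initialization); the fit is
#'   deterministic under it.
#' @return class `trajectory`: `centroids`, `edges` (`a`, `b`, `len`),
#'   `cell_edge`, `cell_offset` (position in `[0, 1]` along the edge from
#'   `a`), `scores`, `ordering_genes`.
#' @export
fit_principal_tree <- function(dataset, ordering_genes, n_centroids = 10,
                               n_pcs = 10, seed = 1) {
  stopifnot(inherits(dataset, "umi_dataset"))
  if (n_centroids < 2) stop("n_centroids must be >= 2")
  if (ncol(dataset$counts) < n_centroids)
    stop("fewer cells than centroids")
  x <- log2p1(dataset$counts[ordering_genes, , drop = FALSE])
  pc <- pca_embed(x, n_components = n_pcs)
  S <- pc$scores
  km <- with_seed(derive_seed(seed, "tree"),
                  kmeans(S, centers = n_centroids, nstart = 10,
                         iter.max = 100))
  C <- km$centers
  D <- as.matrix(dist(C))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  mstg <- igraph::mst(g)
  el <- igraph::as_edgelist(mstg, names = FALSE)
  edges <- data.frame(a = pmin(el[, 1], el[, 2]),
                      b = pmax(el[, 1], el[, 2]))
  edges$len <- sqrt(rowSums((C[edges$a, , drop = FALSE] -
                             C[edges$b, , drop = FALSE])^2))
  edges <- edges[order(edges$a, edges$b), ]
  rownames(edges) <- NULL

  n <- nrow(S)
  cell_edge <- integer(n); cell_off <- numeric(n)
  for (i in seq_len(n)) {
    p <- S[i, ]
    best <- c(Inf, NA, NA)
    for (e in seq_len(nrow(edges))) {
      A <- C[edges$a[e], ]; B <- C[edges$b[e], ]
      ab <- B - A
      t <- sum((p - A) * ab) / sum(ab * ab)
      t <- min(max(t, 0), 1)
      d2 <- sum((A + t * ab - p)^2)
      if (d2 < best[1] - 1e-12) best <- c(d2, e, t)
    }
    cell_edge[i] <- best[2]; cell_off[i] <- best[3]
  }
  structure(list(centroids = C, edges = edges,
                 cell_edge = setNames(cell_edge, rownames(S)),
                 cell_offset = setNames(cell_off, rownames(S)),
                 scores = S, ordering_genes = ordering_genes),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  deg <- table(c(x$edges$a, x$edges$b))
  cat("trajectory:", nrow(x$centroids), "centroids,", nrow(x$edges),
      "tree edges,", length(x$cell_edge), "cells;",
      sum(deg >= 3), "branch point(s)\n")
  invisible(x)
}

#' Assign geodesic pseudotime along a principal tree
#'
#' Pseudotime is the geodesic distance along the tree from the root centroid
#' to each cell's projected position, normalized to `[0, 1]`. The root
#' centroid is the tree node nearest to the centroid of the root cluster's
#' cells (or a node index given directly).
#'
#' @param trajectory a [fit_principal_tree()] result.
#' @param labels per-cell cluster/population labels (used with
#'   `root_cluster`).
#' @param root_cluster label of the starting population.
#' @param root_node alternatively, a centroid index to use as root.
#' @return list with `tau` (named pseudotime per cell), `root_node`, and
#'   `branch` (index of the root-adjacent subtree each cell lies in).
#' @export
assign_pseudotime <- function(trajectory, labels = NULL, root_cluster = NULL,
                              root_node = NULL) {
  tr <- trajectory
  C <- tr$centroids
  if (is.null(root_node)) {
    if (is.null(labels) || is.null(root_cluster))
      stop("supply either root_node or labels + root_cluster")
    i <- which(labels == root_cluster)
    if (!length(i)) stop("no cells carry the root cluster label")
    ctr <- colMeans(tr$scores[i, , drop = FALSE])
    root_node <- which.min(colSums((t(C) - ctr)^2))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = tr$edges$a, to = tr$edges$b, weight = tr$edges$len),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(C))))
  dn <- as.numeric(igraph::distances(g, v = as.character(root_node)))
  a <- tr$edges$a[tr$cell_edge]; b <- tr$edges$b[tr$cell_edge]
  len <- tr$edges$len[tr$cell_edge]
  off <- tr$cell_offset
  d_cell <- pmin(dn[a] + off * len, dn[b] + (1 - off) * len)
  tau <- if (max(d_cell) > 0) d_cell / max(d_cell) else d_cell
  ## branch: the root-adjacent neighbor on the path to the cell's far node
  far <- ifelse(dn[a] >= dn[b], a, b)
  paths <- igraph::shortest_paths(g, from = as.character(root_node),
                                  to = igraph::V(g))$vpath
  first_step <- vapply(paths, function(p)
    if (length(p) >= 2) as.integer(names(p)[2]) else as.integer(root_node), 0L)
  branch <- first_step[far]
  list(tau = setNames(tau, names(tr$cell_edge)),
       root_node = root_node,
       branch = setNames(branch, names(tr$cell_edge)))
}

#' Test genes for pseudotime dependence
#'
#' Per gene, a likelihood-ratio test (Gaussian working model on
#' `log2(expected count + 1)`) of a natural cubic spline of pseudotime
#' (`df` degrees of freedom) against an intercept-only model, with
#' Benjamini-Hochberg FDR across genes. A branch label may be included as an
#' additive covariate in both models to test pseudotime beyond branch
#' membership.
#'
#' @param dataset a `umi_dataset`.
#' @param tau pseudotime per cell, in `[0, 1]`.
#' @param genes gene subset (default all).
#' @param df spline degrees of freedom.
#' @param branch optional per-cell branch factor.
#' @return `data.frame` with `gene`, `lrt`, `df`, `p`, `FDR`.
#' @export
test_pseudotime_dependence <- function(dataset, tau, genes = NULL, df = 3,
                                       branch = NULL) {
  x <- log2p1(dataset$counts)
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  stopifnot(ncol(x) == length(tau))
  n <- length(tau)
  B <- splines::ns(tau, df = df)
  X1 <- cbind(1, B)
  X0 <- matrix(1, n, 1)
  if (!is.null(branch) && length(unique(branch)) > 1) {
    Bm <- stats::model.matrix(~ factor(branch))[, -1, drop = FALSE]
    X1 <- cbind(X1, Bm); X0 <- cbind(X0, Bm)
  }
  fit_rss <- function(X, y) {
    f <- stats::lm.fit(X, y)
    sum(f$residuals^2)
  }
  lrt <- p <- numeric(nrow(x))
  for (g in seq_len(nrow(x))) {
    y <- x[g, ]
    r1 <- fit_rss(X1, y); r0 <- fit_rss(X0, y)
    if (r1 <= 0 || r0 <= 0) { lrt[g] <- 0; p[g] <- 1; next }
    lrt[g] <- n * log(r0 / r1)
    p[g] <- pchisq(lrt[g], df = df, lower.tail = FALSE)
  }
  data.frame(gene = rownames(x), lrt = lrt, df = df, p = p,
             FDR = p.adjust(p, "BH"), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Binned pseudotime expression profiles
#'
#' Mean `log2(expected count + 1)` per gene in `n_bins` equal-width
#' pseudotime bins spanning `[0, 1]`; empty bins are filled by linear
#' interpolation (constant extrapolation at the ends). Optionally min-max
#' scales each gene's profile.
#'
#' @param dataset a `umi_dataset`.
#' @param tau pseudotime per cell.
#' @param genes genes to profile (default all).
#' @param n_bins number of bins (default 100).
#' @param scale min-max scale each gene.
#' @return genes x bins matrix; column names are bin midpoints.
#' @export
bin_pseudotime_profiles <- function(dataset, tau, genes = NULL,
                                    n_bins = 100, scale = FALSE) {
  x <- log2p1(dataset$counts)
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  br <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(pmin(pmax(tau, 0), 1), breaks = br, include.lowest = TRUE,
             labels = FALSE)
  mids <- (br[-1] + br[-length(br)]) / 2
  prof <- matrix(NA_real_, nrow(x), n_bins,
                 dimnames = list(rownames(x), signif(mids, 4)))
  for (b in seq_len(n_bins)) {
    i <- which(bin == b)
    if (length(i)) prof[, b] <- rowMeans(x[, i, drop = FALSE])
  }
  filled <- which(!is.na(prof[1, ]))
  if (length(filled) < n_bins && length(filled) >= 2) {
    for (g in seq_len(nrow(prof)))
      prof[g, ] <- approx(mids[filled], prof[g, filled], xout = mids,
                          rule = 2)$y
  }
  if (scale) {
    rng <- t(apply(prof, 1, range))
    span <- rng[, 2] - rng[, 1]
    prof <- (prof - rng[, 1]) / ifelse(span > 0, span, 1)
  }
  prof
}

#' Correlation and fold change of the Atoh1 transgene vs endogenous Atoh1
#'
#' Squared Pearson correlation between the HA-tagged transgene and endogenous
#' Atoh1 on `log2(expected count + 1)` over cells expressing either feature,
#' and the fold change of transgene expression between two named clusters on
#' the linear expected-count scale.
#'
#' @param dataset a `umi_dataset` with flagged `special_features`.
#' @param labels per-cell cluster/population labels.
#' @param cluster_high,cluster_low clusters whose linear mean ratio is
#'   reported (default the most- and least-converted cHC states).
#' @return list with `r_squared`, `fold_change`, `n_cells`.
#' @export
transgene_correlation <- function(dataset, labels,
                                  cluster_high = "cHC3",
                                  cluster_low = "cHC1") {
  sf <- dataset$special_features
  endo <- dataset$counts[sf[["atoh1_endogenous"]], ]
  ha <- dataset$counts[sf[["atoh1_ha"]], ]
  use <- endo > 0 | ha > 0
  r <- cor(log2p1(endo[use]), log2p1(ha[use]))
  hi <- labels == cluster_high; lo <- labels == cluster_low
  if (!any(hi) || !any(lo)) stop("named clusters not found in labels")
  fold <- mean(ha[hi]) / mean(ha[lo])
  list(r_squared = r^2, fold_change = fold, n_cells = sum(use))
}
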