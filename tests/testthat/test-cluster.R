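test_that("PCA reproduces hand-computed structure", {
  ## rank-1 matrix: one nonzero component
  x <- outer(c(1, 2, 3), c(1, 2, 3, 4))
  p <- pca_embed(x, 3)
  expect_gt(p$variance_explained[1], 1e-10)
  expect_true(all(p$variance_explained[-1] < 1e-20))
  ## 2 genes x 2 cells, hand eigendecomposition: cells at (0,0) and (2,2)
  ## center -> (-1,-1), (1,1); first PC direction (1,1)/sqrt(2), scores -+sqrt(2)
  y <- matrix(c(0, 0, 2, 2), 2, 2)
  p2 <- pca_embed(y, 2)
  expect_equal(abs(p2$scores[, 1]), c(sqrt(2), sqrt(2)), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## variance_explained sums to the total variance over cells
  set.seed(1)
  z <- matrix(rnorm(50), 5, 10)
  p3 <- pca_embed(z, 5)
  expect_equal(sum(p3$variance_explained), sum(apply(t(z), 2, var)))
})

test_that("t-SNE is deterministic under seed and separates distant blobs", {
  set.seed(2)
  pc <- rbind(matrix(rnorm(50 * 5), 50, 5),
              matrix(rnorm(50 * 5, mean = 25), 50, 5))
  lab <- rep(c("a", "b"), each = 50)
  e1 <- tsne_embed(pc, perplexity = 10, seed = 3)
  e2 <- tsne_embed(pc, perplexity = 10, seed = 3)
  expect_identical(e1, e2)
  expect_gt(mean_silhouette(e1, lab), 0.5)
  expect_error(tsne_embed(pc, perplexity = 40), "perplexity")
})

test_that("SNN weights are Jaccard overlaps with deterministic ties", {
  ## k = n-1: every pair shares all neighbors except each other
  set.seed(4)
  pc <- matrix(rnorm(12 * 3), 12, 3)
  g <- build_snn_graph(pc, k = 11, prune = 0)
  expect_equal(nrow(g$edges), choose(12, 2))
  expect_true(all(abs(g$edges$w - 1) < 1e-12))
  ## two distant pairs, k = 1: neighbor sets disjoint across pairs
  pc2 <- matrix(c(0, 0.1, 100, 100.1, 0, 0, 0, 0), 4, 2)
  g2 <- build_snn_graph(pc2, k = 1, prune = 0)
  w <- matrix(0, 4, 4)
  w[cbind(g2$edges$i, g2$edges$j)] <- g2$edges$w
  expect_equal(w[1, 2], 1)   # mutual neighbors
  expect_equal(w[3, 4], 1)
  expect_true(all(w[1:2, 3:4] == 0))
  ## weights bounded and no self-edges
  expect_true(all(g$edges$w > 0 & g$edges$w <= 1 & g$edges$i < g$edges$j))
})

test_that("modularity Q matches the brute-force formula on arbitrary partitions", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    full <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pick <- sample(nrow(full), sample(3:nrow(full), 1))
    edges <- data.frame(i = full[pick, 1], j = full[pick, 2],
                        w = runif(length(pick), 0.2, 2))
    memb <- sample(1:3, n, replace = TRUE)
    m <- sum(edges$w)
    deg <- numeric(n)
    for (k in seq_len(nrow(edges))) {
      deg[edges$i[k]] <- deg[edges$i[k]] + edges$w[k]
      deg[edges$j[k]] <- deg[edges$j[k]] + edges$w[k]
    }
    q_direct <- 0
    for (cc in unique(memb)) {
      inc <- memb == cc
      Lc <- sum(edges$w[inc[edges$i] & inc[edges$j]])
      q_direct <- q_direct + Lc / m - (sum(deg[inc]) / (2 * m))^2
    }
    expect_equal(modularity_q(edges, memb, n), q_direct)
  }
})

test_that("modularity clustering solves small graphs exactly", {
  ## two 3-cliques joined by one edge: optimum splits the cliques, Q = 5/14
  cliq <- data.frame(i = c(1, 1, 2, 4, 4, 5, 3),
                     j = c(2, 3, 3, 5, 6, 6, 4),
                     w = 1)
  g <- list(edges = cliq, n = 6, cell_ids = as.character(1:6))
  res <- cluster_modularity(g)
  expect_equal(res$n_clusters, 2)
  expect_equal(unname(res$labels[1:3]), rep(res$labels[[1]], 3))
  expect_equal(unname(res$labels[4:6]), rep(res$labels[[4]], 3))
  expect_equal(res$Q, 5 / 14, tolerance = 1e-12)
  expect_equal(res$Q, best_partition_q(cliq, 6), tolerance = 1e-12)
})

test_that("modularity optimum matches exhaustive enumeration on small graphs", {
  graphs <- list(
    ## complete K5: no split beats the single community (Q = 0)
    k5 = local({
      idx <- which(upper.tri(matrix(0, 5, 5)), arr.ind = TRUE)
      data.frame(i = idx[, 1], j = idx[, 2], w = 1)
    }),
    ## two disjoint triangles
    tri2 = data.frame(i = c(1, 1, 2, 4, 4, 5), j = c(2, 3, 3, 5, 6, 6), w = 1),
    ## path of 6 nodes
    path = data.frame(i = 1:5, j = 2:6, w = 1),
    ## star on 7 nodes
    star = data.frame(i = rep(1, 6), j = 2:7, w = 1),
    ## weighted barbell
    barbell = data.frame(i = c(1, 1, 2, 3, 4, 4, 5),
                         j = c(2, 3, 3, 4, 5, 6, 6),
                         w = c(2, 2, 2, 0.5, 1, 1, 1)))
  sizes <- c(k5 = 5, tri2 = 6, path = 6, star = 7, barbell = 6)
  for (nm in names(graphs)) {
    ed <- graphs[[nm]]
    names(ed)[1:2] <- c("i", "j")
    res <- cluster_modularity(list(edges = ed, n = sizes[[nm]]))
    expect_equal(res$Q, best_partition_q(ed, sizes[[nm]]), tolerance = 1e-10,
                 info = nm)
  }
  ## complete graph collapses to one community
  res_k5 <- cluster_modularity(list(edges = graphs$k5, n = 5))
  expect_equal(res_k5$n_clusters, 1)
  ## disconnected components are never split at the optimum here
  res_tri <- cluster_modularity(list(edges = graphs$tri2, n = 6))
  expect_equal(res_tri$n_clusters, 2)
  expect_error(cluster_modularity(list(edges = NULL, n = 0)), "empty")
})

test_that("clustering agrees with igraph's Louvain on a sizeable graph", {
  set.seed(6)
  pc <- rbind(matrix(rnorm(60 * 4), 60, 4),
              matrix(rnorm(60 * 4, 8), 60, 4),
              matrix(rnorm(60 * 4, -8), 60, 4))
  g <- build_snn_graph(pc, k = 10)
  res <- cluster_modularity(g)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = g$edges$i, to = g$edges$j, weight = g$edges$w),
    directed = FALSE, vertices = data.frame(name = 1:g$n))
  ref <- igraph::cluster_louvain(ig)
  expect_gte(res$Q + 1e-6, max(ref$modularity) * 0.98)
  expect_equal(res$n_clusters, 3)
})

test_that("default preset clusters recover the true populations", {
  ds <- gen_umi_dataset(sim_config(seed = 21))
  pp <- downsample_to_reference_depth(filter_cells_by_library_size(ds),
                                      seed = 21)
  hvg <- select_hvg(pp)
  pc <- pca_embed(log2(pp$counts[hvg$genes, ] + 1), 30)
  cl <- cluster_modularity(build_snn_graph(pc$scores, k = 20))
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(cl$labels, pp$cell_meta$true_population)
  expect_gte(ari, 0.9)
  expect_true(cl$Q >= -0.5 && cl$Q <= 1)
})

test_that("marker detection flags exclusive genes and respects its filters", {
  set.seed(7)
  m <- matrix(rpois(40 * 60, 3), 40, 60)
  m <- rbind(m, c(rep(8L, 30), rep(0L, 30)))   # exclusive to cluster 1
  ds <- make_dataset(m)
  labels <- rep(1:2, each = 30)
  mk <- find_markers(ds, labels)
  top1 <- mk[mk$cluster == 1, ][1, ]
  expect_equal(top1$gene, "g41")
  expect_equal(top1$pct_out, 0)
  ## BH monotone consistency
  for (cl in unique(mk$cluster)) {
    sub <- mk[mk$cluster == cl, ]
    expect_true(all(diff(sub$FDR[order(sub$p)]) >= -1e-12))
  }
  ## identical clusters produce no markers
  ds2 <- make_dataset(cbind(m, m))
  mk2 <- find_markers(ds2, rep(1:2, each = 60))
  expect_true(all(abs(mk2$log2FC) < 0.25) || nrow(mk2) == 0)
})

test_that("permuted labels yield about the nominal number of FDR hits", {
  set.seed(8)
  m <- matrix(rpois(200 * 80, 4), 200, 80)
  ds <- make_dataset(m)
  hits <- vapply(1:20, function(i) {
    lab <- sample(rep(1:2, each = 40))
    mk <- find_markers(ds, lab)
    sum(mk$FDR < 0.05)
  }, 0)
  expect_lte(median(hits), 2)
})

test_that("cluster composition sums to one per sample", {
  meta <- data.frame(sample = rep(c("s1", "s2"), c(10, 20)))
  labels <- c(rep(1, 10), rep(1, 6), rep(2, 14))
  comp <- cluster_composition(labels, meta)
  expect_equal(unname(rowSums(comp)), c(1, 1))
  expect_equal(comp["s2", "1"], 0.3)
  expect_equal(comp["s2", "2"], 0.7)
  expect_equal(comp["s1", "1"], 1)
})

test_that("replicate samples of the preset have similar cluster composition", {
  ds <- gen_umi_dataset(sim_config(seed = 22))
  pp <- downsample_to_reference_depth(filter_cells_by_library_size(ds),
                                      seed = 22)
  hvg <- select_hvg(pp)
  pc <- pca_embed(log2(pp$counts[hvg$genes, ] + 1), 30)
  cl <- cluster_modularity(build_snn_graph(pc$scores, k = 20))
  comp <- cluster_composition(cl$labels, pp$cell_meta)
  conds <- unique(pp$cell_meta$condition)
  for (cond in conds) {
    reps <- rownames(comp)[startsWith(rownames(comp), cond)]
    if (length(reps) == 2)
      expect_true(all(abs(comp[reps[1], ] - comp[reps[2], ]) < 0.1))
  }
})

test_that("cluster means match brute-force group means and min-max scaling", {
  set.seed(9)
  m <- matrix(rpois(15 * 30, 6), 15, 30)
  m[3, ] <- 4L                                 # constant gene
  ds <- make_dataset(m)
  labels <- rep(1:3, each = 10)
  mm <- summarize_cluster_means(ds, labels)
  x <- log2(m + 1)
  expect_equal(mm[5, "2"], mean(x[5, 11:20]))
  sc <- summarize_cluster_means(ds, labels, scale = TRUE)
  expect_true(all(apply(sc[-3, ], 1, max) == 1))
  expect_true(all(apply(sc[-3, ], 1, min) == 0))
  expect_true(all(sc[3, ] == sc[3, 1]))        # constant gene row equal
})
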