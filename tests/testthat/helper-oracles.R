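## Independent oracles and fixture builders used across the suite. These are
## deliberately naive re-derivations (brute force, enumeration, closed form)
## kept separate from the package's own code paths.

## wrap a raw count matrix into a minimal umi_dataset
make_dataset <- function(counts, samples = NULL, populations = NULL,
                         special = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  meta <- data.frame(
    cell_id = colnames(counts),
    sample = samples %||% rep("s1", ncol(counts)),
    condition = samples %||% rep("s1", ncol(counts)),
    true_population = populations %||% rep("P1", ncol(counts)),
    true_latent = NA_real_,
    stringsAsFactors = FALSE)
  rownames(meta) <- meta$cell_id
  structure(list(counts = counts, gene_names = rownames(counts),
                 cell_ids = colnames(counts), cell_meta = meta,
                 special_features = special, truth = NULL, config = NULL),
            class = "umi_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## all set partitions of 1..n (restricted growth strings)
set_partitions <- function(n) {
  out <- list()
  rec <- function(a, mx) {
    k <- length(a) + 1
    if (k > n) { out[[length(out) + 1]] <<- a; return(invisible()) }
    for (v in seq_len(mx + 1)) rec(c(a, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

## exhaustive maximum-modularity partition for small graphs
best_partition_q <- function(edges, n) {
  best <- -Inf
  for (p in set_partitions(n)) {
    q <- modularity_q(edges, p, n)
    if (q > best) best <- q
  }
  best
}

## direct weighted-TMM implementation following the published recipe:
## trim 30% of M values and 5% of A values two-sided, inverse-variance
## weights, factors rescaled to geometric mean 1
tmm_oracle <- function(counts, ref = 1) {
  N <- colSums(counts)
  f <- vapply(seq_len(ncol(counts)), function(k) {
    if (k == ref) return(1)
    x <- counts[, k]; r <- counts[, ref]
    keep <- x > 0 & r > 0
    x <- x[keep]; r <- r[keep]
    M <- log2((x / N[k]) / (r / N[ref]))
    A <- 0.5 * log2((x / N[k]) * (r / N[ref]))
    w <- (N[k] - x) / (N[k] * x) + (N[ref] - r) / (N[ref] * r)
    n <- length(M)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep2 <- rank(M) >= loL & rank(M) <= hiL &
      rank(A) >= loS & rank(A) <= hiS
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, 0)
  f / exp(mean(log(f)))
}

## mean silhouette width of a labelling on a coordinate matrix
mean_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  n <- nrow(coords)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(unique(labels[!own]), function(l)
      mean(d[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

## preprocessed default continuum preset (shared by trajectory/network tests)
continuum_dataset <- function(seed, cells = 150) {
  cfg <- sim_config(population_names = c("SC1", "cHC1", "cHC2", "cHC3"),
                    cells_per_population = cells, seed = seed)
  ds <- gen_umi_dataset(cfg)
  downsample_to_reference_depth(filter_cells_by_library_size(ds), seed = seed)
}
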