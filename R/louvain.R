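## Weighted Louvain modularity maximization with a fixed node-visit order and
## deterministic tie-breaking (toward the lower community label), so repeated
## runs on the same graph give identical partitions. Used both for SNN cell
## clustering and for TF co-expression communities.

#' Modularity Q of a partition
#'
#' Evaluates `Q = sum_c [ L_c / m - (d_c / 2m)^2 ]` on a weighted undirected
#' graph, where `L_c` is the total weight of intra-community edges, `d_c` the
#' total weighted degree of community `c`, and `m` the total edge weight.
#'
#' @param edges `data.frame` with columns `i`, `j` (1-based node indices,
#'   `i != j`) and optionally `w` (weights, default 1).
#' @param membership integer community label per node.
#' @param n_nodes number of nodes (defaults to `length(membership)`).
#' @return the scalar Q.
#' @export
modularity_q <- function(edges, membership, n_nodes = length(membership)) {
  w <- edges$w %||% rep(1, nrow(edges))
  m <- sum(w)
  if (m == 0) return(0)
  deg <- numeric(n_nodes)
  for (k in seq_along(w)) {
    deg[edges$i[k]] <- deg[edges$i[k]] + w[k]
    deg[edges$j[k]] <- deg[edges$j[k]] + w[k]
  }
  intra <- tapply(w[membership[edges$i] == membership[edges$j]],
                  membership[edges$i][membership[edges$i] == membership[edges$j]],
                  sum)
  Lc <- rep(0, length(unique(membership)))
  names(Lc) <- as.character(sort(unique(membership)))
  if (length(intra)) Lc[names(intra)] <- intra
  dc <- tapply(deg, membership, sum)[names(Lc)]
  sum(Lc / m - (dc / (2 * m))^2)
}

## Exact maximum-modularity partition by enumerating restricted growth
## strings; tractable for graphs of up to ~10 nodes. Greedy agglomeration
## has local optima even on toy graphs (e.g. a 6-node path), so small
## problems are solved exactly.
.modularity_exact <- function(edges, n_nodes) {
  best_q <- -Inf
  best <- seq_len(n_nodes)
  a <- integer(n_nodes)
  rec <- function(k, mx) {
    if (k > n_nodes) {
      q <- modularity_q(edges, a[seq_len(n_nodes)], n_nodes)
      if (q > best_q) { best_q <<- q; best <<- a[seq_len(n_nodes)] }
      return(invisible())
    }
    for (v in seq_len(mx + 1)) {
      a[k] <<- v
      rec(k + 1, max(mx, v))
    }
  }
  rec(1L, 0L)
  best
}

## dispatch: exact enumeration for tiny graphs, Louvain otherwise
.maximize_modularity <- function(edges, n_nodes, exact_max = 8) {
  memb <- if (n_nodes <= exact_max) .modularity_exact(edges, n_nodes)
          else .louvain(edges, n_nodes)
  match(memb, unique(memb))
}

## One Louvain level on an adjacency-list graph with self-loop weights.
## Returns the local community assignment (labels in 1..n).
.louvain_one_level <- function(n, nbr, nbrw, selfw, m2) {
  deg <- vapply(seq_len(n), function(v) sum(nbrw[[v]]), 0) + 2 * selfw
  comm <- seq_len(n)
  tot <- deg
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (v in seq_len(n)) {
      cv <- comm[v]
      if (!length(nbr[[v]])) next
      links <- tapply(nbrw[[v]], comm[nbr[[v]]], sum)
      tot[cv] <- tot[cv] - deg[v]
      link_vec <- as.numeric(links)
      cand <- as.integer(names(links))
      if (!(cv %in% cand)) { cand <- c(cand, cv); link_vec <- c(link_vec, 0) }
      ## gain of joining community c with v removed from the graph:
      ## k_{v->c} - tot_c * deg_v / m2
      gains <- link_vec - tot[cand] * deg[v] / m2
      ord <- order(-gains, cand)
      best <- cand[ord[1]]
      cur_gain <- gains[match(cv, cand)]
      if (best != cv && gains[ord[1]] > cur_gain + 1e-12) {
        comm[v] <- best
        tot[best] <- tot[best] + deg[v]
        moved <- TRUE; moved_any <- TRUE
      } else {
        comm[v] <- cv
        tot[cv] <- tot[cv] + deg[v]
      }
    }
    if (!moved) break
  }
  list(comm = comm, moved = moved_any)
}

## Full Louvain: returns membership (1..K, relabeled by first appearance)
.louvain <- function(edges, n_nodes) {
  w <- edges$w %||% rep(1, nrow(edges))
  ei <- as.integer(edges$i); ej <- as.integer(edges$j)
  selfw <- numeric(n_nodes)
  node_map <- seq_len(n_nodes)   # original node -> current meta-node
  n <- n_nodes
  repeat {
    nbr <- vector("list", n); nbrw <- vector("list", n)
    for (k in seq_along(ei)) {
      nbr[[ei[k]]] <- c(nbr[[ei[k]]], ej[k])
      nbrw[[ei[k]]] <- c(nbrw[[ei[k]]], w[k])
      nbr[[ej[k]]] <- c(nbr[[ej[k]]], ei[k])
      nbrw[[ej[k]]] <- c(nbrw[[ej[k]]], w[k])
    }
    m2 <- 2 * (sum(w) + sum(selfw))
    if (m2 == 0) break
    lev <- .louvain_one_level(n, nbr, nbrw, selfw, m2)
    if (!lev$moved) break
    ## relabel communities 1..K and aggregate
    labs <- sort(unique(lev$comm))
    re <- match(lev$comm, labs)
    node_map <- re[node_map]
    K <- length(labs)
    new_selfw <- numeric(K)
    for (c0 in seq_len(K)) new_selfw[c0] <- sum(selfw[re == c0])
    agg <- new.env(parent = emptyenv())
    for (k in seq_along(ei)) {
      a <- re[ei[k]]; b <- re[ej[k]]
      if (a == b) { new_selfw[a] <- new_selfw[a] + w[k]; next }
      key <- paste(min(a, b), max(a, b))
      assign(key, (get0(key, envir = agg) %||% 0) + w[k], envir = agg)
    }
    keys <- ls(agg)
    if (!length(keys)) { selfw <- new_selfw; n <- K; ei <- integer(); ej <- integer(); w <- numeric(); next }
    parts <- do.call(rbind, strsplit(keys, " "))
    ei <- as.integer(parts[, 1]); ej <- as.integer(parts[, 2])
    w <- vapply(keys, function(k) get(k, envir = agg), 0, USE.NAMES = FALSE)
    selfw <- new_selfw
    n <- K
  }
  match(node_map, sort(unique(node_map)))
}
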