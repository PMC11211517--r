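# Independent brute-force oracles. These deliberately avoid igraph and the
# package's own graph code: plain adjacency-list BFS, recursive path
# enumeration and exhaustive subset search, so oracle agreement is a real
# dual-route check.

# adjacency list of traversable arcs: directed edges forward only,
# undirected edges both ways (or everything symmetric when mode=undirected)
oracleAdj <- function(edge_df, nodes, mode = "directed") {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edge_df))) {
    s <- edge_df$source_id[i]; t <- edge_df$target_id[i]
    adj[[s]] <- c(adj[[s]], t)
    if (!edge_df$directed[i] || mode == "undirected")
      adj[[t]] <- c(adj[[t]], s)
  }
  lapply(adj, unique)
}

# BFS distances from one node; Inf for unreachable
oracleBfsDist <- function(adj, from) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (is.infinite(d[w])) {
      d[w] <- d[v] + 1
      queue <- c(queue, w)
    }
  }
  d
}

# every shortest path from -> to, via recursive descent on the BFS distance
# field; returns list of node-id vectors
oracleAllShortestPaths <- function(adj, from, to) {
  if (from == to) return(list(from))
  dist <- oracleBfsDist(adj, from)
  if (is.infinite(dist[to])) return(list())
  walk <- function(v) {
    if (v == from) return(list(from))
    preds <- names(adj)[vapply(names(adj), function(u)
      v %in% adj[[u]] && dist[u] == dist[v] - 1, logical(1))]
    out <- list()
    for (u in preds) for (p in walk(u)) out <- c(out, list(c(p, v)))
    out
  }
  walk(to)
}

# reachability of target from any source after deleting edge rows `drop`
oracleDisconnected <- function(edge_df, nodes, sources, target, drop) {
  keep <- edge_df[setdiff(seq_len(nrow(edge_df)), drop), , drop = FALSE]
  adj <- oracleAdj(keep, nodes)
  for (s in sources) {
    if (is.finite(oracleBfsDist(adj, s)[target])) return(FALSE)
  }
  TRUE
}

# exhaustive minimum cut: subsets of edge rows in ascending capacity order;
# the first disconnecting subset is the minimum (capacity ties irrelevant
# for the minimum value). Returns list(capacity, edge_rows).
oracleMinCut <- function(edge_df, nodes, sources, target,
                         caps = edge_df$rank + 1) {
  m <- nrow(edge_df)
  stopifnot(m <= 16)
  if (oracleDisconnected(edge_df, nodes, sources, target, integer(0)))
    return(list(capacity = 0, edge_rows = integer(0)))
  masks <- 0:(2^m - 1)
  bit <- outer(masks, seq_len(m) - 1L, function(a, b) bitwAnd(a, 2^b) > 0)
  capOf <- as.numeric(bit %*% caps)
  ord <- order(capOf)
  for (k in ord) {
    drop <- which(bit[k, ])
    if (length(drop) == 0) next
    if (oracleDisconnected(edge_df, nodes, sources, target, drop))
      return(list(capacity = capOf[k], edge_rows = drop))
  }
  stop("no disconnecting subset found")
}

# union-find connected components (edges undirected)
oracleComponents <- function(edge_df, nodes) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(edge_df))) {
    a <- find(edge_df$source_id[i]); b <- find(edge_df$target_id[i])
    if (a != b) parent[[a]] <- b
  }
  vapply(nodes, find, "")
}

# canonical string form of a path set, for set-equality comparison
pathSetKey <- function(paths) {
  sort(vapply(paths, paste, "", collapse = ">"))
}
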