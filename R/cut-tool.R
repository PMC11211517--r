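## Rank-capacitated max-flow / min-cut intervention planning.
##
## Traversal semantics match the path queries: directed edges carry flow
## forward only; an undirected edge becomes two opposing arcs that share one
## capacity budget, so a binding interaction is a single severable object
## that can appear at most once in a cut. Multi-source queries introduce a
## dummy super-source wired to every source with effectively infinite
## capacity (one more than the total real capacity), so dummy arcs can never
## be saturated and never appear in a reported cut-set.

#' Edge capacity from reliability rank
#'
#' The default rule sets capacity = rank + 1, exactly as used with the
#' rank-capacitated min-cut; the `unit` rule gives every edge capacity 1 so
#' cuts minimize the *number* of severed interactions instead.
#'
#' @param rank Integer vector of ranks 0--4.
#' @param rule "rank_plus_one" or "unit".
#' @return Numeric capacities.
#' @examples
#' capacityFromRank(0:4)           # 1 2 3 4 5
#' capacityFromRank(0:4, "unit")   # 1 1 1 1 1
#' @export
capacityFromRank <- function(rank, rule = c("rank_plus_one", "unit")) {
  rule <- match.arg(rule)
  stopIfNot(all(rank %in% 0:4), "rank must be in 0..4")
  if (rule == "rank_plus_one") as.numeric(rank + 1) else rep(1, length(rank))
}

#' Attach a super-source to a set of sources
#'
#' Adds a dummy node with one directed arc to each source; each dummy arc
#' carries capacity 1 + (sum of all real edge capacities), i.e. effectively
#' infinite, so it is never part of a minimum cut.
#'
#' @param net A [KnowledgeNetwork-class].
#' @param sources Nonempty set of existing source ids.
#' @param capacity_rule Passed to [capacityFromRank()].
#' @return List with `network` (augmented), `dummy_id` and `dummy_capacity`.
#' @export
addSuperSource <- function(net, sources,
                           capacity_rule = c("rank_plus_one", "unit")) {
  capacity_rule <- match.arg(capacity_rule)
  stopIfNot(length(sources) >= 1, "at least one source required")
  sources <- resolveIds(net, sources, "source")
  dummy <- "__SUPER_SOURCE__"
  k <- 0L
  while (normId(dummy) %in% normId(entities(net)$id)) {
    k <- k + 1L
    dummy <- sprintf("__SUPER_SOURCE_%d__", k)
  }
  total <- sum(capacityFromRank(edges(net)$rank, capacity_rule))
  net <- addEntity(net, entityRecord(dummy, entity_type = "abstract",
                                     stub = TRUE))
  extra <- data.frame(source_id = dummy, target_id = sources,
                      interaction_type = "other", directed = TRUE,
                      sign = "unknown", rank = 0L, provenance = "dummy",
                      stringsAsFactors = FALSE)
  net@edges <- rbind(net@edges, extra)
  rownames(net@edges) <- NULL
  list(network = net, dummy_id = dummy, dummy_capacity = total + 1)
}

## flow graph: vertices = ids, arcs with capacity + edge_index; undirected
## edges expand to antiparallel arc pairs sharing the index
.flowGraph <- function(net, capacity_rule, dummy_id = NULL,
                       dummy_capacity = Inf) {
  ed <- edges(net)
  caps <- capacityFromRank(ed$rank, capacity_rule)
  if (!is.null(dummy_id)) {
    isDummy <- normId(ed$source_id) == normId(dummy_id)
    caps[isDummy] <- dummy_capacity
  }
  en <- entities(net)
  s <- match(normId(ed$source_id), normId(en$id))
  t <- match(normId(ed$target_id), normId(en$id))
  dir <- ed$directed
  ends <- cbind(rbind(s[dir], t[dir]),
                rbind(s[!dir], t[!dir]), rbind(t[!dir], s[!dir]))
  idx <- c(which(dir), which(!dir), which(!dir))
  cap <- caps[idx]
  g <- igraph::make_empty_graph(n = nrow(en), directed = TRUE)
  igraph::V(g)$name <- en$id
  if (length(idx))
    g <- igraph::add_edges(g, ends, capacity = cap, edge_index = idx)
  g
}

#' Minimum cut between sources and a target
#'
#' Computes a rank-capacitated max-flow from the source set (through a
#' super-source) to `target` and reports the canonical source-side minimum
#' cut derived from the residual-graph reachable set, which is deterministic
#' given the node ordering. By the max-flow/min-cut theorem the reported
#' `flowValue` always equals `cutCapacity`.
#'
#' In node-knockout mode every intermediate node is split into an in/out
#' pair joined by an arc carrying the node's capacity (default: the minimum
#' capacity among its incident edges), so a cut may sever nodes -- reported
#' in `cutNodes` -- as well as edges.
#'
#' @param net A [KnowledgeNetwork-class].
#' @param sources Nonempty source ids (must not contain the target).
#' @param target Single target id.
#' @param capacity_rule "rank_plus_one" (default) or "unit".
#' @param node_knockout Enable node-splitting mode.
#' @param node_capacity Optional named numeric of per-node capacities (or a
#'   single number for all); defaults to each node's minimum incident edge
#'   capacity.
#' @return A [CutResult-class]. If the target is unreachable from every
#'   source the result is trivial: empty cut, zero flow.
#' @export
minCut <- function(net, sources, target,
                   capacity_rule = c("rank_plus_one", "unit"),
                   node_knockout = FALSE, node_capacity = NULL) {
  capacity_rule <- match.arg(capacity_rule)
  sources <- resolveIds(net, sources, "source")
  target <- resolveIds(net, target, "target")
  stopIfNot(length(target) == 1, "exactly one target required")
  stopIfNot(!(normId(target) %in% normId(sources)),
            "target must not be in the source set")
  aug <- addSuperSource(net, sources, capacity_rule)
  g <- .flowGraph(aug$network, capacity_rule, aug$dummy_id,
                  aug$dummy_capacity)
  if (node_knockout)
    g <- .splitNodes(g, protect = c(aug$dummy_id, sources, target),
                     node_capacity = node_capacity)
  fl <- igraph::max_flow(g, source = igraph::V(g)[aug$dummy_id],
                         target = igraph::V(g)[target])
  reach <- .residualReachable(g, fl$flow, aug$dummy_id)
  vnames <- igraph::V(g)$name
  inR <- vnames %in% reach
  heads <- igraph::head_of(g, igraph::E(g))$name
  tails <- igraph::tail_of(g, igraph::E(g))$name
  crossing <- which((tails %in% reach) & !(heads %in% reach))
  eidx <- igraph::E(g)$edge_index[crossing]
  isNode <- is.na(eidx)
  cutNodes <- character(0)
  if (node_knockout && any(isNode))
    cutNodes <- sort(unique(igraph::E(g)$node_id[crossing][isNode]))
  cutIdx <- sort(unique(eidx[!isNode]))
  cutEdges <- edges(net)[cutIdx, , drop = FALSE]
  if (nrow(cutEdges)) cutEdges$edge_index <- cutIdx
  else cutEdges <- cbind(emptyFrame(EDGE_COLS),
                         data.frame(edge_index = integer(0)))
  rownames(cutEdges) <- NULL
  ## capacity from the original network's perspective (node arcs included)
  capEdges <- if (length(cutIdx))
    sum(capacityFromRank(edges(net)$rank[cutIdx], capacity_rule)) else 0
  capNodes <- if (length(cutNodes))
    sum(igraph::E(g)$capacity[crossing][isNode][!duplicated(
      igraph::E(g)$node_id[crossing][isNode])]) else 0
  ## partition reported on original node ids
  origNames <- unique(sub("__(IN|OUT)$", "", vnames))
  srcSide <- unique(sub("__(IN|OUT)$", "", vnames[inR]))
  srcSide <- setdiff(srcSide, aug$dummy_id)
  tgtSide <- setdiff(origNames, c(srcSide, aug$dummy_id))
  new("CutResult", cutEdges = cutEdges, cutNodes = cutNodes,
      cutCapacity = capEdges + capNodes, flowValue = fl$value,
      sourceSide = sort(srcSide), targetSide = sort(tgtSide))
}

## split every unprotected node v into v__IN -> v__OUT carrying the node's
## capacity; incoming arcs attach to v__IN, outgoing arcs leave v__OUT
.splitNodes <- function(g, protect, node_capacity = NULL) {
  vnames <- igraph::V(g)$name
  splitv <- setdiff(vnames, protect)
  el <- igraph::as_edgelist(g, names = TRUE)
  caps <- igraph::E(g)$capacity
  eidx <- igraph::E(g)$edge_index
  nodeCap <- function(v) {
    if (is.numeric(node_capacity) && length(node_capacity) == 1 &&
        is.null(names(node_capacity))) return(node_capacity)
    if (!is.null(node_capacity) && v %in% names(node_capacity))
      return(node_capacity[[v]])
    inc <- caps[el[, 1] == v | el[, 2] == v]
    if (!length(inc)) 1 else min(inc)
  }
  capOf <- stats::setNames(vapply(splitv, nodeCap, 0), splitv)
  from <- ifelse(el[, 1] %in% splitv, paste0(el[, 1], "__OUT"), el[, 1])
  to <- ifelse(el[, 2] %in% splitv, paste0(el[, 2], "__IN"), el[, 2])
  allv <- unique(c(from, to, paste0(splitv, "__IN"), paste0(splitv, "__OUT"),
                   protect))
  g2 <- igraph::make_empty_graph(n = length(allv), directed = TRUE)
  igraph::V(g2)$name <- allv
  ends <- rbind(match(from, allv), match(to, allv))
  nodeEnds <- rbind(match(paste0(splitv, "__IN"), allv),
                    match(paste0(splitv, "__OUT"), allv))
  g2 <- igraph::add_edges(g2, ends, capacity = caps, edge_index = eidx,
                          node_id = NA_character_)
  if (length(splitv))
    g2 <- igraph::add_edges(g2, nodeEnds, capacity = unname(capOf),
                            edge_index = NA_integer_, node_id = splitv)
  g2
}

## BFS on the residual graph: forward along arcs with residual capacity,
## backward along arcs carrying positive flow
.residualReachable <- function(g, flow, from) {
  el <- igraph::as_edgelist(g, names = TRUE)
  caps <- igraph::E(g)$capacity
  eps <- 1e-9
  fwd <- split(el[, 2][caps - flow > eps], el[, 1][caps - flow > eps])
  bwd <- split(el[, 1][flow > eps], el[, 2][flow > eps])
  seen <- from
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nxt <- c(fwd[[v]], bwd[[v]])
    nxt <- nxt[!(nxt %in% seen)]
    if (length(nxt)) {
      seen <- c(seen, nxt)
      queue <- c(queue, nxt)
    }
  }
  seen
}

#' Per-target minimum cuts and their merged cut-set
#'
#' Runs [minCut()] independently for every target against the same source
#' set and merges the per-target cut edges into a single deduplicated
#' cut-set -- the set highlighted when all targets must be disconnected.
#'
#' @param net A [KnowledgeNetwork-class].
#' @param sources Source ids.
#' @param targets Nonempty target ids; targets that are themselves sources
#'   are skipped with a warning.
#' @param ... Passed to [minCut()].
#' @return List with `per_target` (named list of [CutResult-class]) and
#'   `merged_cut` (deduplicated edge data.frame).
#' @export
minCutPerTarget <- function(net, sources, targets, ...) {
  stopIfNot(length(targets) > 0, "targets must be nonempty")
  targets <- resolveIds(net, targets, "target")
  inSrc <- normId(targets) %in% normId(resolveIds(net, sources, "source"))
  if (any(inSrc)) {
    warning("target(s) in the source set skipped: ",
            paste(targets[inSrc], collapse = ", "))
    targets <- targets[!inSrc]
  }
  per <- stats::setNames(lapply(targets, function(t)
    minCut(net, sources, t, ...)), targets)
  mergedIdx <- sort(unique(unlist(lapply(per, function(r)
    r@cutEdges$edge_index))))
  merged <- edges(net)[mergedIdx, , drop = FALSE]
  if (nrow(merged)) merged$edge_index <- mergedIdx
  rownames(merged) <- NULL
  list(per_target = per, merged_cut = merged)
}

#' Verify that a cut disconnects sources from targets
#'
#' Removes `cut_edges` from the network and searches for a remaining
#' traversable source-to-target path (directed semantics, undirected edges
#' both ways). Returns the verdict and, when the cut fails, a witness path.
#'
#' @param net A [KnowledgeNetwork-class].
#' @param cut_edges data.frame with an `edge_index` column (as in
#'   [CutResult-class]) or a subset of `edges(net)` rows.
#' @param sources,targets Id sets.
#' @param cut_nodes Optional nodes to remove as well (knockout cuts).
#' @return List with `valid` (logical) and `witness` (node-id path or NULL).
#' @export
verifyCut <- function(net, cut_edges, sources, targets,
                      cut_nodes = character(0)) {
  sources <- resolveIds(net, sources, "source")
  targets <- resolveIds(net, targets, "target")
  ed <- edges(net)
  if (!is.null(cut_edges$edge_index)) drop <- cut_edges$edge_index
  else drop <- which(condensedEdgeKey(ed) %in% condensedEdgeKey(cut_edges))
  keepEd <- ed[setdiff(seq_len(nrow(ed)), drop), , drop = FALSE]
  rownames(keepEd) <- NULL
  en <- entities(net)
  if (length(cut_nodes)) {
    en <- en[!(normId(en$id) %in% normId(cut_nodes)), , drop = FALSE]
    keepEd <- keepEd[normId(keepEd$source_id) %in% normId(en$id) &
                       normId(keepEd$target_id) %in% normId(en$id), ,
                     drop = FALSE]
    sources <- sources[!(normId(sources) %in% normId(cut_nodes))]
    if (!length(sources))
      return(list(valid = TRUE, witness = NULL))
  }
  resid <- knowledgeNetwork(entities = en, edges = keepEd)
  g <- .asIgraph(resid, "traversal")
  for (s in sources) for (t in targets) {
    sp <- suppressWarnings(igraph::shortest_paths(g, from = s, to = t,
                                                  mode = "out"))
    p <- sp$vpath[[1]]
    if (length(p) > 0 &&
        (normId(s) == normId(t) || length(p) > 1))
      return(list(valid = FALSE, witness = igraph::V(g)$name[as.integer(p)]))
  }
  list(valid = TRUE, witness = NULL)
}
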