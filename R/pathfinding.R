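## Shortest-path hypothesis generation between source and target sets, and
## the reaction-participant bipartite projection.

#' Project a reaction hypergraph onto a directed, signed pairwise network
#'
#' For each reaction, every input-like participant (SUBSTRATE, ACTIVATES,
#' INHIBITS, CATALYZES, TRANSPORT_FROM) is connected by a directed edge to
#' every output-like participant (PRODUCT, TRANSPORT_TO). The edge sign is
#' inhibition when the originating role is INHIBITS, activation otherwise;
#' provenance records the reaction id. Parallel projected edges are
#' condensed, but conflicting signs between the same pair are kept as two
#' edges (one per sign). Reactions without an output-like participant that
#' are not flagged as source/sink are skipped with a warning.
#'
#' @param rn A [ReactionNetwork-class].
#' @return A directed, signed [KnowledgeNetwork-class] over entities and
#'   functional-cluster nodes.
#' @export
bipartiteProjection <- function(rn) {
  pp <- participants(rn); rx <- reactions(rn)
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(rx))) {
    rid <- rx$reaction_id[i]
    p <- pp[normId(pp$reaction_id) == normId(rid), , drop = FALSE]
    ins <- p[p$role %in% .inputRoles, , drop = FALSE]
    outs <- p[p$role %in% .outputRoles, , drop = FALSE]
    if (nrow(outs) == 0) {
      if (!rx$source_sink[i]) skipped <- c(skipped, rid)
      next
    }
    if (nrow(ins) == 0) next
    for (a in seq_len(nrow(ins))) for (b in seq_len(nrow(outs))) {
      rows <- c(rows, list(data.frame(
        source_id = ins$node_id[a], target_id = outs$node_id[b],
        interaction_type = "other", directed = TRUE,
        sign = if (ins$role[a] == "INHIBITS") "inhibition" else "activation",
        rank = 0L, provenance = rid, stringsAsFactors = FALSE)))
    }
  }
  if (length(skipped))
    warning("reaction(s) without output-like participant skipped: ",
            paste(skipped, collapse = ", "))
  ed <- do.call(rbind, c(list(emptyFrame(EDGE_COLS)), rows))
  ## condense parallel projected edges per (pair, sign); conflicting signs
  ## between the same ordered pair survive as separate edges
  if (nrow(ed)) {
    key <- paste(normId(ed$source_id), normId(ed$target_id), ed$sign,
                 sep = "\r")
    agg <- lapply(split(seq_len(nrow(ed)), key), function(idx) {
      one <- ed[idx[1], , drop = FALSE]
      one$provenance <- joinSet(unlist(lapply(ed$provenance[idx], splitSet)))
      one
    })
    ed <- do.call(rbind, agg)
    ed <- ed[order(normId(ed$source_id), normId(ed$target_id), ed$sign), ,
             drop = FALSE]
    rownames(ed) <- NULL
  }
  ids <- unique(c(ed$source_id, ed$target_id))
  en <- entities(rn)
  known <- en[normId(en$id) %in% normId(ids), , drop = FALSE]
  clIds <- setdiff(normId(ids), normId(known$id))
  if (length(clIds)) {
    stored <- ids[match(clIds, normId(ids))]
    known <- rbind(known, do.call(rbind, lapply(stored, function(s)
      entityRecord(s, entity_type = "complex", stub = TRUE))))
  }
  rownames(known) <- NULL
  knowledgeNetwork(entities = known, edges = ed)
}

#' All shortest paths between source and target sets
#'
#' Enumerates *all* minimum-length paths for every (source, target) pair. In
#' directed mode, directed edges are traversed forward only while undirected
#' (binding) edges are traversable both ways; in undirected mode all edges
#' are symmetric. A node belonging to both sets yields a zero-length path.
#' Unresolvable ids are reported and skipped; if an entire side is
#' unresolvable the query errors.
#'
#' @param net A [KnowledgeNetwork-class].
#' @param sources,targets Nonempty id sets.
#' @param mode "directed" or "undirected".
#' @param max_paths_per_pair Enumeration cap per pair; exceeding it sets the
#'   `truncated` flag on the result.
#' @return A [PathQueryResult-class]. Paths are sorted lexicographically by
#'   their node-id sequence for reproducibility.
#' @export
allShortestPaths <- function(net, sources, targets,
                             mode = c("directed", "undirected"),
                             max_paths_per_pair = 10000L) {
  mode <- match.arg(mode)
  stopIfNot(length(sources) > 0 && length(targets) > 0,
            "sources and targets must be nonempty")
  norm <- normId(entities(net)$id)
  missS <- sources[!(normId(sources) %in% norm)]
  missT <- targets[!(normId(targets) %in% norm)]
  if (length(missS) == length(sources))
    stop("no source id resolves in the network", call. = FALSE)
  if (length(missT) == length(targets))
    stop("no target id resolves in the network", call. = FALSE)
  if (length(missS) || length(missT))
    warning("unresolved id(s) skipped: ",
            paste(c(missS, missT), collapse = ", "))
  sources <- resolveIds(net, sources[normId(sources) %in% norm])
  targets <- resolveIds(net, targets[normId(targets) %in% norm])
  sources <- sources[!duplicated(normId(sources))]
  targets <- targets[!duplicated(normId(targets))]
  g <- .asIgraph(net, if (mode == "directed") "traversal" else "undirected")
  paths <- list(); info <- list(); dists <- list()
  truncated <- FALSE
  for (s in sources) {
    suppressWarnings(
      res <- igraph::all_shortest_paths(g, from = s, to = targets,
                                        mode = "out"))
    d <- suppressWarnings(
      igraph::distances(g, v = s, to = targets,
                        mode = if (mode == "directed") "out" else "all"))
    for (ti in seq_along(targets)) {
      t <- targets[ti]
      dv <- d[1, ti]
      dists <- c(dists, list(data.frame(
        source = s, target = t,
        distance = if (is.finite(dv)) as.integer(dv) else NA_integer_,
        stringsAsFactors = FALSE)))
      if (!is.finite(dv)) next
      seqs <- lapply(res$vpaths, function(p) igraph::V(g)$name[as.integer(p)])
      seqs <- seqs[vapply(seqs, function(x)
        normId(x[length(x)]) == normId(t), logical(1))]
      ## paths are node sequences: parallel edges (binding + regulation
      ## between one pair) must not duplicate them
      seqs <- seqs[!duplicated(vapply(seqs, paste, "", collapse = "\r"))]
      ord <- order(vapply(seqs, paste, "", collapse = "\r"))
      seqs <- seqs[ord]
      if (length(seqs) > max_paths_per_pair) {
        seqs <- seqs[seq_len(max_paths_per_pair)]
        truncated <- TRUE
      }
      paths <- c(paths, seqs)
      if (length(seqs))
        info <- c(info, list(data.frame(
          source = s, target = t, length = as.integer(dv),
          stringsAsFactors = FALSE)[rep(1, length(seqs)), , drop = FALSE]))
    }
  }
  info <- do.call(rbind, c(list(data.frame(source = character(0),
                                           target = character(0),
                                           length = integer(0))), info))
  rownames(info) <- NULL
  dists <- do.call(rbind, dists)
  rownames(dists) <- NULL
  ## global deterministic order
  if (length(paths)) {
    ord <- order(info$source, info$target,
                 vapply(paths, paste, "", collapse = "\r"))
    paths <- paths[ord]
    info <- info[ord, , drop = FALSE]
    rownames(info) <- NULL
  }
  new("PathQueryResult", sources = sources, targets = targets,
      paths = paths, pathInfo = info, distances = dists,
      merged = .mergedFromPaths(net, paths, mode), mode = mode,
      truncated = truncated)
}

## union of path nodes and path edges, as a KnowledgeNetwork
.mergedFromPaths <- function(net, paths, mode) {
  if (!length(paths))
    return(knowledgeNetwork())
  nodes <- unique(unlist(paths))
  ed <- edges(net)
  keep <- rep(FALSE, nrow(ed))
  for (p in paths) {
    if (length(p) < 2) next
    for (k in seq_len(length(p) - 1)) {
      u <- normId(p[k]); v <- normId(p[k + 1])
      hit <- (normId(ed$source_id) == u & normId(ed$target_id) == v) |
        ((normId(ed$source_id) == v & normId(ed$target_id) == u) &
           (!ed$directed | mode == "undirected"))
      keep <- keep | hit
    }
  }
  en <- entities(net)
  en <- en[normId(en$id) %in% normId(nodes), , drop = FALSE]
  ed <- ed[keep, , drop = FALSE]
  rownames(en) <- NULL; rownames(ed) <- NULL
  knowledgeNetwork(entities = en, edges = ed)
}

#' Closest sources for one target
#'
#' Returns the source(s) at minimum distance to `target` (all ties kept);
#' empty when the target is unreachable from every source.
#'
#' @param result A [PathQueryResult-class].
#' @param target Target id present in the result.
#' @return Character vector of source ids.
#' @export
closestSources <- function(result, target) {
  d <- result@distances
  stopIfNot(normId(target) %in% normId(d$target),
            paste0("target not in result: ", target))
  d <- d[normId(d$target) == normId(target) & !is.na(d$distance), ,
         drop = FALSE]
  if (!nrow(d)) return(character(0))
  sort(d$source[d$distance == min(d$distance)])
}

#' Restrict a path query to closest sources per target
#'
#' For each target, keeps only paths originating from the source(s) with the
#' minimum distance to that target (the closest upstream candidates); paths
#' from more distant sources are dropped and the merged network is rebuilt.
#' Zero-length self-paths (a target that is itself a source) are always the
#' minimum and are retained. Distances are facts about the network and are
#' left untouched.
#'
#' @param result A [PathQueryResult-class].
#' @return A restricted [PathQueryResult-class].
#' @export
restrictToClosest <- function(result) {
  if (!length(result@paths)) return(result)
  keep <- rep(FALSE, length(result@paths))
  info <- result@pathInfo
  for (t in result@targets) {
    cs <- closestSources(result, t)
    keep <- keep | (normId(info$target) == normId(t) &
                      normId(info$source) %in% normId(cs))
  }
  out <- result
  out@paths <- result@paths[keep]
  out@pathInfo <- info[keep, , drop = FALSE]
  rownames(out@pathInfo) <- NULL
  out@merged <- .mergedFromPaths(
    knowledgeNetwork(entities = entities(result@merged),
                     edges = edges(result@merged)),
    out@paths, result@mode)
  out
}

#' Expand a subnetwork by its first neighbors
#'
#' Adds every node adjacent (in either direction) to any node of the
#' subnetwork, then induces on the expanded node set -- the standard context
#' step after merging shortest paths.
#'
#' @param net The full [KnowledgeNetwork-class].
#' @param subnetwork A [KnowledgeNetwork-class] (or character vector of
#'   node ids) contained in `net`.
#' @return Induced subnetwork of `net`.
#' @export
expandFirstNeighbors <- function(net, subnetwork) {
  ids <- if (is.character(subnetwork)) subnetwork
         else entities(subnetwork)$id
  if (!length(ids)) return(knowledgeNetwork())
  neighborhoodSubnetwork(net, ids, radius = 1)
}

#' Histogram of source-to-target path lengths
#'
#' Counts reachable (source, target) pairs by shortest-path length.
#' Zero-length pairs (a target already in the source set) are tallied under
#' their own `"0"` bin.
#'
#' @param result A [PathQueryResult-class].
#' @return Named integer vector, names = number of steps.
#' @export
pathLengthHistogram <- function(result) {
  d <- result@distances
  d <- d[!is.na(d$distance), , drop = FALSE]
  if (!nrow(d)) return(stats::setNames(integer(0), character(0)))
  tb <- table(d$distance)
  stats::setNames(as.integer(tb), names(tb))
}
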