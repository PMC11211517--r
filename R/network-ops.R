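## Subnetwork extraction: node/edge/tissue filters, connected components,
## neighborhoods and hub scoring.

## ---- igraph bridge ---------------------------------------------------------

## Build an igraph view of a KnowledgeNetwork.
##  mode "traversal":  directed graph; a directed edge becomes one arc, an
##                     undirected edge two opposing arcs (binding edges are
##                     traversable both ways inside directed queries).
##  mode "undirected": undirected graph, one igraph edge per edge row.
## Every arc carries edge_index, the row number in edges(net).
.asIgraph <- function(net, mode = c("traversal", "undirected")) {
  mode <- match.arg(mode)
  en <- entities(net); ed <- edges(net)
  if (mode == "undirected") {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, nrow(en), name = en$id)
    if (nrow(ed))
      g <- igraph::add_edges(g,
             rbind(match(normId(ed$source_id), normId(en$id)),
                   match(normId(ed$target_id), normId(en$id))),
             edge_index = seq_len(nrow(ed)))
    return(g)
  }
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, nrow(en), name = en$id)
  if (nrow(ed)) {
    s <- match(normId(ed$source_id), normId(en$id))
    t <- match(normId(ed$target_id), normId(en$id))
    dir <- ed$directed
    ends <- cbind(rbind(s[dir], t[dir]),
                  rbind(s[!dir], t[!dir]), rbind(t[!dir], s[!dir]))
    idx <- c(which(dir), which(!dir), which(!dir))
    if (length(idx))
      g <- igraph::add_edges(g, ends, edge_index = idx)
  }
  g
}

## resolve user-supplied ids to stored entity ids (case-insensitive)
resolveIds <- function(net, ids, what = "id") {
  i <- match(normId(ids), normId(entities(net)$id))
  if (anyNA(i))
    stop("unknown ", what, ": ", paste(ids[is.na(i)], collapse = ", "),
         call. = FALSE)
  entities(net)$id[i]
}

## induced subnetwork on a set of entity ids (stored form or any case)
induceSubnetwork <- function(net, ids) {
  keepNorm <- unique(normId(ids))
  en <- entities(net)
  en <- en[normId(en$id) %in% keepNorm, , drop = FALSE]
  ed <- edges(net)
  ed <- ed[normId(ed$source_id) %in% keepNorm &
             normId(ed$target_id) %in% keepNorm, , drop = FALSE]
  rownames(en) <- NULL; rownames(ed) <- NULL
  out <- knowledgeNetwork(entities = en, edges = ed)
  metadata(out) <- metadata(net)
  out
}

## ---- filters ---------------------------------------------------------------

#' Node filter specification
#'
#' At least one criterion must be set. The tissue criterion passes when a
#' node's tissue annotation intersects `tissue_terms`; nodes without any
#' tissue annotation are retained by default (absence of annotation is not
#' evidence of absence), unless `strict_tissue = TRUE`.
#'
#' @param entity_types Optional subset of [entityTypes()].
#' @param origin Optional "plant" or "foreign".
#' @param tissue_terms Optional character vector of ontology term ids.
#' @param strict_tissue Drop unannotated nodes when filtering by tissue.
#' @return A `NodeFilterSpec` list.
#' @export
nodeFilterSpec <- function(entity_types = NULL, origin = NULL,
                           tissue_terms = NULL, strict_tissue = FALSE) {
  stopIfNot(!is.null(entity_types) || !is.null(origin) ||
              !is.null(tissue_terms),
            "at least one filter criterion must be set")
  if (!is.null(origin))
    stopIfNot(all(origin %in% entityOrigins()), "unknown origin value")
  structure(list(entity_types = entity_types, origin = origin,
                 tissue_terms = tissue_terms, strict_tissue = strict_tissue),
            class = "NodeFilterSpec")
}

#' Filter nodes by type, origin and tissue
#'
#' Returns the induced subnetwork on nodes satisfying *all* set criteria:
#' only edges with both endpoints retained survive.
#'
#' @param net A [KnowledgeNetwork-class].
#' @param spec A [nodeFilterSpec()].
#' @return Induced subnetwork.
#' @export
filterNodes <- function(net, spec) {
  stopIfNot(inherits(spec, "NodeFilterSpec"), "spec must be a NodeFilterSpec")
  en <- entities(net)
  keep <- rep(TRUE, nrow(en))
  if (!is.null(spec$entity_types))
    keep <- keep & en$entity_type %in% spec$entity_types
  if (!is.null(spec$origin)) keep <- keep & en$origin %in% spec$origin
  if (!is.null(spec$tissue_terms)) {
    annotated <- unique(unlist(lapply(en$tissues, splitSet)))
    unknown <- setdiff(spec$tissue_terms, annotated)
    if (length(unknown))
      warning("tissue term(s) not found among annotations: ",
              paste(unknown, collapse = ", "))
    hit <- vapply(en$tissues, function(t) {
      terms <- splitSet(t)
      if (!length(terms)) !spec$strict_tissue
      else length(intersect(terms, spec$tissue_terms)) > 0
    }, logical(1))
    keep <- keep & hit
  }
  induceSubnetwork(net, en$id[keep])
}

#' Filter edges by reliability rank
#'
#' Keeps edges with rank at most `max_rank` (0 = most reliable). All nodes
#' are retained unless `drop_isolated = TRUE`, in which case nodes left
#' without any incident edge are dropped too.
#'
#' @param net A [KnowledgeNetwork-class].
#' @param max_rank Integer 0--4.
#' @param drop_isolated Drop nodes isolated by the edge filter.
#' @return Subnetwork.
#' @export
filterEdgesByRank <- function(net, max_rank, drop_isolated = FALSE) {
  stopIfNot(length(max_rank) == 1 && max_rank >= 0 && max_rank <= 4,
            "max_rank must be a single value in 0..4")
  ed <- edges(net)[edges(net)$rank <= max_rank, , drop = FALSE]
  rownames(ed) <- NULL
  en <- entities(net)
  if (drop_isolated) {
    used <- unique(normId(c(ed$source_id, ed$target_id)))
    en <- en[normId(en$id) %in% used, , drop = FALSE]
    rownames(en) <- NULL
  }
  out <- knowledgeNetwork(entities = en, edges = ed)
  metadata(out) <- metadata(net)
  out
}

#' Largest (weakly) connected component
#'
#' Components are computed treating every edge as undirected. Size ties are
#' broken by the smallest lexicographic member id.
#'
#' @param net A nonempty [KnowledgeNetwork-class].
#' @return Induced subnetwork of the largest component.
#' @export
largestConnectedComponent <- function(net) {
  stopIfNot(nEntities(net) > 0, "network is empty")
  g <- .asIgraph(net, "undirected")
  comp <- igraph::components(g, mode = "weak")
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1) {
    minIds <- vapply(cand, function(k)
      min(igraph::V(g)$name[comp$membership == k]), "")
    cand <- cand[order(minIds)][1]
  }
  induceSubnetwork(net, igraph::V(g)$name[comp$membership == cand[1]])
}

#' Neighborhood of a seed set
#'
#' Induced subnetwork on all nodes within `radius` steps of any seed,
#' ignoring edge direction.
#'
#' @param net A [KnowledgeNetwork-class].
#' @param seed_ids Seed entity ids (must exist).
#' @param radius Integer >= 1.
#' @return Induced subnetwork.
#' @export
neighborhoodSubnetwork <- function(net, seed_ids, radius = 1) {
  stopIfNot(radius >= 1, "radius must be >= 1")
  seeds <- resolveIds(net, seed_ids, "seed")
  g <- .asIgraph(net, "undirected")
  nb <- igraph::ego(g, order = radius, nodes = seeds, mode = "all")
  induceSubnetwork(net, unique(unlist(lapply(nb, function(v) v$name))))
}

#' Degree and source/target reach scores per node
#'
#' Degrees count network edges exactly (in/out over directed edges;
#' `undirected_degree` counts all incident edges ignoring direction). When
#' labeled `sources` / `targets` are supplied, each node is additionally
#' scored with the number of distinct sources that can reach it by a
#' directed traversal and the number of distinct targets it reaches --
#' highlighting hubs that integrate several upstream signals and fan out to
#' several downstream targets.
#'
#' @param net A [KnowledgeNetwork-class].
#' @param sources,targets Optional labeled node sets.
#' @return data.frame with one row per node.
#' @export
hubScores <- function(net, sources = NULL, targets = NULL) {
  en <- entities(net); ed <- edges(net)
  norm <- normId(en$id)
  inDeg <- outDeg <- undDeg <- integer(length(norm))
  if (nrow(ed)) {
    s <- factor(normId(ed$source_id), levels = norm)
    t <- factor(normId(ed$target_id), levels = norm)
    dir <- ed$directed
    outDeg <- as.integer(table(s[dir]))
    inDeg <- as.integer(table(t[dir]))
    undDeg <- as.integer(table(s)) + as.integer(table(t))
  }
  out <- data.frame(id = en$id, in_degree = inDeg, out_degree = outDeg,
                    undirected_degree = undDeg,
                    n_sources_reached_from = NA_integer_,
                    n_targets_reaching = NA_integer_,
                    stringsAsFactors = FALSE)
  if (!is.null(sources) || !is.null(targets)) {
    g <- .asIgraph(net, "traversal")
    if (!is.null(sources)) {
      sources <- resolveIds(net, sources, "source")
      reach <- matrix(FALSE, length(sources), nrow(en))
      for (i in seq_along(sources))
        reach[i, ] <- is.finite(igraph::distances(g, v = sources[i],
                                                  mode = "out"))
      cnt <- colSums(reach)
      ## a node does not count itself as an upstream source
      self <- match(normId(sources), norm)
      cnt[self] <- cnt[self] - 1L
      out$n_sources_reached_from <- as.integer(cnt)
    }
    if (!is.null(targets)) {
      targets <- resolveIds(net, targets, "target")
      reach <- matrix(FALSE, length(targets), nrow(en))
      for (i in seq_along(targets))
        reach[i, ] <- is.finite(igraph::distances(g, v = targets[i],
                                                  mode = "in"))
      cnt <- colSums(reach)
      self <- match(normId(targets), norm)
      cnt[self] <- cnt[self] - 1L
      out$n_targets_reaching <- as.integer(cnt)
    }
  }
  out
}
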