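## Integration of per-resource interaction tables into a condensed, ranked
## knowledge network: load -> rank -> integrate (multigraph) -> condense ->
## identifier update, plus gene-level expansion of functional clusters.

RAW_COLS <- c(source_id = "character", target_id = "character",
              interaction_type = "character", directed = "logical",
              sign = "character", evidence_class = "character",
              resource_name = "character", reference = "character")

#' Describe an interaction resource
#'
#' @param resource_name Unique resource name.
#' @param default_evidence_class Evidence class assumed for rows without a
#'   per-row evidence column; one of `names(evidenceClasses())`.
#' @param interaction_types Optional declared interaction types.
#' @return A `SourceMeta` list.
#' @export
sourceMeta <- function(resource_name, default_evidence_class,
                       interaction_types = interactionTypes()) {
  stopIfNot(default_evidence_class %in% names(evidenceClasses()),
            paste0("unknown evidence class: ", default_evidence_class))
  structure(list(resource_name = resource_name,
                 default_evidence_class = default_evidence_class,
                 interaction_types = interaction_types),
            class = "SourceMeta")
}

#' Load one resource's interaction table
#'
#' Reads a TSV with header columns `source_id`, `target_id` and optionally
#' `interaction_type`, `directed`, `sign`, `evidence_class`, `reference`;
#' missing optional columns fall back to the [sourceMeta()] defaults. Rows
#' with an empty endpoint are rejected and reported, never silently dropped.
#'
#' @param path File path.
#' @param meta A [sourceMeta()] description.
#' @return List with `raw` (data.frame of raw interactions) and `rejects`
#'   (data.frame of rejected rows with a reason column).
#' @export
loadSourceTable <- function(path, meta) {
  stopIfNot(file.exists(path), paste0("no such file: ", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0) {
    warning("empty source table: ", path)
    return(list(raw = emptyFrame(RAW_COLS), rejects = emptyFrame(RAW_COLS)))
  }
  for (col in c("source_id", "target_id"))
    if (!col %in% names(tab))
      stop("missing mandatory column '", col, "' in ", path, call. = FALSE)
  if (!"interaction_type" %in% names(tab)) tab$interaction_type <- "binding"
  if (!"directed" %in% names(tab))
    tab$directed <- tab$interaction_type != "binding"
  if (!"sign" %in% names(tab)) tab$sign <- "unknown"
  if (!"evidence_class" %in% names(tab))
    tab$evidence_class <- meta$default_evidence_class
  else {
    blank <- !nzchar(tab$evidence_class)
    tab$evidence_class[blank] <- meta$default_evidence_class
  }
  if (!"reference" %in% names(tab)) tab$reference <- ""
  tab$resource_name <- meta$resource_name
  tab$directed <- as.logical(toupper(tab$directed) %in%
                               c("TRUE", "T", "1", "YES"))
  ## binding edges are undirected unless explicitly overridden in the file
  bad <- !nzchar(trimws(tab$source_id)) | !nzchar(trimws(tab$target_id))
  rejects <- tab[bad, , drop = FALSE]
  if (nrow(rejects)) rejects$reason <- "empty endpoint identifier"
  raw <- fillColumns(tab[!bad, , drop = FALSE], RAW_COLS)
  unknown <- !(raw$evidence_class %in% names(evidenceClasses()))
  if (any(unknown))
    stop("unknown evidence class in ", path, ": ",
         paste(unique(raw$evidence_class[unknown]), collapse = ", "),
         call. = FALSE)
  rownames(raw) <- NULL
  list(raw = raw, rejects = rejects)
}

#' Map evidence classes to reliability ranks
#'
#' The bijection `curated_pss` -> 0, `targeted_experimental` -> 1,
#' `high_throughput` -> 2, `literature_or_validated_prediction` -> 3,
#' `in_silico_prediction` -> 4; lower numbers are more reliable.
#'
#' @param evidence_class Character vector of evidence classes.
#' @return Integer vector of ranks 0--4.
#' @examples
#' assignRank(c("curated_pss", "in_silico_prediction"))  # 0 4
#' @export
assignRank <- function(evidence_class) {
  map <- evidenceClasses()
  unknown <- !(evidence_class %in% names(map))
  if (any(unknown))
    stop("unknown evidence class: ",
         paste(unique(evidence_class[unknown]), collapse = ", "),
         call. = FALSE)
  unname(map[evidence_class])
}

#' Integrate raw interaction collections into a multigraph
#'
#' All raw interactions from all resources are retained as parallel edges;
#' nothing is merged at this stage, so per-pair multiplicity remains
#' queryable via [edgeMultiplicity()].
#'
#' @param raw_collections List of raw-interaction data.frames (from
#'   [loadSourceTable()]`$raw`).
#' @return data.frame of all raw interactions with a `rank` column.
#' @export
integrateSources <- function(raw_collections) {
  if (is.data.frame(raw_collections)) raw_collections <- list(raw_collections)
  multi <- do.call(rbind, c(list(emptyFrame(RAW_COLS)),
                            lapply(raw_collections, fillColumns,
                                   template = RAW_COLS)))
  multi$rank <- if (nrow(multi)) assignRank(multi$evidence_class) else integer(0)
  rownames(multi) <- NULL
  multi
}

#' Parallel-edge multiplicity per (pair, type)
#'
#' @param multi Multigraph data.frame from [integrateSources()].
#' @return data.frame with node pair, interaction type and count.
#' @export
edgeMultiplicity <- function(multi) {
  if (!nrow(multi))
    return(data.frame(node_a = character(0), node_b = character(0),
                      interaction_type = character(0), n = integer(0)))
  lo <- pmin(normId(multi$source_id), normId(multi$target_id))
  hi <- pmax(normId(multi$source_id), normId(multi$target_id))
  key <- paste(lo, hi, multi$interaction_type, sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  data.frame(node_a = vapply(parts, `[`, "", 1),
             node_b = vapply(parts, `[`, "", 2),
             interaction_type = vapply(parts, `[`, "", 3),
             n = agg$Freq, stringsAsFactors = FALSE)
}

## provenance string for one raw row: "resource" or "resource:reference"
.provString <- function(resource, reference) {
  ifelse(is.na(reference) | !nzchar(reference), resource,
         paste0(resource, ":", reference))
}

#' Condense a multigraph into a knowledge network
#'
#' Collapses parallel interactions of the same type between a pair of
#' interactors into a single edge. The most reliable contributing
#' interaction (numerically smallest rank) takes precedence for the edge's
#' rank, directionality and sign, while the provenance of *all* contributing
#' resources is retained as the union. Directed duplicates in opposite
#' orientations are kept as two edges (regulation is orientation-specific);
#' sign conflicts at the best rank resolve to "unknown" and are recorded in
#' `metadata(net)$condense_report`.
#'
#' @param multi Multigraph data.frame from [integrateSources()].
#' @return A condensed [KnowledgeNetwork-class]; endpoint entities are
#'   auto-created as stubs.
#' @export
condenseEdges <- function(multi) {
  if (!nrow(multi)) return(knowledgeNetwork())
  stopIfNot(all(multi$rank %in% 0:4), "every raw edge needs a rank 0-4")
  ed <- data.frame(source_id = multi$source_id, target_id = multi$target_id,
                   interaction_type = multi$interaction_type,
                   directed = multi$directed, sign = multi$sign,
                   rank = as.integer(multi$rank),
                   provenance = .provString(multi$resource_name,
                                            multi$reference),
                   stringsAsFactors = FALSE)
  res <- .condenseEdgeTable(ed)
  ids <- c(res$edges$source_id, res$edges$target_id)
  first <- !duplicated(normId(ids))
  en <- do.call(rbind, lapply(ids[first], function(i)
    entityRecord(i, stub = TRUE)))
  net <- knowledgeNetwork(entities = en, edges = res$edges)
  metadata(net)$condense_report <- res$report
  net
}

## Core merge on an edge table whose provenance is already ";"-joined.
## Shared by condenseEdges() and updateIdentifiers() (re-condensation after
## node merges).
.condenseEdgeTable <- function(ed) {
  ns <- normId(ed$source_id); nt <- normId(ed$target_id)
  lo <- pmin(ns, nt); hi <- pmax(ns, nt)
  group <- paste(lo, hi, ed$interaction_type, sep = "\r")
  ## orientation within the unordered pair: f = stored (lo->hi), r = reverse
  orient <- ifelse(!ed$directed, "u", ifelse(ns <= nt, "f", "r"))
  outRows <- list()
  conflicts <- list()
  for (g in unique(group)) {
    idx <- which(group == g)
    ori <- orient[idx]
    both <- all(c("f", "r") %in% ori)
    if (both) {
      ## both directed orientations present: one condensed edge per
      ## orientation; undirected contributors join the orientation holding
      ## the most reliable directed edge (tie -> forward)
      u <- idx[ori == "u"]
      f <- idx[ori == "f"]; r <- idx[ori == "r"]
      uTo <- if (length(u) == 0) "f"
             else if (min(ed$rank[f]) <= min(ed$rank[r])) "f" else "r"
      partsF <- c(f, if (uTo == "f") u)
      partsR <- c(r, if (uTo == "r") u)
      outRows <- c(outRows, list(.mergeGroup(ed[partsF, , drop = FALSE]),
                                 .mergeGroup(ed[partsR, , drop = FALSE])))
      cf <- attr(outRows[[length(outRows) - 1L]], "conflict")
      cr <- attr(outRows[[length(outRows)]], "conflict")
      conflicts <- c(conflicts, cf, cr)
    } else {
      m <- .mergeGroup(ed[idx, , drop = FALSE])
      outRows <- c(outRows, list(m))
      conflicts <- c(conflicts, attr(m, "conflict"))
    }
  }
  edges <- do.call(rbind, outRows)
  rownames(edges) <- NULL
  ## deterministic canonical order
  edges <- edges[order(normId(edges$source_id), normId(edges$target_id),
                       edges$interaction_type, !edges$directed), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges,
       report = if (length(conflicts))
         data.frame(edge = unlist(conflicts),
                    issue = "sign conflict at best rank; sign set to unknown",
                    stringsAsFactors = FALSE)
       else data.frame(edge = character(0), issue = character(0)))
}

## merge one group of parallel edges into a single condensed edge
.mergeGroup <- function(rows) {
  best <- min(rows$rank)
  top <- rows[rows$rank == best, , drop = FALSE]
  ## directionality follows the most reliable edge; ties resolve to directed
  directed <- any(top$directed)
  rep <- top[order(!top$directed), , drop = FALSE][1, , drop = FALSE]
  signs <- unique(top$sign[top$sign != "unknown"])
  conflict <- NULL
  if (length(signs) == 1) sign <- signs
  else if (length(signs) == 0) sign <- "unknown"
  else {
    sign <- "unknown"
    conflict <- list(paste(rep$source_id, rep$target_id,
                           rep$interaction_type, sep = "|"))
  }
  out <- data.frame(source_id = rep$source_id, target_id = rep$target_id,
                    interaction_type = rep$interaction_type,
                    directed = directed, sign = sign, rank = as.integer(best),
                    provenance = joinSet(unlist(lapply(rows$provenance,
                                                       splitSet))),
                    stringsAsFactors = FALSE)
  attr(out, "conflict") <- conflict
  out
}

#' Apply an identifier-update mapping
#'
#' Renames merged gene loci and removes obsolete ones: a mapping row
#' `old -> new` re-keys the node (edges follow); `old -> OBSOLETE` removes
#' the node together with its incident edges. A rename onto an existing node
#' merges the two nodes and unions their edges (re-condensed so the
#' one-edge-per-(pair,type) invariant holds).
#'
#' @param net A [KnowledgeNetwork-class].
#' @param mapping data.frame with columns `old_id`, `new_id` (`new_id` may
#'   be the literal `"OBSOLETE"`).
#' @return List with `network` (updated) and `report` (one row per change:
#'   old_id, new_id, action, n_edges_removed).
#' @export
updateIdentifiers <- function(net, mapping) {
  stopIfNot(!any(duplicated(normId(mapping$old_id))),
            "mapping keys must be unique")
  en <- entities(net); ed <- edges(net)
  report <- list()
  for (i in seq_len(nrow(mapping))) {
    old <- mapping$old_id[i]; newid <- mapping$new_id[i]
    j <- match(normId(old), normId(en$id))
    if (is.na(j)) next
    if (toupper(newid) == "OBSOLETE") {
      inc <- normId(ed$source_id) == normId(old) |
        normId(ed$target_id) == normId(old)
      ed <- ed[!inc, , drop = FALSE]
      en <- en[-j, , drop = FALSE]
      report <- c(report, list(data.frame(
        old_id = old, new_id = "OBSOLETE", action = "removed",
        n_edges_removed = sum(inc), stringsAsFactors = FALSE)))
    } else {
      k <- match(normId(newid), normId(en$id))
      ed$source_id[normId(ed$source_id) == normId(old)] <- newid
      ed$target_id[normId(ed$target_id) == normId(old)] <- newid
      if (!is.na(k) && k != j) {
        ## merge: keep the existing node's record, drop the renamed one
        nBefore <- nrow(ed)
        res <- .condenseEdgeTable(ed)
        ed <- res$edges
        en <- en[-j, , drop = FALSE]
        report <- c(report, list(data.frame(
          old_id = old, new_id = newid, action = "merged",
          n_edges_removed = nBefore - nrow(ed), stringsAsFactors = FALSE)))
      } else {
        en$id[j] <- newid
        if (en$short_name[j] == old) en$short_name[j] <- newid
        report <- c(report, list(data.frame(
          old_id = old, new_id = newid, action = "renamed",
          n_edges_removed = 0L, stringsAsFactors = FALSE)))
      }
    }
  }
  ## drop self-referential duplicates introduced by merges
  rownames(en) <- NULL; rownames(ed) <- NULL
  out <- knowledgeNetwork(entities = en, edges = ed)
  metadata(out) <- metadata(net)
  list(network = out,
       report = if (length(report)) do.call(rbind, report)
       else data.frame(old_id = character(0), new_id = character(0),
                       action = character(0), n_edges_removed = integer(0)))
}

#' Expand cluster-level interactions to gene level
#'
#' Projects the reaction network to pairwise interactions (via
#' [bipartiteProjection()]) and replaces every functional-cluster endpoint
#' by the Cartesian expansion over its member genes. Expanded edges keep the
#' curated rank 0; provenance records the originating reaction id.
#'
#' @param rn A [ReactionNetwork-class].
#' @param edge_table Optional pre-computed cluster-level edge data.frame
#'   (defaults to `edges(bipartiteProjection(rn))`).
#' @return data.frame of gene-level interaction edges.
#' @export
expandClusters <- function(rn, edge_table = NULL) {
  cl <- clusters(rn)
  empty <- !nzchar(cl$member_gene_ids)
  if (any(empty))
    stop("empty functional cluster: ",
         paste(cl$cluster_id[empty], collapse = ", "), call. = FALSE)
  if (is.null(edge_table)) edge_table <- edges(bipartiteProjection(rn))
  members <- stats::setNames(lapply(cl$member_gene_ids, splitSet),
                             normId(cl$cluster_id))
  expandEnd <- function(id) {
    m <- members[[normId(id)]]
    if (is.null(m)) id else m
  }
  rows <- lapply(seq_len(nrow(edge_table)), function(i) {
    src <- expandEnd(edge_table$source_id[i])
    tgt <- expandEnd(edge_table$target_id[i])
    grid <- expand.grid(source_id = src, target_id = tgt,
                        stringsAsFactors = FALSE)
    grid$interaction_type <- edge_table$interaction_type[i]
    grid$directed <- edge_table$directed[i]
    grid$sign <- edge_table$sign[i]
    grid$rank <- 0L
    grid$provenance <- edge_table$provenance[i]
    grid
  })
  out <- do.call(rbind, c(list(emptyFrame(EDGE_COLS)), rows))
  rownames(out) <- NULL
  out
}
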