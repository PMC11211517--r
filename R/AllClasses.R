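## S4 classes for the core data model.
##
## The containers hold plain data.frames (entities, edges, clusters,
## reactions, participants) so that serialization is lossless and cheap;
## igraph objects are built on demand by the algorithms. Set-valued fields
## (tissues, external references, provenance) are ";"-joined sorted strings.
## S4 validity checks only structure (column presence and types); domain
## invariants are checked by validateNetwork(), which returns violations as
## data rather than raising, so that broken networks can be loaded and
## reported on.

ENTITY_COLS <- c(id = "character", short_name = "character",
                 entity_type = "character", origin = "character",
                 species = "character", tissues = "character",
                 external_refs = "character", stub = "logical")

EDGE_COLS <- c(source_id = "character", target_id = "character",
               interaction_type = "character", directed = "logical",
               sign = "character", rank = "integer",
               provenance = "character")

CLUSTER_COLS <- c(cluster_id = "character", member_gene_ids = "character")

REACTION_COLS <- c(reaction_id = "character", reaction_type = "character",
                   provenance = "character", source_sink = "logical")

PARTICIPANT_COLS <- c(reaction_id = "character", node_id = "character",
                      role = "character", location = "character",
                      form = "character")

emptyFrame <- function(template) {
  cols <- lapply(template, function(t) vector(t, 0L))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

.checkFrame <- function(df, template, what) {
  miss <- setdiff(names(template), names(df))
  if (length(miss))
    return(sprintf("%s is missing column(s): %s", what,
                   paste(miss, collapse = ", ")))
  for (nm in names(template)) {
    if (!is(df[[nm]], template[[nm]]))
      return(sprintf("%s column '%s' must be %s", what, nm, template[[nm]]))
  }
  TRUE
}

#' KnowledgeNetwork: a condensed, ranked interaction network
#'
#' Holds molecular entities and condensed pairwise interactions. Each edge
#' carries an interaction type, directionality, regulatory sign, a
#' reliability rank 0--4 (0 = manually curated, 4 = purely in-silico) and
#' the union of contributing resources as provenance.
#'
#' @slot entities data.frame of entities (id, short_name, entity_type,
#'   origin, species, tissues, external_refs, stub).
#' @slot edges data.frame of interactions (source_id, target_id,
#'   interaction_type, directed, sign, rank, provenance).
#' @slot metadata Free-form list (reports, annotations, omics joins).
#' @export
setClass("KnowledgeNetwork",
         slots = c(entities = "data.frame", edges = "data.frame",
                   metadata = "list"),
         prototype = list(entities = emptyFrame(ENTITY_COLS),
                          edges = emptyFrame(EDGE_COLS),
                          metadata = list()))

setValidity("KnowledgeNetwork", function(object) {
  ok <- .checkFrame(object@entities, ENTITY_COLS, "entities")
  if (!isTRUE(ok)) return(ok)
  .checkFrame(object@edges, EDGE_COLS, "edges")
})

#' ReactionNetwork: a curated reaction hypergraph
#'
#' Bipartite representation of curated signaling knowledge: entities and
#' functional clusters on one side, typed reaction nodes on the other,
#' joined by role-annotated participant links (SUBSTRATE, PRODUCT,
#' ACTIVATES, INHIBITS, CATALYZES, TRANSPORT_FROM, TRANSPORT_TO) that also
#' carry the subcellular location and molecular form of the participant.
#'
#' @slot entities data.frame as in [KnowledgeNetwork-class].
#' @slot clusters data.frame (cluster_id, member_gene_ids as ";"-joined set).
#' @slot reactions data.frame (reaction_id, reaction_type, provenance,
#'   source_sink flag for reactions allowed to lack inputs or outputs).
#' @slot participants data.frame (reaction_id, node_id, role, location, form).
#' @slot metadata Free-form list.
#' @export
setClass("ReactionNetwork",
         slots = c(entities = "data.frame", clusters = "data.frame",
                   reactions = "data.frame", participants = "data.frame",
                   metadata = "list"),
         prototype = list(entities = emptyFrame(ENTITY_COLS),
                          clusters = emptyFrame(CLUSTER_COLS),
                          reactions = emptyFrame(REACTION_COLS),
                          participants = emptyFrame(PARTICIPANT_COLS),
                          metadata = list()))

setValidity("ReactionNetwork", function(object) {
  for (chk in list(.checkFrame(object@entities, ENTITY_COLS, "entities"),
                   .checkFrame(object@clusters, CLUSTER_COLS, "clusters"),
                   .checkFrame(object@reactions, REACTION_COLS, "reactions"),
                   .checkFrame(object@participants, PARTICIPANT_COLS,
                               "participants"))) {
    if (!isTRUE(chk)) return(chk)
  }
  TRUE
})

#' PathQueryResult: all shortest paths between source and target sets
#'
#' @slot sources,targets Resolved source/target entity ids.
#' @slot paths List of node-id sequences, one per shortest path, sorted
#'   lexicographically.
#' @slot pathInfo data.frame (source, target, length) aligned with `paths`.
#' @slot distances data.frame (source, target, distance); `NA` marks an
#'   unreachable pair.
#' @slot merged [KnowledgeNetwork-class] holding the union of path nodes and
#'   path edges.
#' @slot mode "directed" or "undirected" traversal.
#' @slot truncated TRUE if any pair hit the per-pair path-enumeration cap.
#' @export
setClass("PathQueryResult",
         slots = c(sources = "character", targets = "character",
                   paths = "list", pathInfo = "data.frame",
                   distances = "data.frame", merged = "KnowledgeNetwork",
                   mode = "character", truncated = "logical"))

#' CutResult: a certified minimum cut
#'
#' @slot cutEdges data.frame of cut edges (subset of the network's edge
#'   table, plus an `edge_index` column referring to rows of `edges(net)`).
#' @slot cutNodes Character vector of knocked-out nodes (node-knockout mode
#'   only; empty for edge cuts).
#' @slot cutCapacity,flowValue Cut capacity and max-flow value; equal by the
#'   max-flow/min-cut theorem.
#' @slot sourceSide,targetSide Node partition certified by the cut.
#' @export
setClass("CutResult",
         slots = c(cutEdges = "data.frame", cutNodes = "character",
                   cutCapacity = "numeric", flowValue = "numeric",
                   sourceSide = "character", targetSide = "character"))
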