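## Reaction-hypergraph construction helpers.

#' Construct a reaction network
#'
#' @param entities,clusters,reactions,participants Optional data.frames; see
#'   [ReactionNetwork-class] for columns. Missing optional columns are
#'   filled with defaults.
#' @return A [ReactionNetwork-class].
#' @export
reactionNetwork <- function(entities = NULL, clusters = NULL,
                            reactions = NULL, participants = NULL) {
  rn <- new("ReactionNetwork")
  if (!is.null(entities)) rn@entities <- fillColumns(entities, ENTITY_COLS)
  if (!is.null(clusters)) rn@clusters <- fillColumns(clusters, CLUSTER_COLS)
  if (!is.null(reactions)) rn@reactions <- fillColumns(reactions, REACTION_COLS)
  if (!is.null(participants))
    rn@participants <- fillColumns(participants, PARTICIPANT_COLS)
  for (sl in c("entities", "clusters", "reactions", "participants"))
    rownames(slot(rn, sl)) <- NULL
  rn
}

#' Add a functional cluster
#'
#' Functional clusters group genes (possibly across species) that mediate
#' the same function, encoding genetic redundancy.
#'
#' @param rn A [ReactionNetwork-class].
#' @param cluster_id Stable cluster id.
#' @param member_gene_ids Nonempty character vector of gene ids.
#' @return Updated network.
#' @export
addCluster <- function(rn, cluster_id, member_gene_ids) {
  stopIfNot(length(member_gene_ids) > 0,
            paste0("cluster '", cluster_id, "' has no members"))
  stopIfNot(!(normId(cluster_id) %in% normId(rn@clusters$cluster_id)),
            paste0("cluster id already present: ", cluster_id))
  rn@clusters <- rbind(rn@clusters, data.frame(
    cluster_id = cluster_id, member_gene_ids = joinSet(member_gene_ids),
    stringsAsFactors = FALSE))
  rn
}

#' Add a typed reaction with role-annotated participants
#'
#' @param rn A [ReactionNetwork-class].
#' @param reaction_id Stable reaction id (e.g. "rx00459").
#' @param reaction_type One of [reactionTypes()].
#' @param participants data.frame with columns node_id, role and optionally
#'   location, form.
#' @param provenance Character vector of references.
#' @param source_sink TRUE for reactions explicitly allowed to lack an
#'   input-like or output-like participant.
#' @return Updated network.
#' @export
addReaction <- function(rn, reaction_id, reaction_type, participants,
                        provenance = character(0), source_sink = FALSE) {
  stopIfNot(!(normId(reaction_id) %in% normId(rn@reactions$reaction_id)),
            paste0("reaction id already present: ", reaction_id))
  participants$reaction_id <- reaction_id
  participants <- fillColumns(participants, PARTICIPANT_COLS)
  rn@reactions <- rbind(rn@reactions, data.frame(
    reaction_id = reaction_id, reaction_type = reaction_type,
    provenance = joinSet(provenance), source_sink = source_sink,
    stringsAsFactors = FALSE))
  rn@participants <- rbind(rn@participants, participants)
  rn
}
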