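## Core data-model operations: construction, entity management, validation.

#' Construct an entity record
#'
#' @param id Stable identifier (nonempty). Compared case-insensitively after
#'   trimming; stored as given.
#' @param short_name Display name; defaults to `id`.
#' @param entity_type One of [entityTypes()].
#' @param origin "plant" or "foreign". Foreign origin is only permitted for
#'   foreign, abstract or process entities.
#' @param species Optional taxon label.
#' @param tissues Character vector of ontology term ids.
#' @param external_refs Named list, resource name -> character vector of
#'   identifiers.
#' @param stub TRUE for entities auto-created during edge import, so
#'   provenance gaps stay visible.
#' @return One-row data.frame with the entity columns.
#' @examples
#' e <- entityRecord("AT3G24650", entity_type = "gene")
#' @export
entityRecord <- function(id, short_name = id, entity_type = "gene",
                         origin = "plant", species = NA_character_,
                         tissues = character(0),
                         external_refs = list(), stub = FALSE) {
  stopIfNot(length(id) == 1 && nzchar(trimws(id)), "entity id must be nonempty")
  refs <- if (length(external_refs))
    joinSet(vapply(names(external_refs), function(r)
      paste0(r, ":", paste(external_refs[[r]], collapse = ",")), ""))
  else ""
  data.frame(id = as.character(id), short_name = as.character(short_name),
             entity_type = entity_type, origin = origin,
             species = as.character(species),
             tissues = joinSet(as.character(tissues)),
             external_refs = refs, stub = stub,
             stringsAsFactors = FALSE)
}

#' Construct a knowledge network
#'
#' @param entities Optional data.frame of entity records (see
#'   [entityRecord()]).
#' @param edges Optional data.frame of interaction edges.
#' @return A [KnowledgeNetwork-class].
#' @export
knowledgeNetwork <- function(entities = NULL, edges = NULL) {
  net <- new("KnowledgeNetwork")
  if (!is.null(entities)) {
    entities <- fillColumns(entities, ENTITY_COLS)
    dup <- duplicated(normId(entities$id))
    stopIfNot(!any(dup), paste0("duplicate entity id(s): ",
                                paste(unique(entities$id[dup]), collapse = ", ")))
    net@entities <- entities
  }
  if (!is.null(edges)) net@edges <- fillColumns(edges, EDGE_COLS)
  rownames(net@entities) <- NULL
  rownames(net@edges) <- NULL
  net
}

## coerce a data.frame to the template column set/order, filling defaults
fillColumns <- function(df, template) {
  defaults <- list(short_name = NA_character_, entity_type = "gene",
                   origin = "plant", species = NA_character_, tissues = "",
                   external_refs = "", stub = FALSE, sign = "unknown",
                   directed = TRUE, provenance = "", location = "",
                   form = "unspecified", source_sink = FALSE,
                   rank = NA_integer_)
  for (nm in names(template)) {
    if (!nm %in% names(df)) {
      d <- if (nm %in% names(defaults)) defaults[[nm]] else
        vector(template[[nm]], 1L)
      df[[nm]] <- rep(d, nrow(df))
    }
    mode_fun <- match.fun(paste0("as.", template[[nm]]))
    df[[nm]] <- mode_fun(df[[nm]])
  }
  if ("short_name" %in% names(df)) {
    miss <- is.na(df$short_name)
    df$short_name[miss] <- df$id[miss]
  }
  df[, names(template), drop = FALSE]
}

#' @rdname accessors
#' @param x A network container.
#' @aliases entities,KnowledgeNetwork-method
setMethod("entities", "KnowledgeNetwork", function(x) x@entities)
#' @rdname accessors
setMethod("entities", "ReactionNetwork", function(x) x@entities)
#' @rdname accessors
setMethod("edges", "KnowledgeNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("clusters", "ReactionNetwork", function(x) x@clusters)
#' @rdname accessors
setMethod("reactions", "ReactionNetwork", function(x) x@reactions)
#' @rdname accessors
setMethod("participants", "ReactionNetwork", function(x) x@participants)
#' @rdname accessors
setMethod("nEntities", "KnowledgeNetwork", function(x) nrow(x@entities))
#' @rdname accessors
setMethod("nEntities", "ReactionNetwork", function(x) nrow(x@entities))
#' @rdname accessors
setMethod("nEdges", "KnowledgeNetwork", function(x) nrow(x@edges))
#' @rdname accessors
setMethod("metadata", "KnowledgeNetwork", function(x) x@metadata)
#' @rdname accessors
setMethod("metadata", "ReactionNetwork", function(x) x@metadata)
#' @rdname accessors
setReplaceMethod("metadata", "KnowledgeNetwork", function(x, value) {
  x@metadata <- value; x
})
#' @rdname accessors
setReplaceMethod("metadata", "ReactionNetwork", function(x, value) {
  x@metadata <- value; x
})

#' Add an entity to a network
#'
#' @param x A [KnowledgeNetwork-class] or [ReactionNetwork-class].
#' @param entity One-row data.frame from [entityRecord()].
#' @return Updated network; adding an id already present (case-insensitive)
#'   is an error naming the id.
#' @rdname graph-model
#' @export addEntity
setMethod("addEntity", "KnowledgeNetwork", function(x, entity) {
  x@entities <- .appendEntity(x@entities, entity); x
})
#' @rdname graph-model
setMethod("addEntity", "ReactionNetwork", function(x, entity) {
  x@entities <- .appendEntity(x@entities, entity); x
})

.appendEntity <- function(tab, entity) {
  entity <- fillColumns(entity, ENTITY_COLS)
  hit <- normId(entity$id) %in% normId(tab$id)
  if (any(hit))
    stop("entity id already present: ", paste(entity$id[hit], collapse = ", "),
         call. = FALSE)
  rbind(tab, entity)
}

#' Retrieve an entity by id
#'
#' @param net Network container.
#' @param id Entity id (case-insensitive match).
#' @return One-row data.frame, or error if absent.
#' @export
getEntity <- function(net, id) {
  i <- match(normId(id), normId(entities(net)$id))
  stopIfNot(!is.na(i), paste0("no entity with id '", id, "'"))
  entities(net)[i, , drop = FALSE]
}

## ---- validation ------------------------------------------------------------

.violation <- function(element, rule, message) {
  data.frame(element = element, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

.emptyViolations <- function() {
  data.frame(element = character(0), rule = character(0),
             message = character(0), stringsAsFactors = FALSE)
}

#' Validate a network against the data-model invariants
#'
#' Violations are returned as data, not raised, so that imported networks
#' can be inspected and repaired: each row names the offending element and
#' the rule breached. An empty data.frame means the network is valid.
#'
#' @param x A [KnowledgeNetwork-class] or [ReactionNetwork-class].
#' @param ... Unused.
#' @return data.frame with columns element, rule, message.
#' @rdname validateNetwork
#' @export validateNetwork
setMethod("validateNetwork", "KnowledgeNetwork", function(x, ...) {
  v <- list(.validateEntities(x@entities))
  ed <- x@edges
  if (nrow(ed)) {
    badRank <- !(ed$rank %in% 0:4)
    if (any(badRank))
      v <- c(v, list(.violation(
        paste(ed$source_id[badRank], ed$target_id[badRank], sep = "--"),
        "edge_rank", sprintf("rank %s outside 0-4", ed$rank[badRank]))))
    badType <- !(ed$interaction_type %in% interactionTypes())
    if (any(badType))
      v <- c(v, list(.violation(
        paste(ed$source_id[badType], ed$target_id[badType], sep = "--"),
        "interaction_type",
        sprintf("unknown interaction type '%s'", ed$interaction_type[badType]))))
    badSign <- !(ed$sign %in% interactionSigns())
    if (any(badSign))
      v <- c(v, list(.violation(
        paste(ed$source_id[badSign], ed$target_id[badSign], sep = "--"),
        "sign", sprintf("unknown sign '%s'", ed$sign[badSign]))))
    norm <- normId(entities(x)$id)
    orphan <- !(normId(ed$source_id) %in% norm) |
      !(normId(ed$target_id) %in% norm)
    if (any(orphan))
      v <- c(v, list(.violation(
        paste(ed$source_id[orphan], ed$target_id[orphan], sep = "--"),
        "orphan_edge", "edge endpoint does not resolve to an entity")))
    noProv <- !nzchar(ed$provenance)
    if (any(noProv))
      v <- c(v, list(.violation(
        paste(ed$source_id[noProv], ed$target_id[noProv], sep = "--"),
        "provenance", "edge has empty provenance set")))
    key <- condensedEdgeKey(ed)
    dup <- duplicated(key)
    if (any(dup))
      v <- c(v, list(.violation(
        paste(ed$source_id[dup], ed$target_id[dup], sep = "--"),
        "condensed_uniqueness",
        "more than one edge for the same (pair, interaction type)")))
  }
  out <- do.call(rbind, v)
  if (is.null(out)) .emptyViolations() else out
})

#' @rdname validateNetwork
setMethod("validateNetwork", "ReactionNetwork",
          function(x, reaction_types = reactionTypes(), ...) {
  v <- list(.validateEntities(x@entities))
  cl <- x@clusters
  if (nrow(cl)) {
    dup <- duplicated(normId(cl$cluster_id))
    if (any(dup))
      v <- c(v, list(.violation(cl$cluster_id[dup], "cluster_id",
                                "duplicate cluster id")))
    empty <- !nzchar(cl$member_gene_ids)
    if (any(empty))
      v <- c(v, list(.violation(cl$cluster_id[empty], "cluster_members",
                                "cluster has no member genes")))
    memb <- lapply(cl$member_gene_ids, splitSet)
    multi <- table(normId(unlist(memb)))
    multi <- names(multi)[multi > 1]
    if (length(multi))
      v <- c(v, list(.violation(multi, "multi_cluster_membership",
        "gene belongs to multiple functional clusters (permitted, flagged)")))
  }
  rx <- x@reactions
  pp <- x@participants
  if (nrow(rx)) {
    dup <- duplicated(normId(rx$reaction_id))
    if (any(dup))
      v <- c(v, list(.violation(rx$reaction_id[dup], "reaction_id",
                                "duplicate reaction id")))
    badType <- !(rx$reaction_type %in% reaction_types)
    if (any(badType))
      v <- c(v, list(.violation(rx$reaction_id[badType], "reaction_type",
        sprintf("reaction type '%s' not in vocabulary",
                rx$reaction_type[badType]))))
    for (i in seq_len(nrow(rx))) {
      if (rx$source_sink[i]) next
      roles <- pp$role[normId(pp$reaction_id) == normId(rx$reaction_id[i])]
      if (!any(roles %in% .inputRoles) || !any(roles %in% .outputRoles))
        v <- c(v, list(.violation(rx$reaction_id[i], "reaction_roles",
          "reaction lacks an input-like or output-like participant")))
    }
  }
  if (nrow(pp)) {
    badRole <- !(pp$role %in% participantRoles())
    if (any(badRole))
      v <- c(v, list(.violation(pp$reaction_id[badRole], "participant_role",
        sprintf("unknown role '%s'", pp$role[badRole]))))
    badForm <- !(pp$form %in% participantForms())
    if (any(badForm))
      v <- c(v, list(.violation(pp$reaction_id[badForm], "participant_form",
        sprintf("unknown form '%s'", pp$form[badForm]))))
    known <- c(normId(x@entities$id), normId(cl$cluster_id))
    orphan <- !(normId(pp$node_id) %in% known)
    if (any(orphan))
      v <- c(v, list(.violation(pp$node_id[orphan], "participant_node",
        "participant node is neither an entity nor a cluster")))
    orphanRx <- !(normId(pp$reaction_id) %in% normId(rx$reaction_id))
    if (any(orphanRx))
      v <- c(v, list(.violation(pp$reaction_id[orphanRx], "participant_reaction",
        "participant references an unknown reaction")))
  }
  out <- do.call(rbind, v)
  if (is.null(out)) .emptyViolations() else out
})

.validateEntities <- function(en) {
  v <- list(.emptyViolations())
  if (!nrow(en)) return(v[[1]])
  dup <- duplicated(normId(en$id))
  if (any(dup))
    v <- c(v, list(.violation(en$id[dup], "entity_id", "duplicate entity id")))
  empty <- !nzchar(trimws(en$id))
  if (any(empty))
    v <- c(v, list(.violation("<empty>", "entity_id", "empty entity id")))
  badType <- !(en$entity_type %in% entityTypes())
  if (any(badType))
    v <- c(v, list(.violation(en$id[badType], "entity_type",
      sprintf("unknown entity type '%s'", en$entity_type[badType]))))
  badOrig <- !(en$origin %in% entityOrigins())
  if (any(badOrig))
    v <- c(v, list(.violation(en$id[badOrig], "origin",
      sprintf("unknown origin '%s'", en$origin[badOrig]))))
  foreignBad <- en$origin == "foreign" &
    !(en$entity_type %in% .foreignEntityTypes)
  if (any(foreignBad))
    v <- c(v, list(.violation(en$id[foreignBad], "foreign_origin",
      "foreign origin only allowed for foreign/abstract/process entities")))
  do.call(rbind, v)
}

## canonical condensation key: unordered pair for undirected edges, ordered
## pair for directed ones, plus the interaction type
condensedEdgeKey <- function(ed) {
  ns <- normId(ed$source_id); nt <- normId(ed$target_id)
  lo <- pmin(ns, nt); hi <- pmax(ns, nt)
  ifelse(ed$directed,
         paste(ns, nt, ed$interaction_type, "d", sep = "\r"),
         paste(lo, hi, ed$interaction_type, "u", sep = "\r"))
}

setMethod("show", "KnowledgeNetwork", function(object) {
  cat(sprintf("KnowledgeNetwork with %d entities and %d edges\n",
              nEntities(object), nEdges(object)))
  if (nEdges(object)) {
    tb <- table(object@edges$rank)
    cat("  edges by rank:",
        paste(sprintf("%s:%d", names(tb), as.integer(tb)), collapse = " "),
        "\n")
  }
})

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf(paste0("ReactionNetwork with %d entities, %d clusters, ",
                     "%d reactions, %d participant links\n"),
              nrow(object@entities), nrow(object@clusters),
              nrow(object@reactions), nrow(object@participants)))
})

setMethod("show", "PathQueryResult", function(object) {
  cat(sprintf(paste0("PathQueryResult (%s): %d source(s), %d target(s), ",
                     "%d shortest path(s)%s\n"),
              object@mode, length(object@sources), length(object@targets),
              length(object@paths),
              if (object@truncated) " [truncated]" else ""))
})

setMethod("show", "CutResult", function(object) {
  cat(sprintf("CutResult: capacity %g = flow %g; %d cut edge(s)%s\n",
              object@cutCapacity, object@flowValue, nrow(object@cutEdges),
              if (length(object@cutNodes))
                paste0("; knocked-out nodes: ",
                       paste(object@cutNodes, collapse = ", "))
              else ""))
})
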