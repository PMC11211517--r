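## Lossless tabular serialization and the reaction-network JSON interchange.

#' Write / read the full network as node and edge TSV tables
#'
#' Lossless serialization of every entity and edge attribute (rank, sign,
#' provenance included) with canonical column order and canonical row order,
#' so the same network always yields byte-identical files and a round trip
#' restores an identical network.
#'
#' @param net A [KnowledgeNetwork-class].
#' @param node_path,edge_path TSV paths.
#' @return `writeNetworkTables` returns the paths invisibly;
#'   `readNetworkTables` returns a [KnowledgeNetwork-class].
#' @export
writeNetworkTables <- function(net, node_path, edge_path) {
  en <- entities(net)
  en <- en[order(normId(en$id)), names(ENTITY_COLS), drop = FALSE]
  ed <- edges(net)
  ed <- ed[.canonicalEdgeOrder(ed), names(EDGE_COLS), drop = FALSE]
  utils::write.table(en, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(ed, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(node_path, edge_path))
}

#' @rdname writeNetworkTables
#' @export
readNetworkTables <- function(node_path, edge_path) {
  en <- utils::read.delim(node_path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "NA")
  ed <- utils::read.delim(edge_path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "NA")
  missN <- setdiff(names(ENTITY_COLS), names(en))
  missE <- setdiff(names(EDGE_COLS), names(ed))
  if (length(missN) || length(missE))
    stop("schema mismatch; missing column(s): ",
         paste(c(missN, missE), collapse = ", "), call. = FALSE)
  en$stub <- as.logical(en$stub)
  en$tissues[is.na(en$tissues)] <- ""
  en$external_refs[is.na(en$external_refs)] <- ""
  ed$directed <- as.logical(ed$directed)
  ed$rank <- as.integer(ed$rank)
  ed$provenance[is.na(ed$provenance)] <- ""
  knowledgeNetwork(entities = fillColumns(en, ENTITY_COLS),
                   edges = fillColumns(ed, EDGE_COLS))
}

#' Read / write a reaction network as structured JSON
#'
#' The interchange document has four arrays: `entities` (id, short_name,
#' entity_type, origin, species, tissues, external_refs), `clusters`
#' (cluster_id, member_gene_ids), `reactions` (reaction_id, reaction_type,
#' provenance, source_sink) and `participants` (reaction_id, node_id, role,
#' location, form). Unknown role or form tokens are an error naming the
#' token; other domain violations are reported through
#' [validateNetwork()] and attached as `metadata(rn)$load_violations`.
#'
#' @param path JSON file path.
#' @param rn A [ReactionNetwork-class] (for writing).
#' @return `readReactionNetwork`: a [ReactionNetwork-class].
#' @export
readReactionNetwork <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  toDF <- function(x, template) {
    if (is.null(x) || (is.data.frame(x) && !nrow(x)) || !length(x))
      return(emptyFrame(template))
    if (!is.data.frame(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
    fillColumns(x, template)
  }
  pp <- toDF(doc$participants, PARTICIPANT_COLS)
  badRole <- setdiff(unique(pp$role), participantRoles())
  stopIfNot(length(badRole) == 0,
            paste0("unknown participant role token: ",
                   paste(badRole, collapse = ", ")))
  badForm <- setdiff(unique(pp$form), participantForms())
  stopIfNot(length(badForm) == 0,
            paste0("unknown participant form token: ",
                   paste(badForm, collapse = ", ")))
  rn <- reactionNetwork(entities = toDF(doc$entities, ENTITY_COLS),
                        clusters = toDF(doc$clusters, CLUSTER_COLS),
                        reactions = toDF(doc$reactions, REACTION_COLS),
                        participants = pp)
  viol <- validateNetwork(rn)
  viol <- viol[viol$rule != "multi_cluster_membership", , drop = FALSE]
  if (nrow(viol)) {
    md <- metadata(rn)
    md$load_violations <- viol
    metadata(rn) <- md
    warning(nrow(viol), " validation issue(s) in ", path,
            "; see metadata(rn)$load_violations")
  }
  rn
}

#' @rdname readReactionNetwork
#' @export
writeReactionNetwork <- function(rn, path) {
  doc <- list(entities = entities(rn), clusters = clusters(rn),
              reactions = reactions(rn), participants = participants(rn))
  jsonlite::write_json(doc, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
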