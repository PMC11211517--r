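## SIF and DOT exporters. All writers are deterministic: edges are emitted
## in canonical sorted order so the same network always produces a
## byte-identical file.

.canonicalEdgeOrder <- function(ed) {
  order(normId(ed$source_id), normId(ed$target_id), ed$interaction_type,
        !ed$directed, ed$sign)
}

#' Write / read simple interaction format (SIF)
#'
#' One line per edge: `source <TAB> interaction_type <TAB> target`. SIF
#' carries only the skeleton; rank, directionality, sign and provenance are
#' written to an optional sidecar edge-attribute TSV and restored from it on
#' read. Without a sidecar, directionality is inferred from the interaction
#' type (binding = undirected) and rank/sign default to 4/"unknown".
#'
#' @param net A [KnowledgeNetwork-class].
#' @param path SIF file path.
#' @param attr_path Optional sidecar TSV path.
#' @return `writeSif` returns `path` invisibly; `readSif` returns a
#'   [KnowledgeNetwork-class] skeleton.
#' @export
writeSif <- function(net, path, attr_path = NULL) {
  ed <- edges(net)
  ed <- ed[.canonicalEdgeOrder(ed), , drop = FALSE]
  lines <- if (nrow(ed))
    paste(ed$source_id, ed$interaction_type, ed$target_id, sep = "\t")
  else character(0)
  writeLines(lines, path)
  if (!is.null(attr_path)) {
    at <- data.frame(source_id = ed$source_id, target_id = ed$target_id,
                     interaction_type = ed$interaction_type,
                     directed = ed$directed, sign = ed$sign, rank = ed$rank,
                     provenance = ed$provenance, stringsAsFactors = FALSE)
    utils::write.table(at, attr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeSif
#' @export
readSif <- function(path, attr_path = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(knowledgeNetwork())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) != 3)
  if (length(bad))
    stop("malformed SIF line ", bad[1], ": '", lines[bad[1]], "'",
         call. = FALSE)
  ed <- data.frame(source_id = vapply(parts, `[`, "", 1),
                   interaction_type = vapply(parts, `[`, "", 2),
                   target_id = vapply(parts, `[`, "", 3),
                   stringsAsFactors = FALSE)
  if (!is.null(attr_path) && file.exists(attr_path)) {
    at <- utils::read.delim(attr_path, stringsAsFactors = FALSE)
    ed <- merge(ed, at, by = c("source_id", "target_id", "interaction_type"),
                all.x = TRUE, sort = FALSE)
  } else {
    ed$directed <- ed$interaction_type != "binding"
    ed$sign <- "unknown"
    ed$rank <- 4L
    ed$provenance <- "sif"
  }
  ed <- fillColumns(ed, EDGE_COLS)
  ed <- ed[.canonicalEdgeOrder(ed), , drop = FALSE]
  rownames(ed) <- NULL
  ids <- unique(c(ed$source_id, ed$target_id))
  en <- do.call(rbind, lapply(ids[!duplicated(normId(ids))], function(i)
    entityRecord(i, stub = TRUE)))
  knowledgeNetwork(entities = en[order(normId(en$id)), , drop = FALSE],
                   edges = ed)
}

#' Write a Graphviz DOT file
#'
#' Emits a valid `digraph`: activation edges get a normal arrowhead,
#' inhibition edges a tee head, unknown-sign directed edges an open vee, and
#' undirected binding edges are drawn dashed without direction. Identifiers
#' are always quoted (with embedded quotes escaped).
#'
#' @param net A [KnowledgeNetwork-class].
#' @param path Output path.
#' @param graph_name Name of the digraph.
#' @return `path`, invisibly.
#' @export
writeDot <- function(net, path, graph_name = "network") {
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  en <- entities(net)
  ed <- edges(net)
  ed <- ed[.canonicalEdgeOrder(ed), , drop = FALSE]
  lines <- c(sprintf("digraph %s {", q(graph_name)))
  for (i in order(normId(en$id)))
    lines <- c(lines, sprintf("  %s [label=%s];", q(en$id[i]),
                              q(en$short_name[i])))
  if (nrow(ed)) {
    style <- ifelse(!ed$directed,
                    "dir=none, style=dashed",
                    ifelse(ed$sign == "inhibition",
                           "arrowhead=tee, style=solid",
                           ifelse(ed$sign == "activation",
                                  "arrowhead=normal, style=solid",
                                  "arrowhead=vee, style=solid")))
    lines <- c(lines, sprintf("  %s -> %s [%s, rank=%d];",
                              q(ed$source_id), q(ed$target_id), style,
                              ed$rank))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
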