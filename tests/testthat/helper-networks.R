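# Small hand-built networks used across test files.

mkNet <- function(edge_list, extra_nodes = character(0)) {
  ed <- do.call(rbind, lapply(edge_list, function(e) {
    data.frame(source_id = e$s, target_id = e$t,
               interaction_type = e$type %||% "tf_regulation",
               directed = e$directed %||% TRUE,
               sign = e$sign %||% "activation",
               rank = as.integer(e$rank %||% 1L),
               provenance = e$prov %||% "test",
               stringsAsFactors = FALSE)
  }))
  ids <- unique(c(if (!is.null(ed)) c(ed$source_id, ed$target_id),
                  extra_nodes))
  en <- do.call(rbind, lapply(ids, entityRecord))
  knowledgeNetwork(entities = en, edges = ed)
}

e <- function(s, t, ...) c(list(s = s, t = t), list(...))

`%||%` <- function(a, b) if (is.null(a)) b else a

rawRow <- function(s, t, type = "binding", directed = FALSE,
                   sign = "unknown", class = "high_throughput",
                   resource = "res1", ref = "") {
  data.frame(source_id = s, target_id = t, interaction_type = type,
             directed = directed, sign = sign, evidence_class = class,
             resource_name = resource, reference = ref,
             stringsAsFactors = FALSE)
}
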