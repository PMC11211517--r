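## Generics and accessors.

#' @rdname accessors
#' @export
setGeneric("entities", function(x) standardGeneric("entities"))

#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))

#' @rdname accessors
#' @export
setGeneric("participants", function(x) standardGeneric("participants"))

#' @rdname accessors
#' @export
setGeneric("nEntities", function(x) standardGeneric("nEntities"))

#' @rdname accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname accessors
#' @export
setGeneric("metadata", function(x) standardGeneric("metadata"))

#' @rdname accessors
#' @export
setGeneric("metadata<-", function(x, value) standardGeneric("metadata<-"))

#' @rdname graph-model
#' @export
setGeneric("addEntity", function(x, entity) standardGeneric("addEntity"))

#' @rdname graph-model
#' @export
setGeneric("validateNetwork",
           function(x, ...) standardGeneric("validateNetwork"))

## Accessor documentation stub
#' Accessors for network containers
#'
#' `entities()`, `edges()`, `clusters()`, `reactions()`, `participants()`
#' return the underlying data.frames; `nEntities()` / `nEdges()` count them;
#' `metadata()` reads or replaces the free-form metadata list.
#'
#' @param x A [KnowledgeNetwork-class] or [ReactionNetwork-class].
#' @param value Replacement metadata list.
#' @return A data.frame, count, or list as appropriate.
#' @name accessors
NULL
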