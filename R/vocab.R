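## Controlled vocabularies shared across the data model.

#' Controlled vocabularies
#'
#' Closed vocabularies used throughout the package: entity types, entity
#' origins, interaction types, regulatory signs, evidence classes (which map
#' one-to-one onto reliability ranks 0--4), participant roles and molecular
#' forms.
#'
#' @format Character vectors (and, for [evidenceClasses()], a named integer
#'   vector mapping class to rank).
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
entityTypes <- function() {
  c("gene", "protein", "complex", "metabolite", "metabolite_family",
    "ncRNA", "process", "abstract", "foreign")
}

#' @rdname vocabularies
#' @export
entityOrigins <- function() c("plant", "foreign")

## entity types a foreign-origin node may take
.foreignEntityTypes <- c("foreign", "abstract", "process")

#' @rdname vocabularies
#' @export
interactionTypes <- function() {
  c("binding", "tf_regulation", "ncRNA_interaction", "ptm", "other")
}

#' @rdname vocabularies
#' @export
interactionSigns <- function() c("activation", "inhibition", "unknown")

#' Evidence classes and reliability ranks
#'
#' The five evidence classes map bijectively onto reliability ranks 0--4:
#' manually curated reactions from the hand-built signaling model rank best
#' (0), targeted experimental evidence ranks 1, purely high-throughput
#' detection ranks 2, literature extraction or validated predictions rank 3,
#' and purely in-silico predictions rank worst (4).
#'
#' @return Named integer vector mapping evidence class to rank.
#' @export
evidenceClasses <- function() {
  c(curated_pss = 0L,
    targeted_experimental = 1L,
    high_throughput = 2L,
    literature_or_validated_prediction = 3L,
    in_silico_prediction = 4L)
}

#' @rdname vocabularies
#' @export
participantRoles <- function() {
  c("SUBSTRATE", "PRODUCT", "ACTIVATES", "INHIBITS", "CATALYZES",
    "TRANSPORT_FROM", "TRANSPORT_TO")
}

## roles on the input (regulator/substrate) side of a reaction vs. the
## output (product) side; used by the bipartite projection
.inputRoles  <- c("SUBSTRATE", "ACTIVATES", "INHIBITS", "CATALYZES",
                  "TRANSPORT_FROM")
.outputRoles <- c("PRODUCT", "TRANSPORT_TO")

#' @rdname vocabularies
#' @export
participantForms <- function() {
  c("gene", "transcript", "protein", "metabolite", "complex", "unspecified")
}

#' Formal reaction types
#'
#' The reaction-type vocabulary is configuration data: a default set of ten
#' formal types ships with the package and can be replaced by pointing
#' `file` at a one-column text file.
#'
#' @param file Path to a plain-text vocabulary file, one type per line;
#'   defaults to the file shipped in `extdata`.
#' @return Character vector of reaction types.
#' @export
reactionTypes <- function(file = system.file("extdata", "reaction_types.txt",
                                             package = "stressnet")) {
  x <- readLines(file, warn = FALSE)
  x <- trimws(x[!grepl("^\\s*(#|$)", x)])
  unique(x)
}

## ---- identifier handling ---------------------------------------------------

## Identifiers are compared case-insensitively after trimming; the stored
## form keeps the input capitalization.
normId <- function(x) tolower(trimws(as.character(x)))

## split/join for set-valued character fields serialized as ";"-joined strings
splitSet <- function(x) {
  if (length(x) == 0 || is.na(x) || !nzchar(x)) character(0)
  else strsplit(x, ";", fixed = TRUE)[[1]]
}

joinSet <- function(x) paste(sort(unique(x[nzchar(x)])), collapse = ";")

## run expr under a fixed seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
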