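## Two-contrast omics responder filtering and network annotation.
##
## The design emulated here: a stimulus contrast (e.g. peroxide vs. mock)
## and a conditional contrast (stimulus under a blocker vs. blocker only),
## each measured at one or more timepoints as log2 fold changes with
## FDR-adjusted significance. Condition-dependent responders are proteins
## significantly regulated by the stimulus whose response disappears under
## the blocker.

#' Describe a primary/conditional contrast pair
#'
#' @param primary Character vector of primary-contrast labels, one per
#'   timepoint (column suffixes `L_<label>` / `q_<label>` in the table).
#' @param conditional Conditional-contrast labels, aligned with `primary`.
#' @param delta_threshold Minimum `abs(L1 - L2)` between the two contrasts
#'   (log2 units); default 1.
#' @param fc_threshold Fold-change cutoff on the natural scale; default 1.5
#'   (i.e. |log2FC| > log2(1.5)).
#' @param fdr_threshold FDR cutoff; default 0.05.
#' @return A `ContrastPair` list.
#' @export
contrastPair <- function(primary, conditional, delta_threshold = 1,
                         fc_threshold = 1.5, fdr_threshold = 0.05) {
  stopIfNot(length(primary) == length(conditional) && length(primary) >= 1,
            "primary and conditional must be aligned, nonempty label vectors")
  stopIfNot(delta_threshold > 0 && fc_threshold > 0, "thresholds must be > 0")
  stopIfNot(fdr_threshold > 0 && fdr_threshold < 1,
            "fdr_threshold must be in (0,1)")
  structure(list(primary = primary, conditional = conditional,
                 delta_threshold = delta_threshold,
                 fc_threshold = fc_threshold,
                 fdr_threshold = fdr_threshold),
            class = "ContrastPair")
}

#' Replicate-detection filter
#'
#' Keeps protein groups detected in at least `min_detected` of
#' `n_replicates` replicates in at least one treatment group (default: three
#' of five).
#'
#' @param table Omics data.frame with `detected_<group>` columns.
#' @param min_detected Minimum detections required; default 3.
#' @param n_replicates Replicates per treatment group; default 5.
#' @return Filtered table.
#' @export
replicateFilter <- function(table, min_detected = 3, n_replicates = 5) {
  stopIfNot(min_detected <= n_replicates,
            "min_detected cannot exceed n_replicates")
  cols <- grep("^detected_", names(table), value = TRUE)
  stopIfNot(length(cols) > 0, "no detected_<group> columns present")
  counts <- as.matrix(table[, cols, drop = FALSE])
  stopIfNot(all(counts >= 0 & counts <= n_replicates, na.rm = TRUE),
            "detection counts outside [0, n_replicates]")
  keep <- apply(counts, 1, function(x) any(x >= min_detected, na.rm = TRUE))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Significance call for one contrast
#'
#' `up` when L > log2(fc_threshold) and q < fdr_threshold, `down` when
#' L < -log2(fc_threshold) and q < fdr_threshold, else `ns`. Missing values
#' yield `ns` (flagged via the "missing" attribute).
#'
#' @param L log2 fold change(s).
#' @param q FDR-adjusted significance value(s).
#' @param fc_threshold Fold-change cutoff (natural scale); default 1.5.
#' @param fdr_threshold FDR cutoff; default 0.05.
#' @return Character vector in {"up","down","ns"}.
#' @examples
#' significanceCall(1.0, 0.01)   # "up": 1.0 > log2(1.5) ~ 0.585
#' significanceCall(-0.3, 0.001) # "ns": |L| below log2(1.5)
#' @export
significanceCall <- function(L, q, fc_threshold = 1.5, fdr_threshold = 0.05) {
  cut <- log2(fc_threshold)
  out <- rep("ns", length(L))
  miss <- is.na(L) | is.na(q)
  ok <- !miss & q < fdr_threshold
  out[ok & L > cut] <- "up"
  out[ok & L < -cut] <- "down"
  attr(out, "missing") <- which(miss)
  out
}

#' Condition-dependent responders from a two-contrast design
#'
#' A protein group responds at a timepoint when (i) it is significantly
#' regulated in the primary contrast, (ii) it is *not* significantly
#' regulated in the same direction in the conditional contrast (the
#' direction-specific subtraction: an up is only cancelled by an up), and
#' (iii) the fold changes differ compellingly, `abs(L1 - L2) >=
#' delta_threshold`. The responder set is the union over timepoints.
#'
#' @param table Omics data.frame with `L_<label>` / `q_<label>` columns for
#'   every label in `pair`.
#' @param pair A [contrastPair()].
#' @return Character vector of responder `group_id`s.
#' @export
dependentResponders <- function(table, pair) {
  stopIfNot(inherits(pair, "ContrastPair"), "pair must be a ContrastPair")
  resp <- rep(FALSE, nrow(table))
  for (k in seq_along(pair$primary)) {
    Lc <- paste0("L_", pair$primary[k]); qc <- paste0("q_", pair$primary[k])
    Lb <- paste0("L_", pair$conditional[k])
    qb <- paste0("q_", pair$conditional[k])
    for (col in c(Lc, qc, Lb, qb))
      stopIfNot(col %in% names(table),
                paste0("missing contrast column: ", col))
    call1 <- significanceCall(table[[Lc]], table[[qc]],
                              pair$fc_threshold, pair$fdr_threshold)
    call2 <- significanceCall(table[[Lb]], table[[qb]],
                              pair$fc_threshold, pair$fdr_threshold)
    delta <- abs(table[[Lc]] - table[[Lb]])
    delta[is.na(delta)] <- 0
    resp <- resp | (call1 %in% c("up", "down") & call2 != call1 &
                      delta >= pair$delta_threshold)
  }
  table$group_id[resp]
}

#' Assign multi-group identifiers to a single group
#'
#' Identifiers occurring in multiple protein groups are removed from the
#' group(s) where they occur the least, i.e. each identifier is kept only in
#' its highest-occurrence group. Ties are broken by the group with more
#' total evidence, then by lexicographic group id; tie-broken assignments
#' are flagged in the report.
#'
#' @param membership data.frame with columns `identifier`, `group_id`,
#'   `count` (per-group occurrence of the identifier) and optionally
#'   `evidence` (total evidence for the group).
#' @return data.frame mapping each identifier to exactly one group, with a
#'   `tie_broken` flag.
#' @export
disambiguateGroups <- function(membership) {
  for (col in c("identifier", "group_id", "count"))
    stopIfNot(col %in% names(membership),
              paste0("membership needs column '", col, "'"))
  if (!"evidence" %in% names(membership)) membership$evidence <- 0
  parts <- split(membership, membership$identifier)
  rows <- lapply(parts, function(m) {
    best <- m$count == max(m$count)
    tie <- sum(best) > 1
    m <- m[best, , drop = FALSE]
    if (nrow(m) > 1) m <- m[m$evidence == max(m$evidence), , drop = FALSE]
    if (nrow(m) > 1) m <- m[order(m$group_id)[1], , drop = FALSE]
    data.frame(identifier = m$identifier[1], group_id = m$group_id[1],
               tie_broken = tie, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$identifier), , drop = FALSE]
}

#' Join omics measurements onto network nodes
#'
#' Matches protein-group member identifiers to network entity ids
#' (case-insensitive; optionally through an explicit `id_map`) and attaches
#' a per-node measurement table (timepoint x contrast log fold changes with
#' significance calls) plus responder flags. Unmatched groups are reported.
#'
#' @param net A [KnowledgeNetwork-class].
#' @param table Omics data.frame (`group_id`, `member_ids` ";"-joined,
#'   contrast columns).
#' @param pair A [contrastPair()] naming the contrast columns to attach.
#' @param responders Character vector of responder group ids (e.g. from
#'   [dependentResponders()]).
#' @param id_map Optional data.frame (`member_id`, `node_id`) overriding the
#'   direct identifier join.
#' @return The network with `metadata(net)$omics` holding `measurements`
#'   (long data.frame: node_id, group_id, contrast, L, q, call, responder)
#'   and `unmatched` (group ids matching no node).
#' @export
annotateNodes <- function(net, table, pair, responders = character(0),
                          id_map = NULL) {
  en <- entities(net)
  rows <- list()
  unmatched <- character(0)
  labels <- c(pair$primary, pair$conditional)
  for (i in seq_len(nrow(table))) {
    members <- splitSet(table$member_ids[i])
    if (!is.null(id_map)) {
      members <- id_map$node_id[normId(id_map$member_id) %in% normId(members)]
    }
    hit <- en$id[normId(en$id) %in% normId(members)]
    if (!length(hit)) {
      unmatched <- c(unmatched, table$group_id[i])
      next
    }
    for (node in hit) for (lab in labels) {
      L <- table[[paste0("L_", lab)]][i]
      q <- table[[paste0("q_", lab)]][i]
      rows <- c(rows, list(data.frame(
        node_id = node, group_id = table$group_id[i], contrast = lab,
        L = L, q = q,
        call = significanceCall(L, q, pair$fc_threshold,
                                pair$fdr_threshold)[1],
        responder = table$group_id[i] %in% responders,
        stringsAsFactors = FALSE)))
    }
  }
  meas <- do.call(rbind, c(list(data.frame(
    node_id = character(0), group_id = character(0), contrast = character(0),
    L = numeric(0), q = numeric(0), call = character(0),
    responder = logical(0))), rows))
  rownames(meas) <- NULL
  md <- metadata(net)
  md$omics <- list(measurements = meas, unmatched = unmatched)
  metadata(net) <- md
  net
}

#' Source set from ontology/bin annotations
#'
#' Takes the union of genes annotated with any of the listed terms and, when
#' a network is supplied, intersects it with the network's nodes.
#'
#' @param annotations data.frame with columns `gene_id`, `term_id`.
#' @param term_ids Character vector of ontology/bin term ids.
#' @param net Optional [KnowledgeNetwork-class] to intersect with.
#' @return Character vector of gene ids (empty with a warning when no gene
#'   carries any term).
#' @export
sourceSetFromAnnotations <- function(annotations, term_ids, net = NULL) {
  hit <- annotations$gene_id[annotations$term_id %in% term_ids]
  hit <- hit[!duplicated(normId(hit))]
  if (!is.null(net)) {
    en <- entities(net)
    hit <- en$id[normId(en$id) %in% normId(hit)]
  }
  if (!length(hit)) warning("no gene carries any of the requested terms")
  sort(hit)
}
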