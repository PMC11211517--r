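## Boolean-network compilation, the "targets, factors" text dialect, and a
## synchronous simulator for the restricted rule grammar this package emits.
##
## Rule convention (the derivation convention is this package's documented
## choice): a node's next state is OR(activators) AND NOT OR(inhibitors).
## Nodes with no regulators are inputs and get the identity rule
## ("A, A"); nodes with inhibitors but no activators are constitutively on
## unless inhibited ("!(I1 | I2)"). Undirected edges carry no causal
## direction and are excluded from compilation (reported); so are edges of
## unknown sign (warned).

#' Compile a network to Boolean update rules
#'
#' For a [KnowledgeNetwork-class], only directed edges with a known sign are
#' used; for a [ReactionNetwork-class], the network is first projected via
#' [bipartiteProjection()].
#'
#' @param x A [KnowledgeNetwork-class] or [ReactionNetwork-class].
#' @return A `BoolRuleSet`: data.frame with columns `target`, `activators`,
#'   `inhibitors` (";"-joined) and `factors` (the rule expression), one row
#'   per node, plus attributes `excluded_undirected` / `excluded_unknown`.
#' @export
compileBoolnet <- function(x) {
  if (is(x, "ReactionNetwork")) x <- bipartiteProjection(x)
  stopIfNot(is(x, "KnowledgeNetwork"),
            "x must be a KnowledgeNetwork or ReactionNetwork")
  ed <- edges(x)
  exclUnd <- ed[!ed$directed, , drop = FALSE]
  exclUnk <- ed[ed$directed & ed$sign == "unknown", , drop = FALSE]
  if (nrow(exclUnk))
    warning(nrow(exclUnk), " directed edge(s) of unknown sign excluded ",
            "from Boolean compilation")
  use <- ed[ed$directed & ed$sign %in% c("activation", "inhibition"), ,
            drop = FALSE]
  nodes <- entities(x)$id
  rules <- do.call(rbind, lapply(nodes, function(v) {
    inc <- use[normId(use$target_id) == normId(v), , drop = FALSE]
    act <- sort(unique(inc$source_id[inc$sign == "activation"]))
    inh <- sort(unique(inc$source_id[inc$sign == "inhibition"]))
    factors <- if (!length(act) && !length(inh)) v
    else if (!length(inh)) paste(act, collapse = " | ")
    else if (!length(act)) paste0("!(", paste(inh, collapse = " | "), ")")
    else paste0("(", paste(act, collapse = " | "), ") & !(",
                paste(inh, collapse = " | "), ")")
    data.frame(target = v, activators = joinSet(act),
               inhibitors = joinSet(inh), factors = factors,
               stringsAsFactors = FALSE)
  }))
  rules <- rules[order(normId(rules$target)), , drop = FALSE]
  rownames(rules) <- NULL
  structure(rules, class = c("BoolRuleSet", "data.frame"),
            excluded_undirected = exclUnd, excluded_unknown = exclUnk)
}

#' Write / read the boolnet "targets, factors" dialect
#'
#' @param rules A `BoolRuleSet` from [compileBoolnet()] (or compatible
#'   data.frame with `target` and `factors` columns).
#' @param path File path.
#' @return `writeBoolnet` returns `path` invisibly; `readBoolnet` returns a
#'   `BoolRuleSet`. Only the restricted grammar emitted by
#'   [compileBoolnet()] is parsed: an identity token, a disjunction of
#'   activators, `!(inhibitors)`, or `(activators) & !(inhibitors)`.
#' @export
writeBoolnet <- function(rules, path) {
  lines <- c("targets, factors",
             paste(rules$target, rules$factors, sep = ", "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeBoolnet
#' @export
readBoolnet <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  stopIfNot(length(lines) >= 1 &&
              grepl("^\\s*targets\\s*,\\s*factors\\s*$", lines[1]),
            "not a boolnet file: missing 'targets, factors' header")
  body <- lines[-1]
  rows <- lapply(seq_along(body), function(i) {
    m <- regmatches(body[i], regexec("^\\s*([^,]+?)\\s*,\\s*(.+?)\\s*$",
                                     body[i]))[[1]]
    stopIfNot(length(m) == 3,
              paste0("malformed boolnet line ", i + 1, ": ", body[i]))
    target <- m[2]; expr <- m[3]
    toks <- function(x) {
      x <- trimws(strsplit(x, "|", fixed = TRUE)[[1]])
      x <- x[nzchar(x)]
      bad <- grepl("[^A-Za-z0-9_.:-]", x)
      if (any(bad))
        stop("unsupported boolnet expression on line ", i + 1, ": ", expr,
             call. = FALSE)
      x
    }
    if (grepl("^\\(.*\\)\\s*&\\s*!\\(.*\\)$", expr)) {
      p <- regmatches(expr,
        regexec("^\\((.*)\\)\\s*&\\s*!\\((.*)\\)$", expr))[[1]]
      act <- toks(p[2]); inh <- toks(p[3])
    } else if (grepl("^!\\(.*\\)$", expr)) {
      act <- character(0)
      inh <- toks(sub("^!\\((.*)\\)$", "\\1", expr))
    } else if (!grepl("[&!()]", expr)) {
      tk <- toks(expr)
      if (length(tk) == 1 && tk == target) {
        act <- character(0); inh <- character(0)
      } else {
        act <- tk; inh <- character(0)
      }
    } else {
      stop("unsupported boolnet expression on line ", i + 1, ": ", expr,
           call. = FALSE)
    }
    data.frame(target = target, activators = joinSet(act),
               inhibitors = joinSet(inh), factors = expr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ids <- unique(c(out$target, unlist(lapply(out$activators, splitSet)),
                  unlist(lapply(out$inhibitors, splitSet))))
  unknown <- setdiff(normId(ids), normId(out$target))
  stopIfNot(length(unknown) == 0,
            paste0("rule references unknown node(s): ",
                   paste(unknown, collapse = ", ")))
  rownames(out) <- NULL
  structure(out, class = c("BoolRuleSet", "data.frame"))
}

#' Synchronous Boolean simulation
#'
#' `boolnetStep` applies one synchronous update; `boolnetAttractor` iterates
#' until a fixed point or cycle; `boolnetTransitionTable` enumerates the
#' full synchronous transition table over all 2^n states.
#'
#' @param rules A `BoolRuleSet`.
#' @param state Named logical/0-1 vector over all rule targets.
#' @param max_iter Iteration cap for attractor search.
#' @return `boolnetStep`: the next state. `boolnetAttractor`: list with
#'   `type` ("fixed_point" or "cycle"), `states` (the attractor states) and
#'   `transient` (steps to reach it). `boolnetTransitionTable`: data.frame
#'   of from/to state strings.
#' @export
boolnetStep <- function(rules, state) {
  state <- stats::setNames(as.logical(state), names(state))
  stopIfNot(all(rules$target %in% names(state)),
            "state must cover every rule target")
  nxt <- vapply(seq_len(nrow(rules)), function(i) {
    act <- splitSet(rules$activators[i])
    inh <- splitSet(rules$inhibitors[i])
    if (!length(act) && !length(inh)) return(state[[rules$target[i]]])
    actOK <- if (length(act)) any(state[act]) else TRUE
    inhOK <- if (length(inh)) !any(state[inh]) else TRUE
    actOK && inhOK
  }, logical(1))
  stats::setNames(nxt, rules$target)
}

#' @rdname boolnetStep
#' @export
boolnetAttractor <- function(rules, state, max_iter = 1000L) {
  state <- stats::setNames(as.logical(state), names(state))
  seen <- character(0)
  traj <- list()
  for (i in seq_len(max_iter)) {
    key <- paste(as.integer(state[rules$target]), collapse = "")
    hit <- match(key, seen)
    if (!is.na(hit)) {
      states <- traj[hit:length(traj)]
      return(list(type = if (length(states) == 1) "fixed_point" else "cycle",
                  states = states, transient = hit - 1L))
    }
    seen <- c(seen, key)
    traj <- c(traj, list(state))
    state <- boolnetStep(rules, state)
  }
  stop("no attractor within max_iter steps", call. = FALSE)
}

#' @rdname boolnetStep
#' @export
boolnetTransitionTable <- function(rules) {
  n <- nrow(rules)
  stopIfNot(n <= 20, "transition table limited to 20 nodes")
  states <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  names(states) <- rules$target
  from <- to <- character(nrow(states))
  for (i in seq_len(nrow(states))) {
    s <- stats::setNames(as.logical(states[i, ]), rules$target)
    nx <- boolnetStep(rules, s)
    from[i] <- paste(as.integer(s), collapse = "")
    to[i] <- paste(as.integer(nx[rules$target]), collapse = "")
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}
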