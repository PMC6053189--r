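#' Asynchronous successors of a state
#'
#' Under the asynchronous update, exactly one unstable node changes per
#' transition: node i is unstable when its rule value differs from its
#' current value, and its update moves it one step toward the rule value
#' (for binary nodes, a flip). There is one successor per unstable node;
#' a state with no successor is a fixed point. Inputs and clamped nodes are
#' never unstable.
#'
#' @param network A [BooleanNetwork-class].
#' @param state A state: named logical/0-1 vector, a logical vector in node
#'   order, or a single encoded integer.
#' @return A logical matrix with one row per successor (zero rows at a fixed
#'   point), columns named by node.
#' @examples
#' toggle <- booleanNetwork(c(a = "NOT b", b = "NOT a"))
#' asynchronousSuccessors(toggle, c(a = 1, b = 1))
#' @export
asynchronousSuccessors <- function(network, state) {
  stopifnot(is(network, "BooleanNetwork"))
  enc <- if (is.numeric(state) && length(state) == 1L && is.null(names(state)))
    as.integer(state) else .encodeState(state, network@nodes)
  succ <- .succOf(network, enc)
  .decodeStates(succ, network@nodes)
}

## Encoded asynchronous successors of one encoded full state.
.succOf <- function(network, enc) {
  vals <- as.list(.decodeStates(enc, network@nodes)[1L, ])
  succ <- integer(0)
  clamped <- names(network@clamps)
  for (nm in setdiff(network@nodes, c(network@inputs, clamped))) {
    K <- evaluateRule(network@rules[[nm]], vals)
    if (xor(K, vals[[nm]]))
      succ <- c(succ, bitwXor(enc, bitwShiftL(1L, match(nm, network@nodes) - 1L)))
  }
  succ
}

#' Synchronous successor of a state
#'
#' All unclamped, non-input nodes are simultaneously set to their rule
#' values; deterministic.
#'
#' @inheritParams asynchronousSuccessors
#' @return A named logical vector (the unique successor).
#' @examples
#' toggle <- booleanNetwork(c(a = "NOT b", b = "NOT a"))
#' synchronousSuccessor(toggle, c(a = 1, b = 1))
#' @export
synchronousSuccessor <- function(network, state) {
  stopifnot(is(network, "BooleanNetwork"))
  enc <- if (is.numeric(state) && length(state) == 1L && is.null(names(state)))
    as.integer(state) else .encodeState(state, network@nodes)
  vals <- as.list(.decodeStates(enc, network@nodes)[1L, ])
  out <- unlist(vals)
  for (nm in setdiff(network@nodes, c(network@inputs, names(network@clamps))))
    out[[nm]] <- evaluateRule(network@rules[[nm]], vals)
  out
}

#' Exhaustively enumerate the stable states
#'
#' A stable state (fixed point) is a state where every unclamped node's rule
#' returns the node's current value and every clamped node sits at its clamp
#' value. Enumeration is exhaustive over all free-node assignments, so each
#' input combination contributes its own fixed points ("wild type" pools the
#' IR=0 and IR=1 slices). Order is deterministic: ascending integer encoding.
#'
#' @param network A [BooleanNetwork-class].
#' @param guard Maximum number of states for the exhaustive regime (default
#'   2^24); beyond it an error directs the user to the sampling path.
#' @return A logical matrix, one row per stable state, with the encoded
#'   states in \code{attr(, "encoded")}.
#' @examples
#' stableStates(booleanNetwork(c(a = "NOT b", b = "NOT a")))
#' @export
stableStates <- function(network, guard = .MAXSTATES) {
  stopifnot(is(network, "BooleanNetwork"))
  im <- .imageMap(network, guard)
  fps <- .subToFull(which(im$diff == 0L) - 1L, im)
  fps <- sort(fps)
  out <- .decodeStates(fps, network@nodes)
  attr(out, "encoded") <- fps
  out
}

#' Build a state transition graph
#'
#' @param network A [BooleanNetwork-class].
#' @param seeds \code{"full"} for the whole (clamp-consistent) state space,
#'   or a vector/matrix of seed states (encoded integers, or a logical
#'   matrix/vector) whose forward-reachable set is explored.
#' @param scheme Update scheme; asynchronous (default) gives one transition
#'   per unstable node, synchronous a single deterministic transition.
#' @param guard Exhaustive-regime guard (number of states).
#' @return A [StateTransitionGraph-class].
#' @examples
#' stg <- buildSTG(booleanNetwork(c(a = "NOT b", b = "NOT a")))
#' length(stg@states)
#' @export
buildSTG <- function(network, seeds = "full",
                     scheme = c("asynchronous", "synchronous"),
                     guard = .MAXSTATES) {
  stopifnot(is(network, "BooleanNetwork"))
  scheme <- match.arg(scheme)
  im <- .imageMap(network, guard)
  N <- 2^im$f
  if (identical(seeds, "full")) {
    keep <- NULL
  } else {
    seedEnc <- if (is.matrix(seeds) || is.logical(seeds) || !is.null(names(seeds)))
      as.integer(apply(rbind(seeds), 1L, .encodeState, nodes = network@nodes))
    else as.integer(seeds)
    seedSub <- .fullToSub(seedEnc, im)
    keep <- .forwardClosure(seedSub, im, scheme)
  }
  if (scheme == "asynchronous") {
    ed <- .subEdges(im)
    if (!is.null(keep)) {
      inKeep <- logical(N); inKeep[keep + 1L] <- TRUE
      sel <- inKeep[ed$from + 1L]
      ed$from <- ed$from[sel]; ed$to <- ed$to[sel]
    }
  } else {
    syncTo <- bitwXor(0:(N - 1L), im$diff)
    from <- which(im$diff != 0L) - 1L
    ed <- list(from = from, to = syncTo[from + 1L])
    if (!is.null(keep)) {
      inKeep <- logical(N); inKeep[keep + 1L] <- TRUE
      sel <- inKeep[ed$from + 1L]
      ed$from <- ed$from[sel]; ed$to <- ed$to[sel]
    }
  }
  states <- if (is.null(keep)) .subToFull(0:(N - 1L), im) else .subToFull(sort(keep), im)
  new("StateTransitionGraph", states = sort(states),
      from = .subToFull(ed$from, im), to = .subToFull(ed$to, im),
      scheme = scheme, network = network)
}

## Forward closure of a set of sub-states (vectorized BFS).
.forwardClosure <- function(seedSub, im, scheme = "asynchronous") {
  N <- 2^im$f
  visited <- logical(N)
  visited[seedSub + 1L] <- TRUE
  frontier <- unique(seedSub)
  while (length(frontier)) {
    nxt <- list()
    if (scheme == "asynchronous") {
      d <- im$diff[frontier + 1L]
      for (j in seq_len(im$f)) {
        sel <- bitwAnd(d, im$subBit[j]) != 0L
        if (any(sel)) nxt[[length(nxt) + 1L]] <- bitwXor(frontier[sel], im$subBit[j])
      }
    } else {
      nxt[[1L]] <- bitwXor(frontier, im$diff[frontier + 1L])
    }
    cand <- unique(unlist(nxt, use.names = FALSE))
    cand <- cand[!visited[cand + 1L]]
    visited[cand + 1L] <- TRUE
    frontier <- cand
  }
  which(visited) - 1L
}

## Backward closure from a set of sub-states over the asynchronous STG.
.backwardClosure <- function(targetSub, im) {
  N <- 2^im$f
  visited <- logical(N)
  visited[targetSub + 1L] <- TRUE
  frontier <- targetSub
  while (length(frontier)) {
    nxt <- list()
    for (j in seq_len(im$f)) {
      cand <- bitwXor(frontier, im$subBit[j])
      sel <- !visited[cand + 1L] & (bitwAnd(im$diff[cand + 1L], im$subBit[j]) != 0L)
      if (any(sel)) nxt[[length(nxt) + 1L]] <- cand[sel]
    }
    cand <- unique(unlist(nxt, use.names = FALSE))
    if (length(cand)) cand <- cand[!visited[cand + 1L]]
    visited[cand + 1L] <- TRUE
    frontier <- cand
  }
  which(visited) - 1L
}

#' Find all attractors of the asynchronous dynamics
#'
#' Attractors are the terminal strongly connected components (SCCs) of the
#' asynchronous state transition graph: fixed points (singletons) and
#' complex attractors (oscillations). For small state spaces the full STG is
#' decomposed into SCCs directly; for larger ones the fixed points are
#' enumerated first and the SCC decomposition is applied only to the states
#' that cannot reach any fixed point (computed by a vectorized backward
#' closure) — the two routes return identical attractors.
#'
#' @param network A [BooleanNetwork-class].
#' @param restriction Optional named vector fixing input nodes (e.g.
#'   \code{c(IR = 1)}): the search is restricted to that input slice.
#' @param guard Exhaustive-regime guard (number of states).
#' @return An [AttractorSet-class], fixed points first, each ordered by its
#'   smallest encoded state.
#' @examples
#' findAttractors(booleanNetwork(c(a = "NOT c", b = "a", c = "b")))
#' @export
findAttractors <- function(network, restriction = NULL, guard = .MAXSTATES) {
  stopifnot(is(network, "BooleanNetwork"))
  if (!is.null(restriction)) {
    bad <- setdiff(names(restriction), network@inputs)
    if (length(bad))
      stop("restriction may only fix input nodes; not inputs: ",
           paste(bad, collapse = ", "))
    network <- applyPerturbation(network, restriction)
  }
  im <- .imageMap(network, guard)
  N <- 2^im$f
  attractorsSub <-
    if (N <= 2^16) .attractorsBySCC(im) else .attractorsByClosure(im)
  states <- lapply(attractorsSub, function(s) sort(.subToFull(s, im)))
  kind <- ifelse(lengths(states) == 1L, "fixed_point", "complex")
  ord <- order(kind != "fixed_point", vapply(states, min, 0L))
  states <- states[ord]; kind <- kind[ord]
  att <- new("AttractorSet", states = states, kind = kind,
             phenotype = rep("Undefined", length(states)), network = network)
  if (length(network@outputs) == 3L)
    att@phenotype <- vapply(seq_along(states), function(i)
      classifyAttractor(att, i), "")
  att
}

## Terminal SCCs by full decomposition (igraph); sub coordinates.
.attractorsBySCC <- function(im) {
  N <- 2^im$f
  ed <- .subEdges(im)
  if (length(ed$from) == 0L) return(as.list(0:(N - 1L)))
  g <- igraph::make_graph(rbind(ed$from + 1L, ed$to + 1L), n = N, directed = TRUE)
  comp <- igraph::components(g, mode = "strong")$membership
  crossing <- comp[ed$from + 1L] != comp[ed$to + 1L]
  nonTerminal <- unique(comp[ed$from + 1L][crossing])
  terminal <- setdiff(unique(comp), nonTerminal)
  lapply(terminal, function(cc) which(comp == cc) - 1L)
}

## Fixed points + SCC decomposition of the residual (states that cannot
## reach a fixed point); sub coordinates.
.attractorsByClosure <- function(im) {
  fps <- which(im$diff == 0L) - 1L
  basin <- .backwardClosure(fps, im)
  out <- as.list(fps)
  N <- 2^im$f
  if (length(basin) < N) {
    inBasin <- logical(N); inBasin[basin + 1L] <- TRUE
    resid <- which(!inBasin) - 1L
    # residual is forward-closed: decompose its induced subgraph
    idx <- integer(N); idx[resid + 1L] <- seq_along(resid)
    ed <- .subEdges(im)
    sel <- !inBasin[ed$from + 1L]
    from <- idx[ed$from[sel] + 1L]; to <- idx[ed$to[sel] + 1L]
    g <- igraph::make_graph(rbind(from, to), n = length(resid), directed = TRUE)
    comp <- igraph::components(g, mode = "strong")$membership
    crossing <- comp[from] != comp[to]
    nonTerminal <- unique(comp[from][crossing])
    terminal <- setdiff(unique(comp), nonTerminal)
    out <- c(out, lapply(terminal, function(cc) resid[comp == cc]))
  }
  out
}

#' @describeIn AttractorSet-class Number of attractors.
#' @param x An \code{AttractorSet}.
#' @export
setMethod("length", "AttractorSet", function(x) length(x@states))

setMethod("show", "AttractorSet", function(object) {
  k <- length(object@states)
  cat(sprintf("AttractorSet with %d attractor%s (%d fixed point%s, %d complex)\n",
              k, if (k == 1L) "" else "s",
              sum(object@kind == "fixed_point"),
              if (sum(object@kind == "fixed_point") == 1L) "" else "s",
              sum(object@kind == "complex")))
  for (i in seq_len(k))
    cat(sprintf("  [%d] %s (%d state%s): %s\n", i, object@kind[i],
                length(object@states[[i]]),
                if (length(object@states[[i]]) == 1L) "" else "s",
                object@phenotype[i]))
})
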