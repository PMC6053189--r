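#' Enumerate the elementary circuits of the regulatory graph
#'
#' An elementary circuit (feedback loop) is a directed cycle of the inferred
#' regulatory graph with no repeated node other than the closure; self-loops
#' count as length-1 circuits. Rotations of the same cycle are identified:
#' the canonical form starts at the member that comes first in node
#' declaration order. Enumeration follows Johnson's algorithm (blocked
#' depth-first search from each root in turn), so the output order is
#' deterministic: by length, then by canonical node sequence.
#'
#' @param network A [BooleanNetwork-class], or a data.frame of edges with
#'   \code{source}/\code{target} columns as returned by
#'   [inferSignedEdges()].
#' @param maxCircuits Hard cap on the number of circuits; exceeding it is an
#'   explicit error (never a silent truncation).
#' @return A list of character vectors, each a canonical node cycle.
#' @examples
#' elementaryCircuits(booleanNetwork(c(a = "b", b = "a")))
#' @export
elementaryCircuits <- function(network, maxCircuits = 100000L) {
  if (is(network, "BooleanNetwork")) {
    edges <- inferSignedEdges(network)
    nodes <- network@nodes
  } else {
    edges <- network
    nodes <- unique(c(edges$source, edges$target))
  }
  si <- match(edges$source, nodes)
  ti <- match(edges$target, nodes)
  n <- length(nodes)
  adj <- lapply(seq_len(n), function(i) sort(ti[si == i]))
  circuits <- list()
  # Johnson's algorithm: for each root s (ascending), search the subgraph
  # induced by vertices >= s; every circuit is reported exactly once, with
  # its smallest vertex first (the canonical rotation).
  for (s in seq_len(n)) {
    blocked <- rep(FALSE, n)
    blist <- lapply(seq_len(n), function(i) integer(0))
    stack <- integer(0)
    unblock <- function(v) {
      blocked[v] <<- FALSE
      for (w in blist[[v]]) if (blocked[w]) unblock(w)
      blist[[v]] <<- integer(0)
    }
    circuit <- function(v) {
      found <- FALSE
      stack <<- c(stack, v)
      blocked[v] <<- TRUE
      for (w in adj[[v]]) {
        if (w < s) next
        if (w == s) {
          circuits[[length(circuits) + 1L]] <<- nodes[stack]
          if (length(circuits) > maxCircuits)
            stop("circuit cap exceeded (", maxCircuits, "); raise 'maxCircuits'")
          found <- TRUE
        } else if (!blocked[w]) {
          if (circuit(w)) found <- TRUE
        }
      }
      if (found) unblock(v)
      else for (w in adj[[v]]) {
        if (w < s) next
        if (!(v %in% blist[[w]])) blist[[w]] <<- c(blist[[w]], v)
      }
      stack <<- stack[-length(stack)]
      found
    }
    if (length(adj[[s]])) circuit(s)
  }
  ord <- order(lengths(circuits),
               vapply(circuits, paste, "", collapse = "\r"))
  circuits[ord]
}

#' Functionality of a feedback circuit
#'
#' A circuit is functional iff its functionality context is nonempty. Two
#' notions of context are offered:
#'
#' \describe{
#'   \item{\code{scope = "circuit"} (default)}{The context is a set of
#'   states of the \emph{complement} of the circuit: an assignment of the
#'   non-circuit nodes belongs to the context iff every circuit edge has a
#'   nonzero discrete derivative for \emph{all} values of the circuit
#'   members appearing among the edge targets' other regulators. A feedback
#'   circuit's functionality is thereby a property of the rest of the
#'   network, independent of the circuit's own state — the convention of
#'   feedback-circuit analysis in logical modeling.}
#'   \item{\code{scope = "state"}}{The context is the set of full network
#'   states in which every circuit edge has a nonzero derivative, each
#'   derivative taken in the regulator context given by that very state
#'   (the local interaction graph notion). This is strictly more permissive.}
#' }
#'
#' The circuit's sign is the product of its edge-derivative signs; positive
#' circuits enable multistationarity, negative circuits enable oscillations.
#' When the sign is not uniform across the context it is reported as
#' \code{"mixed-context"} rather than silently resolved. Contexts are
#' enumerated over the union of the circuit targets' regulators only
#' (clamped nodes held at their clamp value) and the count is scaled by the
#' remaining free nodes — exact, without scanning the full state space.
#' Clamping any circuit member makes the circuit non-functional.
#'
#' @param network A [BooleanNetwork-class].
#' @param circuit Character vector of nodes forming the cycle (consecutive
#'   pairs, closure included, must be edges of the regulatory graph).
#' @param scope Functionality notion, see Details.
#' @return A list with \code{functional}, \code{sign} (\code{"positive"},
#'   \code{"negative"}, \code{"mixed-context"} or \code{NA} when not
#'   functional) and \code{contextSize} (number of full states whose
#'   non-circuit part lies in the context; for \code{scope = "state"}, the
#'   plain number of states in the context).
#' @examples
#' circuitFunctionality(lncapNetwork(), c("p53-MAIN", "Mdm2"))
#' @export
circuitFunctionality <- function(network, circuit, scope = c("circuit", "state")) {
  stopifnot(is(network, "BooleanNetwork"), length(circuit) >= 1L)
  scope <- match.arg(scope)
  nodes <- network@nodes
  if (!all(circuit %in% nodes))
    stop("circuit names unknown node(s): ",
         paste(setdiff(circuit, nodes), collapse = ", "))
  srcs <- circuit
  tgts <- c(circuit[-1L], circuit[1L])
  clamped <- names(network@clamps)
  notFun <- list(functional = FALSE, sign = NA_character_, contextSize = 0)
  # an edge into an input or clamped node has no (varying) rule, and a
  # clamped source cannot vary: derivative 0 everywhere
  if (any(tgts %in% c(network@inputs, clamped)) || any(srcs %in% clamped))
    return(notFun)
  rules <- network@rules[tgts]
  for (k in seq_along(srcs))
    if (!srcs[k] %in% ruleVariables(rules[[k]]))
      return(notFun)
  allCtx <- unique(unlist(lapply(seq_along(srcs), function(k)
    setdiff(ruleVariables(rules[[k]]), srcs[k])), use.names = FALSE))
  allCtx <- setdiff(allCtx, clamped)
  extVars <- if (scope == "circuit") setdiff(allCtx, circuit) else allCtx
  chordVars <- if (scope == "circuit") intersect(allCtx, circuit) else character(0)
  m <- length(extVars)
  idx <- if (m > 0L) 0:(2^m - 1L) else 0L
  env <- list()
  for (j in seq_len(m)) env[[extVars[j]]] <- bitwAnd(idx, bitwShiftL(1L, j - 1L)) != 0L
  for (nm in clamped) env[[nm]] <- network@clamps[[nm]]
  alive <- rep(TRUE, length(idx))
  signPos <- rep(FALSE, length(idx)); signNeg <- rep(FALSE, length(idx))
  q <- length(chordVars)
  for (ci in 0:(2^q - 1L)) {
    env2 <- env
    for (j in seq_len(q))
      env2[[chordVars[j]]] <- bitwAnd(ci, bitwShiftL(1L, j - 1L)) != 0L
    prod <- rep(1L, length(idx))
    for (k in seq_along(srcs)) {
      env1 <- env2; env1[[srcs[k]]] <- TRUE
      env0 <- env2; env0[[srcs[k]]] <- FALSE
      d <- as.integer(evaluateRule(rules[[k]], env1)) -
        as.integer(evaluateRule(rules[[k]], env0))
      if (length(d) == 1L) d <- rep(d, length(idx))
      prod <- prod * d
    }
    alive <- alive & prod != 0L
    signPos <- signPos | prod > 0L
    signNeg <- signNeg | prod < 0L
  }
  nSat <- sum(alive)
  if (nSat == 0L) return(notFun)
  # context states counted over full states: free nodes not enumerated here
  # (including, for scope = "circuit", the circuit members) multiply in
  nFreeOutside <- length(nodes) - length(clamped) - m -
    if (scope == "circuit") length(intersect(circuit, setdiff(nodes, clamped))) else 0L
  anyPos <- any(signPos[alive]); anyNeg <- any(signNeg[alive])
  sign <- if (anyPos && anyNeg) "mixed-context" else
    if (anyPos) "positive" else "negative"
  cs <- nSat * 2^nFreeOutside
  if (scope == "circuit") cs <- cs * 2^length(intersect(circuit, setdiff(nodes, clamped)))
  list(functional = TRUE, sign = sign, contextSize = cs)
}

#' Table of circuits and their functionality
#'
#' Enumerates every elementary circuit of the regulatory graph and decides
#' its functionality and sign. Optionally, for a marker node (in the LNCaP
#' model, miR-449a, which gates the functionality of most circuits), the
#' table reports whether each functional circuit's context intersects the
#' marker-ON and marker-OFF halves of the state space.
#'
#' @param network A [BooleanNetwork-class].
#' @param marker Optional node name; adds \code{markerOn}/\code{markerOff}
#'   columns (context intersection flags) to the table.
#' @param scope Functionality notion, see [circuitFunctionality()].
#' @param maxCircuits Circuit-enumeration cap, see [elementaryCircuits()].
#' @return A data.frame with columns \code{circuit} (nodes joined by "/"),
#'   \code{length}, \code{functional}, \code{sign}, \code{contextSize}, the
#'   functional circuits sorted first (by length then name). The node sets
#'   are attached as \code{attr(, "members")}.
#' @examples
#' tab <- functionalCircuits(lncapNetwork(), marker = "miR-449a")
#' subset(tab, functional)
#' @export
functionalCircuits <- function(network, marker = NULL,
                               scope = c("circuit", "state"),
                               maxCircuits = 100000L) {
  stopifnot(is(network, "BooleanNetwork"))
  scope <- match.arg(scope)
  circuits <- elementaryCircuits(network, maxCircuits = maxCircuits)
  res <- lapply(circuits, circuitFunctionality, network = network, scope = scope)
  tab <- data.frame(
    circuit = vapply(circuits, paste, "", collapse = "/"),
    length = lengths(circuits),
    functional = vapply(res, `[[`, TRUE, "functional"),
    sign = vapply(res, `[[`, "", "sign"),
    contextSize = vapply(res, function(r) as.numeric(r$contextSize), 0),
    stringsAsFactors = FALSE)
  if (!is.null(marker)) {
    if (!marker %in% network@nodes) stop("unknown marker node: ", marker)
    mk <- vapply(seq_along(circuits), function(i) {
      if (!tab$functional[i]) return(c(FALSE, FALSE))
      .markerIntersection(network, circuits[[i]], marker, scope)
    }, logical(2))
    tab$markerOn <- mk[1L, ]
    tab$markerOff <- mk[2L, ]
  }
  ord <- order(!tab$functional, tab$length, tab$circuit)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "members") <- circuits[ord]
  tab
}

## Does the functionality context intersect marker=ON / marker=OFF states?
.markerIntersection <- function(network, circuit, marker, scope = "circuit") {
  onNet <- applyPerturbation(network, stats::setNames("ON", marker))
  offNet <- applyPerturbation(network, stats::setNames("OFF", marker))
  c(circuitFunctionality(onNet, circuit, scope = scope)$functional,
    circuitFunctionality(offNet, circuit, scope = scope)$functional)
}
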