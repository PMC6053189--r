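#' BooleanNetwork: a logical regulatory network
#'
#' An ordered set of binary nodes, one logical rule per non-input node,
#' designated input nodes (held at their initial value; the standard input
#' convention in logical modeling, equivalent to a self-activation), optional
#' clamps forcing nodes permanently ON (gain of function, "E1") or OFF (loss
#' of function, "KO"), and designated phenotype-readout (output) nodes.
#'
#' @slot nodes Character vector of unique node identifiers; declaration order
#'   fixes the bit position used in integer state encodings (bit \code{k} of
#'   an encoded state is node \code{k+1}).
#' @slot rules Named list of \code{BoolExpr} rules, one per non-input node.
#' @slot inputs Character vector of input nodes (no rule; value held).
#' @slot outputs Character vector of readout nodes.
#' @slot clamps Named logical vector of clamped nodes (\code{TRUE} = ON).
#' @seealso [booleanNetwork()], [lncapNetwork()], [applyPerturbation()]
#' @export
setClass("BooleanNetwork",
  representation(nodes = "character", rules = "list", inputs = "character",
                 outputs = "character", clamps = "logical"))

setValidity("BooleanNetwork", function(object) {
  msgs <- character(0)
  nd <- object@nodes
  if (anyDuplicated(nd)) msgs <- c(msgs, "duplicated node identifiers")
  if (!all(object@inputs %in% nd)) msgs <- c(msgs, "inputs must be declared nodes")
  if (!all(object@outputs %in% nd)) msgs <- c(msgs, "outputs must be declared nodes")
  ruled <- setdiff(nd, object@inputs)
  if (!setequal(names(object@rules), ruled))
    msgs <- c(msgs, "exactly one rule per non-input node is required")
  for (nm in names(object@rules)) {
    vars <- ruleVariables(object@rules[[nm]])
    bad <- setdiff(vars, nd)
    if (length(bad))
      msgs <- c(msgs, sprintf("rule for '%s' references undeclared node(s): %s",
                              nm, paste(bad, collapse = ", ")))
  }
  if (length(object@clamps)) {
    if (is.null(names(object@clamps)) || !all(names(object@clamps) %in% nd))
      msgs <- c(msgs, "clamps must be named after declared nodes")
    if (anyDuplicated(names(object@clamps))) msgs <- c(msgs, "duplicated clamp")
    if (anyNA(object@clamps)) msgs <- c(msgs, "clamp values must be TRUE/FALSE")
  }
  if (length(msgs)) msgs else TRUE
})

#' AttractorSet: the attractors of a network
#'
#' The terminal strongly connected components of the asynchronous state
#' transition graph: fixed points (singletons) and complex attractors
#' (cyclic terminal components of two or more states, i.e. sustained
#' oscillations). States are stored integer-encoded over the network's node
#' order.
#'
#' @slot states List of sorted integer vectors, one per attractor (encoded
#'   full states).
#' @slot kind Character vector, \code{"fixed_point"} or \code{"complex"}.
#' @slot phenotype Character vector of phenotype labels (see
#'   [classifyAttractor()]).
#' @slot network The \code{BooleanNetwork} the attractors belong to.
#' @seealso [findAttractors()], [stableStates()], [attractorTable()]
#' @export
setClass("AttractorSet",
  representation(states = "list", kind = "character", phenotype = "character",
                 network = "BooleanNetwork"))

setValidity("AttractorSet", function(object) {
  k <- length(object@states)
  if (length(object@kind) != k || length(object@phenotype) != k)
    return("states, kind and phenotype must have equal length")
  sizes <- lengths(object@states)
  if (any(sizes == 0L)) return("attractors must be nonempty")
  if (any((sizes == 1L) != (object@kind == "fixed_point")))
    return("kind must be fixed_point exactly for singleton attractors")
  TRUE
})

#' StateTransitionGraph: explicit dynamics of a network
#'
#' States and allowed transitions under a chosen update scheme. Under the
#' asynchronous scheme every transition changes exactly one node, flipped
#' toward the value of its rule; a state with no outgoing transition is a
#' fixed point.
#'
#' @slot states Integer vector of encoded states (ascending).
#' @slot from,to Integer vectors of encoded states defining the transitions.
#' @slot scheme \code{"asynchronous"} or \code{"synchronous"}.
#' @slot network The underlying \code{BooleanNetwork}.
#' @seealso [buildSTG()]
#' @export
setClass("StateTransitionGraph",
  representation(states = "integer", from = "integer", to = "integer",
                 scheme = "character", network = "BooleanNetwork"))

setValidity("StateTransitionGraph", function(object) {
  if (length(object@from) != length(object@to))
    return("from/to must have equal length")
  if (!object@scheme %in% c("asynchronous", "synchronous"))
    return("scheme must be asynchronous or synchronous")
  TRUE
})

#' PhenotypeEstimate: Monte Carlo phenotype probabilities
#'
#' The result of absorbing asynchronous random walks into attractors and
#' classifying them by the network's output nodes. Counts plus non-converged
#' walks always sum to the number of runs; the estimate is fully reproducible
#' from the stored seed and policy.
#'
#' @slot counts Named integer vector of walks absorbed per phenotype.
#' @slot attractorCounts Integer vector of walks absorbed per attractor.
#' @slot attractors The \code{AttractorSet} used for absorption detection.
#' @slot nRuns Total number of walks.
#' @slot nonConverged Walks that hit the step cap.
#' @slot seed Integer seed the walk substreams were derived from.
#' @slot policy List describing the initial-state policy and step cap.
#' @seealso [estimatePhenotypeProbabilities()], [phenotypeProbabilities()]
#' @export
setClass("PhenotypeEstimate",
  representation(counts = "integer", attractorCounts = "integer",
                 attractors = "AttractorSet", nRuns = "integer",
                 nonConverged = "integer", seed = "integer", policy = "list"))

setValidity("PhenotypeEstimate", function(object) {
  if (sum(object@counts) + object@nonConverged != object@nRuns)
    return("phenotype counts plus non-converged walks must sum to nRuns")
  if (sum(object@attractorCounts) + object@nonConverged != object@nRuns)
    return("attractor counts plus non-converged walks must sum to nRuns")
  TRUE
})
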