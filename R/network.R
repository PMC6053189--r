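#' Construct a boolean regulatory network
#'
#' @param rules Named character vector (or named list of \code{BoolExpr}) with
#'   one entry per node, in declaration order. An entry whose rule is exactly
#'   the node's own name (the \code{.bnet} input convention, "\code{IR, IR}")
#'   is treated as an input unless it is listed in \code{inputs} already.
#' @param inputs Character vector of input node names. Inputs carry no rule
#'   and hold their initial value under every update.
#' @param outputs Character vector of phenotype-readout node names.
#' @param clamps Named logical vector of nodes forced ON/OFF (usually set via
#'   [applyPerturbation()] rather than here).
#' @return A validated [BooleanNetwork-class] object.
#' @examples
#' toggle <- booleanNetwork(c(a = "NOT b", b = "NOT a"))
#' toggle
#' @export
booleanNetwork <- function(rules, inputs = character(0), outputs = character(0),
                           clamps = logical(0)) {
  if (is.null(names(rules)) || any(!nzchar(names(rules))))
    stop("'rules' must be named, one entry per node")
  nodes <- names(rules)
  parsed <- lapply(seq_along(rules), function(i) {
    r <- rules[[i]]
    if (inherits(r, "BoolExpr")) r else parseRule(r)
  })
  names(parsed) <- nodes
  selfRule <- vapply(seq_along(parsed), function(i) {
    e <- parsed[[i]]
    e$kind == "var" && e$name == nodes[i]
  }, logical(1))
  inputs <- union(inputs, nodes[selfRule])
  parsed <- parsed[setdiff(nodes, inputs)]
  new("BooleanNetwork", nodes = nodes, rules = parsed,
      inputs = inputs, outputs = outputs, clamps = clamps)
}

#' @rdname networkAccessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname networkAccessors
#' @export
setGeneric("networkRules", function(x) standardGeneric("networkRules"))
#' @rdname networkAccessors
#' @export
setGeneric("networkInputs", function(x) standardGeneric("networkInputs"))
#' @rdname networkAccessors
#' @export
setGeneric("networkOutputs", function(x) standardGeneric("networkOutputs"))
#' @rdname networkAccessors
#' @export
setGeneric("networkClamps", function(x) standardGeneric("networkClamps"))

#' Accessors for BooleanNetwork objects
#'
#' \code{networkNodes} returns the ordered node identifiers;
#' \code{networkRules} the rules as strings (inputs and clamped nodes
#' included, rendered as self-maintenance and constants respectively);
#' \code{networkInputs}, \code{networkOutputs} and \code{networkClamps} the
#' corresponding slots.
#'
#' @param x A [BooleanNetwork-class].
#' @return See details above.
#' @name networkAccessors
#' @aliases networkNodes,BooleanNetwork-method networkRules,BooleanNetwork-method
#'   networkInputs,BooleanNetwork-method networkOutputs,BooleanNetwork-method
#'   networkClamps,BooleanNetwork-method
NULL

setMethod("networkNodes", "BooleanNetwork", function(x) x@nodes)
setMethod("networkRules", "BooleanNetwork", function(x) {
  vapply(x@nodes, function(nm) {
    if (nm %in% names(x@clamps)) return(if (x@clamps[[nm]]) "1" else "0")
    if (nm %in% x@inputs) return(nm)
    ruleToString(x@rules[[nm]])
  }, "")
})
setMethod("networkInputs", "BooleanNetwork", function(x) x@inputs)
setMethod("networkOutputs", "BooleanNetwork", function(x) x@outputs)
setMethod("networkClamps", "BooleanNetwork", function(x) x@clamps)

setMethod("show", "BooleanNetwork", function(object) {
  cat(sprintf("BooleanNetwork with %d nodes (%d input%s)\n",
              length(object@nodes), length(object@inputs),
              if (length(object@inputs) == 1L) "" else "s"))
  cat("  nodes:  ", paste(object@nodes, collapse = ", "), "\n", sep = "")
  if (length(object@inputs))
    cat("  inputs: ", paste(object@inputs, collapse = ", "), "\n", sep = "")
  if (length(object@outputs))
    cat("  outputs:", paste(object@outputs, collapse = ", "), "\n")
  if (length(object@clamps))
    cat("  clamps: ",
        paste(sprintf("%s=%s", names(object@clamps),
                      ifelse(object@clamps, "ON", "OFF")), collapse = ", "),
        "\n", sep = "")
})

#' Apply gain/loss-of-function perturbations
#'
#' Clamps nodes permanently ON (gain of function, "E1") or OFF (loss of
#' function, "KO"): a clamped node's value never changes under any update and
#' its rule is ignored. The input network is not modified; clamping is
#' idempotent, and re-clamping an already clamped node overrides its value.
#'
#' @param network A [BooleanNetwork-class].
#' @param spec Named vector describing the clamps. Values may be
#'   \code{"ON"}/\code{"OFF"}, \code{TRUE}/\code{FALSE} or \code{1}/\code{0}.
#'   An empty spec returns a dynamically identical network.
#' @return A new \code{BooleanNetwork} with the clamps applied.
#' @examples
#' net <- lncapNetwork()
#' ko <- applyPerturbation(net, c("miR-449a" = "OFF"))
#' networkClamps(ko)
#' @export
applyPerturbation <- function(network, spec) {
  stopifnot(is(network, "BooleanNetwork"))
  if (length(spec) == 0L) return(network)
  if (is.null(names(spec))) stop("perturbation spec must be named by node")
  if (anyDuplicated(names(spec)))
    stop("contradictory clamp: node(s) listed more than once: ",
         paste(unique(names(spec)[duplicated(names(spec))]), collapse = ", "))
  unknown <- setdiff(names(spec), network@nodes)
  if (length(unknown))
    stop("unknown node(s) in perturbation: ", paste(unknown, collapse = ", "))
  val <- if (is.logical(spec)) spec else if (is.numeric(spec)) spec != 0 else {
    up <- toupper(as.character(spec))
    if (!all(up %in% c("ON", "OFF", "E1", "KO", "1", "0", "TRUE", "FALSE")))
      stop("clamp values must be ON/OFF (or E1/KO, TRUE/FALSE, 1/0)")
    up %in% c("ON", "E1", "1", "TRUE")
  }
  names(val) <- names(spec)
  clamps <- network@clamps
  clamps[names(val)] <- val
  initialize(network, clamps = clamps)
}

#' Infer the signed regulatory graph from the rules
#'
#' For every pair (source, target) where the target's rule syntactically
#' mentions the source, the discrete derivative of the rule with respect to
#' the source is evaluated in every assignment of the target's other
#' regulators. An edge is emitted iff the derivative is nonzero in at least
#' one context; its sign is \code{positive} if every nonzero derivative is
#' +1, \code{negative} if every nonzero derivative is -1, and \code{dual}
#' if both occur. Clamped nodes have a constant rule, so they receive no
#' incoming edges and (their value being frozen) contribute no outgoing
#' edges.
#'
#' @param network A [BooleanNetwork-class].
#' @param includeInputLoops If \code{TRUE}, the self-maintenance loop of each
#'   input (its value reproducing itself) is reported as a positive self-edge.
#'   Whether such loops are counted is a convention; both totals are of
#'   interest for the LNCaP model (60 rule dependencies, 61 with the IR
#'   loop).
#' @return A data.frame with columns \code{source}, \code{target},
#'   \code{sign}, ordered by target then source in node order.
#' @examples
#' edges <- inferSignedEdges(lncapNetwork())
#' subset(edges, source == "miR-449a")
#' @export
inferSignedEdges <- function(network, includeInputLoops = FALSE) {
  stopifnot(is(network, "BooleanNetwork"))
  clamped <- names(network@clamps)
  src <- character(0); tgt <- character(0); sgn <- character(0)
  for (nm in setdiff(network@nodes, c(network@inputs, clamped))) {
    rule <- network@rules[[nm]]
    for (u in setdiff(ruleVariables(rule), clamped)) {
      d <- .edgeDerivatives(network, u, nm)
      if (any(d != 0L)) {
        src <- c(src, u); tgt <- c(tgt, nm)
        sgn <- c(sgn, if (all(d >= 0L)) "positive" else if (all(d <= 0L)) "negative" else "dual")
      }
    }
  }
  if (includeInputLoops) {
    ins <- setdiff(network@inputs, clamped)
    src <- c(src, ins); tgt <- c(tgt, ins); sgn <- c(sgn, rep("positive", length(ins)))
  }
  ord <- order(match(tgt, network@nodes), match(src, network@nodes))
  data.frame(source = src[ord], target = tgt[ord], sign = sgn[ord],
             stringsAsFactors = FALSE)
}

## All discrete derivatives of target's rule w.r.t. source, one per
## assignment of the target's other regulators (clamped regulators held at
## their clamp value). Returns an integer vector over contexts.
.edgeDerivatives <- function(network, source, target) {
  rule <- network@rules[[target]]
  others <- setdiff(ruleVariables(rule), source)
  env <- .contextEnv(network, others)
  env1 <- env; env1[[source]] <- TRUE
  env0 <- env; env0[[source]] <- FALSE
  as.integer(evaluateRule(rule, env1)) - as.integer(evaluateRule(rule, env0))
}

## Named list assigning every node in `vars` either its clamp value (scalar)
## or all 2^m combinations of the free ones (vectors of length 2^m).
.contextEnv <- function(network, vars) {
  clamped <- names(network@clamps)
  freeV <- setdiff(vars, clamped)
  m <- length(freeV)
  idx <- if (m > 0L) 0:(2^m - 1L) else 0L
  env <- list()
  for (j in seq_along(freeV))
    env[[freeV[j]]] <- bitwAnd(idx, bitwShiftL(1L, j - 1L)) != 0L
  for (nm in intersect(vars, clamped)) env[[nm]] <- network@clamps[[nm]]
  env
}

#' Discrete derivative of one edge in a given context
#'
#' The value of the target's rule with the source ON minus its value with the
#' source OFF, the target's other regulators being fixed by \code{context}.
#' A nonzero value means the edge is effective (functional) in that context;
#' the sign gives the direction of regulation there.
#'
#' @param network A [BooleanNetwork-class].
#' @param source,target Node names; \code{source} must appear in the rule of
#'   \code{target}.
#' @param context Named logical vector assigning exactly the other regulators
#'   of \code{target} (may be empty when the source is the sole regulator).
#' @return \code{-1L}, \code{0L} or \code{1L}.
#' @examples
#' edgeDerivative(lncapNetwork(), "p53-Arrest", "Wip1", logical(0))
#' @export
edgeDerivative <- function(network, source, target, context = logical(0)) {
  stopifnot(is(network, "BooleanNetwork"))
  if (target %in% network@inputs || target %in% names(network@clamps))
    stop(sprintf("'%s' has no rule (input or clamped node)", target))
  rule <- network@rules[[target]]
  if (!source %in% ruleVariables(rule))
    stop(sprintf("'%s' is not a regulator of '%s'", source, target))
  others <- setdiff(ruleVariables(rule), source)
  if (!setequal(names(context), others))
    stop(sprintf("context must assign exactly the other regulators of '%s': %s",
                 target, paste(others, collapse = ", ")))
  env <- as.list(context)
  env1 <- env; env1[[source]] <- TRUE
  env0 <- env; env0[[source]] <- FALSE
  as.integer(evaluateRule(rule, env1)) - as.integer(evaluateRule(rule, env0))
}
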