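.PHENOTYPES <- c("Proliferation", "G2M_Arrest", "G2M_Apoptosis", "Undefined")

#' Classify an attractor into a phenotype
#'
#' Reads the network's three output nodes over the attractor's states: an
#' output counts as ON if it is ON in any member state (relevant for complex
#' attractors). The label is assigned by precedence apoptosis > arrest >
#' proliferation — in the LNCaP model the apoptotic fixed point also switches
#' the arrest readout on (p21 and 14-3-3s respond to p53-Killer too), and the
#' precedence resolves the double-ON. \code{Undefined} if no output is ON.
#'
#' @param attractors An [AttractorSet-class].
#' @param index Which attractor to classify.
#' @param outputs Output node names in precedence-relevant order
#'   (proliferation, arrest, apoptosis); defaults to the network's declared
#'   outputs.
#' @return One of \code{"Proliferation"}, \code{"G2M_Arrest"},
#'   \code{"G2M_Apoptosis"}, \code{"Undefined"}.
#' @export
classifyAttractor <- function(attractors, index = 1L, outputs = NULL) {
  stopifnot(is(attractors, "AttractorSet"))
  network <- attractors@network
  if (is.null(outputs)) outputs <- network@outputs
  if (length(outputs) != 3L || !all(outputs %in% network@nodes))
    stop("the network must declare its three output nodes (proliferation, arrest, apoptosis)")
  m <- .decodeStates(attractors@states[[index]], network@nodes)
  on <- apply(m[, outputs, drop = FALSE], 2L, any)
  if (on[[3L]]) "G2M_Apoptosis"
  else if (on[[2L]]) "G2M_Arrest"
  else if (on[[1L]]) "Proliferation"
  else "Undefined"
}

## Deterministic per-walk RNG substream seed; keeps results independent of
## the order in which walks are executed. Stays below 2^31.
.walkSeed <- function(seed, walk) {
  as.integer((as.numeric(seed) * 2654435761 + as.numeric(walk) * 97531) %% 2147483647)
}

#' One asynchronous random walk
#'
#' From an initial state, repeatedly picks one of the current asynchronous
#' successors uniformly at random (equivalently: a uniformly chosen unstable
#' node is flipped toward its rule value) until a fixed point is reached, the
#' walk enters a precomputed attractor, or \code{maxSteps} transitions have
#' been taken. Without a precomputed attractor set, revisiting a state
#' triggers a terminal-SCC check of the forward-reachable subgraph so that
#' complex attractors (oscillations) are detected rather than walked
#' forever.
#'
#' @param network A [BooleanNetwork-class].
#' @param initial Initial state (named logical/0-1 vector or encoded
#'   integer).
#' @param seed Integer seed for this walk's random choices.
#' @param maxSteps Step cap; default 1000 times the node count.
#' @param attractors Optional [AttractorSet-class] used for early absorption
#'   detection.
#' @return A list with \code{attractor} (index into \code{attractors}, or an
#'   encoded state set), \code{phenotype}, \code{steps} and \code{converged}.
#' @examples
#' toggle <- booleanNetwork(c(a = "NOT b", b = "NOT a"))
#' randomWalk(toggle, c(a = 1, b = 1), seed = 1)$steps
#' @export
randomWalk <- function(network, initial, seed = 1L,
                       maxSteps = 1000L * length(network@nodes),
                       attractors = NULL) {
  stopifnot(is(network, "BooleanNetwork"), maxSteps >= 1L)
  im <- .imageMap(network)
  enc <- if (is.numeric(initial) && length(initial) == 1L && is.null(names(initial)))
    as.integer(initial) else .encodeState(initial, network@nodes)
  attrId <- if (!is.null(attractors)) .attractorMembership(attractors, im) else NULL
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  out <- .walk(im, .fullToSub(enc, im), maxSteps, attrId)
  list(
    attractor = out$attractor,
    states = if (!is.null(out$states)) sort(.subToFull(out$states, im)) else NULL,
    phenotype = if (!is.null(attractors) && !is.na(out$attractor))
      attractors@phenotype[out$attractor] else NA_character_,
    steps = out$steps, converged = out$converged)
}

## Membership lookup vector: attrId[sub+1] = attractor index, 0 = none.
.attractorMembership <- function(attractors, im) {
  id <- integer(2^im$f)
  for (i in seq_along(attractors@states))
    id[.fullToSub(attractors@states[[i]], im) + 1L] <- i
  id
}

## Core scalar walk in sub coordinates. Returns list(attractor = index or
## NA, states = attractor states if discovered on the fly, steps, converged).
.walk <- function(im, s, maxSteps, attrId = NULL) {
  bits <- im$subBit
  diff <- im$diff
  visited <- NULL
  if (is.null(attrId)) visited <- new.env(hash = TRUE, parent = emptyenv())
  steps <- 0L
  repeat {
    if (!is.null(attrId)) {
      a <- attrId[s + 1L]
      if (a != 0L) return(list(attractor = a, states = NULL, steps = steps, converged = TRUE))
    }
    m <- diff[s + 1L]
    if (m == 0L)   # fixed point
      return(list(attractor = NA_integer_, states = s, steps = steps, converged = TRUE))
    if (!is.null(visited)) {
      key <- as.character(s)
      if (!is.null(visited[[key]])) {
        scc <- .terminalSCCFrom(im, s)
        if (!is.null(scc))
          return(list(attractor = NA_integer_, states = scc, steps = steps, converged = TRUE))
        rm(list = ls(visited), envir = visited)  # transient cycle: reset window
      }
      visited[[key]] <- TRUE
    }
    if (steps >= maxSteps)
      return(list(attractor = NA_integer_, states = NULL, steps = steps, converged = FALSE))
    j <- which(bitwAnd(m, bits) != 0L)
    if (length(j) > 1L) j <- j[sample.int(length(j), 1L)]
    s <- bitwXor(s, bits[j])
    steps <- steps + 1L
  }
}

## If sub-state s lies in a terminal SCC of its forward-reachable subgraph,
## return that SCC's states, else NULL.
.terminalSCCFrom <- function(im, s) {
  reach <- .forwardClosure(s, im)
  idx <- integer(2^im$f); idx[reach + 1L] <- seq_along(reach)
  from <- list(); to <- list()
  d <- im$diff[reach + 1L]
  for (j in seq_len(im$f)) {
    sel <- bitwAnd(d, im$subBit[j]) != 0L
    if (any(sel)) {
      from[[length(from) + 1L]] <- idx[reach[sel] + 1L]
      to[[length(to) + 1L]] <- idx[bitwXor(reach[sel], im$subBit[j]) + 1L]
    }
  }
  from <- unlist(from, use.names = FALSE); to <- unlist(to, use.names = FALSE)
  g <- igraph::make_graph(rbind(from, to), n = length(reach), directed = TRUE)
  comp <- igraph::components(g, mode = "strong")$membership
  mine <- comp[idx[s + 1L]]
  crossing <- any(comp[from] == mine & comp[to] != mine)
  if (crossing) return(NULL)
  reach[comp == mine]
}

#' Monte Carlo estimate of phenotype probabilities
#'
#' Runs independent asynchronous random walks from random initial states and
#' classifies the attractor absorbing each walk, estimating the basin size
#' (probability) of each phenotype. Each walk draws its randomness from a
#' substream derived from \code{(seed, walk index)}, so results are
#' reproducible and independent of execution order. Attractors are
#' precomputed exhaustively when the state space is within \code{guard},
#' which lets walks stop the moment they enter any attractor (including
#' complex ones); walks hitting the step cap are reported as non-converged,
#' never folded into a phenotype.
#'
#' @param network A [BooleanNetwork-class].
#' @param nRuns Number of walks (>= 1).
#' @param seed Integer master seed.
#' @param policy \code{"uniform_all"}: every free node, inputs included,
#'   sampled by a fair coin; \code{"fixed_inputs"}: inputs held at
#'   \code{fixedInputs}, all other free nodes sampled fairly.
#' @param fixedInputs Named vector of input values for
#'   \code{policy = "fixed_inputs"}.
#' @param maxSteps Per-walk step cap; default 1000 times the node count.
#' @param attractors Optional precomputed [AttractorSet-class].
#' @param guard Exhaustive-regime guard for the attractor precomputation.
#' @return A [PhenotypeEstimate-class].
#' @examples
#' est <- estimatePhenotypeProbabilities(
#'   booleanNetwork(c(a = "NOT b", b = "NOT a")), nRuns = 200, seed = 42)
#' @export
estimatePhenotypeProbabilities <- function(network, nRuns = 1000L, seed = 1L,
                                           policy = c("uniform_all", "fixed_inputs"),
                                           fixedInputs = NULL,
                                           maxSteps = 1000L * length(network@nodes),
                                           attractors = NULL, guard = .MAXSTATES) {
  stopifnot(is(network, "BooleanNetwork"), nRuns >= 1L)
  policy <- match.arg(policy)
  im <- .imageMap(network, guard)
  if (is.null(attractors))
    attractors <- findAttractors(network, guard = guard)
  attrId <- .attractorMembership(attractors, im)
  # initial-state mask for fixed inputs (sub coordinates)
  fixMask <- 0L; fixVal <- 0L
  if (policy == "fixed_inputs") {
    if (is.null(fixedInputs) || is.null(names(fixedInputs)))
      stop("policy 'fixed_inputs' needs a named 'fixedInputs' vector")
    bad <- setdiff(names(fixedInputs), setdiff(network@inputs, names(network@clamps)))
    if (length(bad))
      stop("fixedInputs must name unclamped input nodes; offending: ",
           paste(bad, collapse = ", "))
    for (nm in names(fixedInputs)) {
      j <- match(nm, im$free)
      fixMask <- bitwOr(fixMask, im$subBit[j])
      if (as.logical(fixedInputs[[nm]])) fixVal <- bitwOr(fixVal, im$subBit[j])
    }
  }
  N <- 2^im$f
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  phenoCounts <- setNames(integer(length(.PHENOTYPES)), .PHENOTYPES)
  attrCounts <- integer(length(attractors))
  nonConverged <- 0L
  for (w in seq_len(nRuns)) {
    set.seed(.walkSeed(seed, w))
    s <- floor(stats::runif(1) * N)
    s <- bitwOr(bitwAnd(as.integer(s), bitwNot(fixMask)), fixVal)
    res <- .walk(im, s, maxSteps, attrId)
    if (!res$converged) { nonConverged <- nonConverged + 1L; next }
    a <- res$attractor
    if (is.na(a)) {  # fixed point (or on-the-fly SCC) not in the precomputed set
      full <- sort(.subToFull(res$states, im))
      a <- which(vapply(attractors@states, identical, TRUE, y = full))
      if (length(a) != 1L) stop("walk absorbed by an attractor missing from the precomputed set")
    }
    attrCounts[a] <- attrCounts[a] + 1L
    ph <- attractors@phenotype[a]
    phenoCounts[ph] <- phenoCounts[ph] + 1L
  }
  new("PhenotypeEstimate", counts = phenoCounts, attractorCounts = attrCounts,
      attractors = attractors, nRuns = as.integer(nRuns),
      nonConverged = nonConverged, seed = as.integer(seed),
      policy = list(policy = policy,
                    fixedInputs = fixedInputs,
                    clamps = network@clamps,
                    maxSteps = as.integer(maxSteps)))
}

#' Phenotype proportions of an estimate
#'
#' @param estimate A [PhenotypeEstimate-class].
#' @return Named numeric vector of proportions (relative to the total number
#'   of walks; non-converged walks make the proportions sum to less than 1).
#' @export
phenotypeProbabilities <- function(estimate) {
  stopifnot(is(estimate, "PhenotypeEstimate"))
  estimate@counts / estimate@nRuns
}

#' Per-attractor absorption proportions of an estimate
#'
#' @param estimate A [PhenotypeEstimate-class].
#' @return Numeric vector, one entry per attractor of the estimate's
#'   attractor set.
#' @export
attractorProbabilities <- function(estimate) {
  stopifnot(is(estimate, "PhenotypeEstimate"))
  estimate@attractorCounts / estimate@nRuns
}

setMethod("show", "PhenotypeEstimate", function(object) {
  cat(sprintf("PhenotypeEstimate: %d walks (seed %d, policy %s), %d non-converged\n",
              object@nRuns, object@seed, object@policy$policy, object@nonConverged))
  p <- phenotypeProbabilities(object)
  for (nm in names(p))
    if (p[[nm]] > 0 || nm != "Undefined")
      cat(sprintf("  %-14s %6.1f%%  (%d walks)\n", nm, 100 * p[[nm]], object@counts[[nm]]))
})
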