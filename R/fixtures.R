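#' Generate a random boolean network
#'
#' Random networks emulating the structural makeup of small signed logical
#' models (bounded in-degree, AND/OR combinations of possibly negated
#' regulators, a few designated inputs and outputs) so that every engine
#' component can be exercised on networks whose ground truth is computable
#' by brute force. Identical arguments (including \code{seed}) always yield
#' the identical network.
#'
#' @param nNodes Number of nodes.
#' @param maxInDegree Maximum regulators per rule (1..nNodes).
#' @param pNegative Probability that a regulator enters its rule negated;
#'   with \code{pNegative = 0} every inferred edge is positive.
#' @param nInputs Number of input nodes (must leave at least one ruled
#'   node).
#' @param seed Integer seed.
#' @return A [BooleanNetwork-class] with nodes \code{n01}, \code{n02}, ...;
#'   the first \code{nInputs} nodes are the inputs.
#' @examples
#' randomNetwork(6, maxInDegree = 3, seed = 7)
#' @export
randomNetwork <- function(nNodes, maxInDegree = 3L, pNegative = 0.3,
                          nInputs = 1L, seed = 1L) {
  if (nNodes < 1L || maxInDegree < 1L || maxInDegree > nNodes)
    stop("need 1 <= maxInDegree <= nNodes")
  if (nInputs >= nNodes)
    stop("nInputs must leave at least one non-input node")
  if (pNegative < 0 || pNegative > 1) stop("pNegative must be in [0, 1]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  nodes <- sprintf("n%02d", seq_len(nNodes))
  inputs <- nodes[seq_len(nInputs)]
  rules <- stats::setNames(as.list(nodes), nodes)  # inputs: self-maintenance
  for (nm in setdiff(nodes, inputs)) {
    k <- sample.int(maxInDegree, 1L)
    # a bare self-rule would read as the .bnet input convention; keep plain
    # self-regulation for k >= 2 only
    regs <- if (k == 1L) sample(setdiff(nodes, nm), 1L) else sample(nodes, k)
    lits <- ifelse(stats::runif(k) < pNegative, paste0("NOT ", regs), regs)
    expr <- lits[1L]
    for (j in seq_len(k - 1L)) {
      op <- if (stats::runif(1) < 0.5) "AND" else "OR"
      expr <- sprintf("(%s) %s %s", expr, op, lits[j + 1L])
    }
    rules[[nm]] <- expr
  }
  booleanNetwork(unlist(rules), inputs = inputs)
}

#' Exact absorption probabilities of the asynchronous dynamics
#'
#' Treats the asynchronous state transition graph as a discrete Markov chain
#' with uniform transition probability over each state's successors (the
#' same kernel as the random-walk estimator), collapses the attractor states
#' into absorbing classes and solves the linear system for the absorption
#' probabilities, averaged over the initial distribution. This is the exact
#' counterpart of [estimatePhenotypeProbabilities()] and serves as its
#' oracle at fixture scale.
#'
#' @param network A [BooleanNetwork-class].
#' @param initial \code{"uniform"} (uniform over all clamp-consistent
#'   states) or a numeric vector of initial probabilities over the
#'   sub-state space (length \code{2^f}, summing to 1).
#' @param guard Exhaustive guard; the solver is meant for fixture-scale
#'   spaces (default up to 2^16 states).
#' @return A list with \code{attractors} (an [AttractorSet-class]),
#'   \code{probabilities} (per-attractor absorption probability), and
#'   \code{phenotypeProbabilities} (the same mass accumulated by phenotype
#'   label).
#' @examples
#' toggle <- booleanNetwork(c(a = "NOT b", b = "NOT a"))
#' exactAbsorptionProbabilities(toggle)$probabilities
#' @export
exactAbsorptionProbabilities <- function(network, initial = "uniform",
                                         guard = 2^16) {
  stopifnot(is(network, "BooleanNetwork"))
  im <- .imageMap(network, guard)
  N <- 2^im$f
  att <- findAttractors(network, guard = guard)
  nA <- length(att)
  attrId <- .attractorMembership(att, im)
  p0 <- if (identical(initial, "uniform")) rep(1 / N, N) else {
    if (length(initial) != N) stop("initial distribution must have length 2^f = ", N)
    if (abs(sum(initial) - 1) > 1e-9) stop("initial distribution must sum to 1")
    initial
  }
  transient <- which(attrId == 0L)  # 1-based sub-state indices
  probs <- numeric(nA)
  # mass starting inside each absorbing class stays there
  for (a in seq_len(nA)) probs[a] <- sum(p0[attrId == a])
  if (length(transient)) {
    nT <- length(transient)
    B <- if (nT < 4096) .absorbDense(im, attrId, transient, nA) else
      .absorbSweeps(im, attrId, transient, nA)
    if (max(abs(rowSums(B) - 1)) > 1e-9)
      stop("absorption solve failed to conserve probability")
    probs <- probs + as.numeric(crossprod(B, p0[transient]))
  }
  php <- stats::setNames(numeric(length(.PHENOTYPES)), .PHENOTYPES)
  for (a in seq_len(nA)) php[[att@phenotype[a]]] <- php[[att@phenotype[a]]] + probs[a]
  list(attractors = att, probabilities = probs, phenotypeProbabilities = php)
}

## Direct dense solve of (I - Q) B = R for the transient block; exact up to
## LAPACK accuracy. Rows of B: transient states; columns: absorbing classes.
.absorbDense <- function(im, attrId, transient, nA) {
  nT <- length(transient)
  tIdx <- integer(2^im$f); tIdx[transient] <- seq_len(nT)
  ed <- .subEdges(im)
  keep <- attrId[ed$from + 1L] == 0L
  from <- ed$from[keep]; to <- ed$to[keep]
  outdeg <- tabulate(tIdx[from + 1L], nbins = nT)
  w <- 1 / outdeg[tIdx[from + 1L]]
  toT <- attrId[to + 1L] == 0L
  A <- diag(nT)
  ii <- tIdx[from[toT] + 1L]; jj <- tIdx[to[toT] + 1L]
  A[cbind(ii, jj)] <- A[cbind(ii, jj)] - w[toT]
  R <- matrix(0, nT, nA)
  ii <- tIdx[from[!toT] + 1L]; jj <- attrId[to[!toT] + 1L]
  for (k in seq_along(ii)) R[ii[k], jj[k]] <- R[ii[k], jj[k]] + w[!toT][k]
  solve(A, R)
}

## Sparse value-iteration solve of the same system: B <- Q B + R via
## bit-sweeps over the hypercube-structured STG (a direct sparse
## factorization fills in catastrophically on this graph family).
.absorbSweeps <- function(im, attrId, transient, nA, tol = 1e-12,
                          maxSweeps = 50000L) {
  N <- 2^im$f
  idx <- 0:(N - 1L)
  outdeg <- integer(N)
  for (j in seq_len(im$f))
    outdeg <- outdeg + (bitwAnd(im$diff, im$subBit[j]) != 0L)
  B <- matrix(0, N, nA)   # over all states; absorbing rows are indicators
  for (a in seq_len(nA)) B[attrId == a, a] <- 1
  frozen <- attrId != 0L
  has <- lapply(seq_len(im$f), function(j)
    which(bitwAnd(im$diff, im$subBit[j]) != 0L))
  nb <- lapply(seq_len(im$f), function(j)
    bitwXor(idx[has[[j]]], im$subBit[j]) + 1L)
  for (it in seq_len(maxSweeps)) {
    delta <- 0
    for (a in seq_len(nA)) {
      acc <- numeric(N)
      for (j in seq_len(im$f))
        acc[has[[j]]] <- acc[has[[j]]] + B[nb[[j]], a]
      newB <- ifelse(frozen, B[, a], acc / pmax(outdeg, 1L))
      delta <- max(delta, max(abs(newB - B[, a])))
      B[, a] <- newB
    }
    if (delta < tol) break
  }
  if (delta >= tol) stop("absorption sweeps did not converge")
  B[transient, , drop = FALSE]
}

#' Catalog of hand-verified fixture networks
#'
#' Small networks whose dynamics is known exactly: the bistable toggle
#' switch (two fixed points), the three-node negative loop (no fixed point,
#' one complex attractor covering all 8 states), a constant network (a
#' single all-zero fixed point), and the LNCaP checkpoint model itself.
#'
#' @return A named list; each entry has \code{network} plus the expected
#'   \code{nFixedPoints} and \code{nComplex} counts.
#' @examples
#' names(knownFixtures())
#' @export
knownFixtures <- function() {
  list(
    toggle_switch = list(
      network = booleanNetwork(c(a = "NOT b", b = "NOT a")),
      nFixedPoints = 2L, nComplex = 0L),
    negative_loop_3 = list(
      network = booleanNetwork(c(a = "NOT c", b = "a", c = "b")),
      nFixedPoints = 0L, nComplex = 1L),
    constant = list(
      network = booleanNetwork(c(a = "0", b = "0", c = "0")),
      nFixedPoints = 1L, nComplex = 0L),
    lncap = list(
      network = lncapNetwork(),
      nFixedPoints = 3L, nComplex = 0L))
}
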