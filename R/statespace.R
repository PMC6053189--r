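## Internal integer-encoded state-space engine.
##
## A full state is an integer whose bit k (0-based) carries the value of
## node k+1 in declaration order. Under clamps, the dynamics lives in the
## sub-space of clamp-consistent states; sub-states are integers over the
## free (unclamped) nodes only, bit j of a sub-state being free node j+1.
## Inputs are free nodes whose update reproduces their own value, so they
## never appear among the unstable nodes and each input combination yields a
## disconnected slice of the dynamics.

.MAXSTATES <- 2^24  # default exhaustive-regime guard

.stateSpace <- function(network) {
  nodes <- network@nodes
  n <- length(nodes)
  clamped <- names(network@clamps)
  free <- setdiff(nodes, clamped)
  f <- length(free)
  freePos <- match(free, nodes) - 1L          # 0-based bit positions, full coords
  clampBits <- 0L
  for (nm in clamped) if (network@clamps[[nm]])
    clampBits <- bitwOr(clampBits, bitwShiftL(1L, match(nm, nodes) - 1L))
  list(nodes = nodes, n = n, free = free, f = f, freePos = freePos,
       clampBits = clampBits,
       subBit = bitwShiftL(1L, seq_len(f) - 1L),
       fullBit = bitwShiftL(1L, freePos))
}

.guardCheck <- function(f, guard) {
  if (2^f > guard)
    stop(sprintf(paste0("state space of 2^%d states exceeds the exhaustive-",
                        "regime guard (%g states); raise 'guard' or use the ",
                        "sampling path (random walks)"), f, guard),
         call. = FALSE)
}

## Sub-state -> full-state encoding (vectorized).
.subToFull <- function(sub, ss) {
  full <- rep.int(ss$clampBits, length(sub))
  for (j in seq_len(ss$f))
    full <- full + bitwAnd(bitwShiftR(sub, j - 1L), 1L) * ss$fullBit[j]
  full
}

## Full-state -> sub-state encoding (vectorized); assumes clamp-consistency.
.fullToSub <- function(full, ss) {
  sub <- integer(length(full))
  for (j in seq_len(ss$f))
    sub <- sub + bitwAnd(bitwShiftR(full, ss$freePos[j]), 1L) * ss$subBit[j]
  sub
}

## Transition image of the whole (clamp-consistent) sub-space.
## Returns ss plus:
##   diff : integer vector of length 2^f; diff[s+1] has bit j set iff free
##          node j+1 is unstable in sub-state s (rule value != current value).
## Clamped nodes and inputs are never unstable by construction.
.imageMap <- function(network, guard = .MAXSTATES) {
  ss <- .stateSpace(network)
  .guardCheck(ss$f, guard)
  N <- 2^ss$f
  idx <- if (N > 1) 0:(N - 1L) else 0L
  vals <- vector("list", ss$n)
  names(vals) <- ss$nodes
  for (j in seq_len(ss$f))
    vals[[ss$free[j]]] <- bitwAnd(idx, ss$subBit[j]) != 0L
  for (nm in names(network@clamps)) vals[[nm]] <- network@clamps[[nm]]
  diff <- integer(N)
  for (j in seq_len(ss$f)) {
    nm <- ss$free[j]
    K <- if (nm %in% network@inputs) vals[[nm]] else
      evaluateRule(network@rules[[nm]], vals)
    unstable <- xor(K, vals[[nm]])
    diff[unstable] <- diff[unstable] + ss$subBit[j]
  }
  ss$diff <- diff
  ss
}

## Asynchronous edges of the sub-space STG (sub coordinates).
.subEdges <- function(im) {
  from <- list(); to <- list()
  for (j in seq_len(im$f)) {
    u <- which(bitwAnd(im$diff, im$subBit[j]) != 0L) - 1L
    if (length(u)) {
      from[[length(from) + 1L]] <- u
      to[[length(to) + 1L]] <- bitwXor(u, im$subBit[j])
    }
  }
  list(from = unlist(from, use.names = FALSE), to = unlist(to, use.names = FALSE))
}

## Decode encoded full states into a logical matrix (rows = states).
.decodeStates <- function(states, nodes) {
  n <- length(nodes)
  m <- matrix(FALSE, nrow = length(states), ncol = n,
              dimnames = list(NULL, nodes))
  for (k in seq_len(n))
    m[, k] <- bitwAnd(states, bitwShiftL(1L, k - 1L)) != 0L
  m
}

## Encode a state given as logical/0-1 vector (named or in node order).
.encodeState <- function(state, nodes) {
  if (!is.null(names(state))) {
    missing <- setdiff(nodes, names(state))
    if (length(missing))
      stop("state misses node(s): ", paste(missing, collapse = ", "))
    state <- state[nodes]
  } else if (length(state) != length(nodes))
    stop("state length must equal the number of nodes")
  v <- as.logical(state)
  if (anyNA(v)) stop("state values must be strictly binary")
  sum(bitwShiftL(1L, which(v) - 1L))
}
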