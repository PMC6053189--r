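# Independent brute-force oracles. These deliberately use only the public
# scalar API (asynchronousSuccessors, evaluateRule) and plain R set
# operations, so that agreement with the vectorized bit-level engine is a
# genuine cross-check.

toyToggle <- function() booleanNetwork(c(a = "NOT b", b = "NOT a"))
toyNegLoop <- function() booleanNetwork(c(a = "NOT c", b = "a", c = "b"))

# all states of a small network as a list of named logical vectors
allStates <- function(net) {
  nodes <- networkNodes(net)
  n <- length(nodes)
  lapply(0:(2^n - 1), function(s)
    setNames(bitwAnd(s, bitwShiftL(1L, seq_len(n) - 1L)) != 0L, nodes))
}

encodeOracle <- function(state) sum(bitwShiftL(1L, which(unname(state)) - 1L))

# successor encodings of one state, via the public API
succOracle <- function(net, state) {
  m <- asynchronousSuccessors(net, state)
  if (nrow(m) == 0L) return(integer(0))
  apply(m, 1L, function(r) encodeOracle(r))
}

# attractors by mutual-reachability over explicit closures: a state belongs
# to an attractor iff every state reachable from it can reach it back
bruteForceAttractors <- function(net) {
  sts <- allStates(net)
  enc <- vapply(sts, encodeOracle, 0)
  succ <- lapply(sts, function(s) succOracle(net, s))
  names(succ) <- as.character(enc)
  closure <- function(e) {
    seen <- e
    frontier <- e
    while (length(frontier)) {
      nxt <- unique(unlist(succ[as.character(frontier)], use.names = FALSE))
      frontier <- setdiff(nxt, seen)
      seen <- c(seen, frontier)
    }
    sort(seen)
  }
  clos <- lapply(enc, closure)
  names(clos) <- as.character(enc)
  inAtt <- vapply(seq_along(enc), function(i)
    all(vapply(clos[[i]], function(t) enc[i] %in% clos[[as.character(t)]], TRUE)),
    TRUE)
  atts <- unique(lapply(which(inAtt), function(i) clos[[i]]))
  atts[order(vapply(atts, min, 0))]
}

# truth table of a rule over given variables (exhaustive)
truthTable <- function(expr, vars) {
  n <- length(vars)
  vapply(0:(2^n - 1), function(s) {
    vals <- setNames(as.list(bitwAnd(s, bitwShiftL(1L, seq_len(n) - 1L)) != 0L), vars)
    evaluateRule(expr, vals)
  }, TRUE)
}

# per-state circuit functionality context, counted by scanning all full
# states and evaluating every edge's local derivative there
bruteForceStateContext <- function(net, circuit) {
  nodes <- networkNodes(net)
  srcs <- circuit; tgts <- c(circuit[-1], circuit[1])
  rules <- networkRules(net)
  count <- 0L
  signs <- integer(0)
  for (st in allStates(net)) {
    ok <- TRUE; pr <- 1L
    for (k in seq_along(srcs)) {
      e <- parseRule(rules[[tgts[k]]])
      v1 <- as.list(st); v1[[srcs[k]]] <- TRUE
      v0 <- as.list(st); v0[[srcs[k]]] <- FALSE
      d <- as.integer(evaluateRule(e, v1)) - as.integer(evaluateRule(e, v0))
      if (d == 0L) { ok <- FALSE; break }
      pr <- pr * d
    }
    if (ok) { count <- count + 1L; signs <- union(signs, pr) }
  }
  list(contextSize = count, signs = signs)
}

# circuit-scope functionality by scanning assignments of the complement and
# requiring functionality for every assignment of the circuit members
bruteForceCircuitContext <- function(net, circuit) {
  nodes <- networkNodes(net)
  outside <- setdiff(nodes, circuit)
  rules <- networkRules(net)
  srcs <- circuit; tgts <- c(circuit[-1], circuit[1])
  nO <- length(outside); nC <- length(circuit)
  count <- 0L
  for (so in 0:(2^nO - 1)) {
    ext <- setNames(as.list(bitwAnd(so, bitwShiftL(1L, seq_len(nO) - 1L)) != 0L), outside)
    okAll <- TRUE
    for (sc in 0:(2^nC - 1)) {
      cin <- setNames(as.list(bitwAnd(sc, bitwShiftL(1L, seq_len(nC) - 1L)) != 0L), circuit)
      vals <- c(ext, cin)
      for (k in seq_along(srcs)) {
        e <- parseRule(rules[[tgts[k]]])
        v1 <- vals; v1[[srcs[k]]] <- TRUE
        v0 <- vals; v0[[srcs[k]]] <- FALSE
        if (evaluateRule(e, v1) == evaluateRule(e, v0)) { okAll <- FALSE; break }
      }
      if (!okAll) break
    }
    if (okAll) count <- count + 1L
  }
  count * 2^nC
}
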