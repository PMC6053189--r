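test_that("asynchronous successors flip exactly one unstable node toward its rule value", {
  toggle <- toyToggle()
  succ <- asynchronousSuccessors(toggle, c(a = 1, b = 1))
  expect_equal(nrow(succ), 2L)
  expect_setequal(apply(succ, 1, paste, collapse = ""),
                  c("FALSETRUE", "TRUEFALSE"))
  # a fixed point has no successors
  expect_equal(nrow(asynchronousSuccessors(toggle, c(a = 1, b = 0))), 0L)

  # single-flip contract on sampled LNCaP states
  net <- lncapNetwork()
  set.seed(99)
  for (i in 1:25) {
    st <- setNames(stats::runif(21) < 0.5, networkNodes(net))
    succ <- asynchronousSuccessors(net, st)
    if (nrow(succ))
      expect_true(all(rowSums(succ != matrix(st, nrow(succ), 21, byrow = TRUE)) == 1L))
    # and each flipped node moves toward its synchronous image
    img <- synchronousSuccessor(net, st)
    for (r in seq_len(nrow(succ))) {
      k <- which(succ[r, ] != st)
      expect_identical(unname(succ[r, k]), unname(img[k]))
    }
  }
})

test_that("synchronous update is simultaneous and deterministic", {
  toggle <- toyToggle()
  expect_identical(synchronousSuccessor(toggle, c(a = 1, b = 1)), c(a = FALSE, b = FALSE))
  expect_identical(synchronousSuccessor(toggle, c(a = 1, b = 0)), c(a = TRUE, b = FALSE))
  # fixed point maps to itself
  expect_identical(synchronousSuccessor(toggle, c(a = 0, b = 1)), c(a = FALSE, b = TRUE))
})

test_that("stable-state enumeration is exhaustive, ordered and clamp-aware", {
  # constant network: the all-zero state only
  const0 <- booleanNetwork(c(a = "0", b = "0", c = "0"))
  ss <- stableStates(const0)
  expect_equal(nrow(ss), 1L)
  expect_false(any(ss))

  expect_equal(nrow(stableStates(toyToggle())), 2L)
  expect_equal(nrow(stableStates(toyNegLoop())), 0L)

  # deterministic ascending encoding order
  ss1 <- stableStates(lncapNetwork())
  ss2 <- stableStates(lncapNetwork())
  expect_identical(attr(ss1, "encoded"), attr(ss2, "encoded"))
  expect_identical(attr(ss1, "encoded"), sort(attr(ss1, "encoded")))

  # the guard directs oversized requests to the sampling path
  big <- randomNetwork(12, seed = 1)
  expect_error(stableStates(big, guard = 2^10), "guard")
})

test_that("every enumerated stable state satisfies its own rules", {
  net <- lncapNetwork()
  ss <- stableStates(net)
  expect_equal(nrow(ss), 3L)
  rules <- networkRules(net)
  for (r in seq_len(nrow(ss))) {
    vals <- as.list(ss[r, ])
    for (nm in setdiff(networkNodes(net), networkInputs(net)))
      expect_identical(evaluateRule(parseRule(rules[[nm]]), vals), unname(ss[r, nm]),
                       info = paste("row", r, nm))
  }
  # the IR=0 stable state is the proliferative one
  prolif <- ss[!ss[, "IR"], , drop = FALSE]
  expect_equal(nrow(prolif), 1L)
  on <- colnames(prolif)[prolif[1, ]]
  expect_setequal(on, c("E2F1", "c-Myc", "Cdc25ABC", "Cdc2-CycB", "Sirt-1",
                        "Mdm2", "Proliferation"))
})

test_that("attractors are the terminal SCCs: fixed points and oscillations", {
  # three-node negative loop: no fixed point, one complex attractor
  att <- findAttractors(toyNegLoop())
  expect_length(att, 1L)
  expect_identical(att@kind, "complex")
  # the classic six-state oscillation; the two homogeneous states are transient
  expect_length(att@states[[1]], 6L)

  att <- findAttractors(toyToggle())
  expect_length(att, 2L)
  expect_identical(att@kind, c("fixed_point", "fixed_point"))

  # attractor states are closed under the asynchronous successors
  for (net in list(toyToggle(), toyNegLoop(), randomNetwork(7, seed = 3))) {
    att <- findAttractors(net)
    pool <- sort(unlist(att@states))
    for (s in pool)
      expect_true(all(succOracle(net, s) %in% pool))
  }
})

test_that("SCC attractor detection agrees with the mutual-reachability oracle", {
  for (seed in 1:12) {
    net <- randomNetwork(7, maxInDegree = 3, pNegative = 0.4, seed = seed)
    got <- lapply(findAttractors(net)@states, as.numeric)
    want <- bruteForceAttractors(net)
    expect_equal(got[order(vapply(got, min, 0))], want, info = paste("seed", seed))
  }
})

test_that("closure-based and SCC-based attractor routes return identical results", {
  for (seed in c(2, 5, 9)) {
    net <- randomNetwork(9, maxInDegree = 3, pNegative = 0.4, seed = seed)
    im <- g2mLogic:::.imageMap(net)
    a <- g2mLogic:::.attractorsBySCC(im)
    b <- g2mLogic:::.attractorsByClosure(im)
    norm <- function(x) lapply(x, sort)[order(vapply(x, min, 0))]
    expect_identical(norm(a), norm(b))
  }
})

test_that("state transition graphs respect the update scheme", {
  stg <- buildSTG(toyNegLoop())
  expect_length(stg@states, 8L)
  # every asynchronous transition changes exactly one node
  nbits <- vapply(bitwXor(stg@from, stg@to), function(x)
    sum(bitwAnd(x, bitwShiftL(1L, 0:7)) != 0L), 0L)
  expect_true(all(nbits == 1L))
  # seeding from a fixed point yields that state alone
  stgFP <- buildSTG(toyToggle(), seeds = c(a = TRUE, b = FALSE))
  expect_length(stgFP@states, 1L)
  expect_length(stgFP@from, 0L)
  # terminal SCCs of a seeded STG match the attractors of the restriction
  net <- randomNetwork(8, nInputs = 1, seed = 4)
  seeds <- which(bitwAnd(0:255, 1L) == 1L) - 1L   # all states with the input ON
  stg1 <- buildSTG(net, seeds = seeds)
  att1 <- findAttractors(net, restriction = c(n01 = 1))
  pool <- sort(unlist(att1@states))
  g <- igraph::make_graph(rbind(match(stg1@from, stg1@states),
                                match(stg1@to, stg1@states)),
                          n = length(stg1@states), directed = TRUE)
  comp <- igraph::components(g, mode = "strong")$membership
  crossing <- comp[match(stg1@from, stg1@states)] != comp[match(stg1@to, stg1@states)]
  nonTerm <- unique(comp[match(stg1@from, stg1@states)][crossing])
  term <- setdiff(unique(comp), nonTerm)
  got <- sort(unlist(lapply(term, function(cc) stg1@states[comp == cc])))
  expect_identical(got, pool)
})
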