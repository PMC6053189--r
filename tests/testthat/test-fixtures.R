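test_that("random networks are reproducible and respect their spec", {
  n1 <- randomNetwork(8, maxInDegree = 3, pNegative = 0.3, seed = 7)
  n2 <- randomNetwork(8, maxInDegree = 3, pNegative = 0.3, seed = 7)
  expect_identical(networkRules(n1), networkRules(n2))
  expect_false(identical(networkRules(n1),
                         networkRules(randomNetwork(8, maxInDegree = 3,
                                                    pNegative = 0.3, seed = 8))))
  expect_identical(networkInputs(n1), "n01")
  # in-degree bound and declared-node closure
  for (r in networkRules(n1))
    expect_lte(length(ruleVariables(parseRule(r))), 3L)
  # with pNegative = 0 every inferred edge is positive
  pos <- randomNetwork(8, maxInDegree = 3, pNegative = 0, seed = 5)
  expect_true(all(inferSignedEdges(pos)$sign == "positive"))
  # full state space of a 6-node fixture
  expect_length(buildSTG(randomNetwork(6, seed = 2))@states, 64L)
  # infeasible specs
  expect_error(randomNetwork(4, nInputs = 4), "non-input")
  expect_error(randomNetwork(4, maxInDegree = 9), "maxInDegree")
})

test_that("exact absorption probabilities solve known chains", {
  ex <- exactAbsorptionProbabilities(toyToggle())
  expect_equal(ex$probabilities, c(0.5, 0.5), tolerance = 1e-12)
  # single-attractor network absorbs with probability one
  ex1 <- exactAbsorptionProbabilities(toyNegLoop())
  expect_equal(ex1$probabilities, 1, tolerance = 1e-12)
  # a point-mass initial distribution inside an attractor
  p0 <- numeric(4); p0[1] <- 1   # state a=0,b=0 of the toggle is transient
  exT <- exactAbsorptionProbabilities(toyToggle(), initial = p0)
  expect_equal(exT$probabilities, c(0.5, 0.5), tolerance = 1e-12)
  expect_error(exactAbsorptionProbabilities(toyToggle(), initial = c(1, 1, 1, 1)),
               "sum to 1")
})

test_that("absorption probabilities sum to one on every fixture", {
  for (seed in 1:20) {
    net <- randomNetwork(8, maxInDegree = 3, pNegative = 0.4, seed = seed)
    ex <- exactAbsorptionProbabilities(net)
    expect_lt(abs(sum(ex$probabilities) - 1), 1e-9)
  }
})

test_that("dense and sweep-based absorption solvers agree", {
  net <- randomNetwork(9, maxInDegree = 3, pNegative = 0.4, seed = 21)
  im <- g2mLogic:::.imageMap(net)
  att <- findAttractors(net)
  attrId <- g2mLogic:::.attractorMembership(att, im)
  transient <- which(attrId == 0L)
  if (length(transient) > 1L && length(att) > 1L) {
    Bd <- g2mLogic:::.absorbDense(im, attrId, transient, length(att))
    Bs <- g2mLogic:::.absorbSweeps(im, attrId, transient, length(att))
    expect_equal(Bd, Bs, tolerance = 1e-8)
  } else skip("degenerate fixture")
})

test_that("the fixture catalog carries its hand-verified ground truth", {
  cat <- knownFixtures()
  expect_setequal(names(cat),
                  c("toggle_switch", "negative_loop_3", "constant", "lncap"))
  for (nm in names(cat)) {
    att <- findAttractors(cat[[nm]]$network)
    expect_equal(sum(att@kind == "fixed_point"), cat[[nm]]$nFixedPoints, info = nm)
    expect_equal(sum(att@kind == "complex"), cat[[nm]]$nComplex, info = nm)
  }
  expect_length(networkNodes(cat$lncap$network), 21L)
})
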