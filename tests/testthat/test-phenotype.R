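test_that("attractor classification reads outputs with apoptosis > arrest > proliferation", {
  net <- lncapNetwork()
  att <- findAttractors(net)
  expect_setequal(att@phenotype, c("Proliferation", "G2M_Arrest", "G2M_Apoptosis"))
  # the killer fixed point also has the arrest readout ON (p21 and 14-3-3s
  # respond to p53-Killer); precedence must resolve the double-ON
  kIdx <- which(att@phenotype == "G2M_Apoptosis")
  kState <- g2mLogic:::.decodeStates(att@states[[kIdx]], networkNodes(net))
  expect_true(kState[, "G2/M-Arrest"])
  expect_true(kState[, "G2/M-Apoptosis"])
  # IR=0 fixed point is proliferative; all-off outputs are Undefined
  pIdx <- which(att@phenotype == "Proliferation")
  expect_false(g2mLogic:::.decodeStates(att@states[[pIdx]], networkNodes(net))[, "IR"])
  noOut <- findAttractors(toyToggle())
  expect_identical(unique(noOut@phenotype), "Undefined")
})

test_that("random walks stop at fixed points and detect oscillations on revisit", {
  toggle <- toyToggle()
  # starting at a fixed point: zero steps
  w <- randomWalk(toggle, c(a = 1, b = 0), seed = 1)
  expect_equal(w$steps, 0L)
  expect_true(w$converged)
  expect_identical(w$states, g2mLogic:::.encodeState(c(a = TRUE, b = FALSE), c("a", "b")))
  # complex attractor discovered without a precomputed attractor set
  w <- randomWalk(toyNegLoop(), c(a = 1, b = 0, c = 0), seed = 5)
  expect_true(w$converged)
  expect_length(w$states, 6L)
})

test_that("the toggle switch absorbs each fixed point half the time", {
  est <- estimatePhenotypeProbabilities(toyToggle(), nRuns = 10000, seed = 123)
  p <- attractorProbabilities(est)
  se3 <- 3 * sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(p[1] - 0.5), se3 + 1e-12)
  expect_equal(sum(est@counts) + est@nonConverged, est@nRuns)
})

test_that("estimates are reproducible from their seed and conserve runs", {
  net <- randomNetwork(8, seed = 11)
  e1 <- estimatePhenotypeProbabilities(net, nRuns = 400, seed = 42)
  e2 <- estimatePhenotypeProbabilities(net, nRuns = 400, seed = 42)
  expect_identical(e1@counts, e2@counts)
  expect_identical(e1@attractorCounts, e2@attractorCounts)
  e3 <- estimatePhenotypeProbabilities(net, nRuns = 400, seed = 43)
  expect_false(identical(e1@attractorCounts, e3@attractorCounts))
  expect_equal(sum(e1@attractorCounts) + e1@nonConverged, 400L)
})

test_that("with IR fixed OFF every walk reaches the proliferative state", {
  net <- lncapNetwork()
  est <- estimatePhenotypeProbabilities(net, nRuns = 200, seed = 7,
                                        policy = "fixed_inputs",
                                        fixedInputs = c(IR = 0))
  expect_equal(unname(phenotypeProbabilities(est)[["Proliferation"]]), 1)
  expect_equal(est@nonConverged, 0L)
})

test_that("perturbation screens label rows, propagate clamp errors and flag oscillations", {
  net <- lncapNetwork()
  tab <- runPerturbationScreen(net, list("IR KO" = c(IR = "OFF")),
                               nRuns = 150, seed = 2)
  expect_equal(tab$label, "IR KO")
  expect_equal(tab$Proliferation, 1)
  expect_error(
    runPerturbationScreen(net, list(bad = c(nope = "ON")), nRuns = 10, seed = 1),
    "bad")
  # a perturbation with an oscillating attractor is flagged
  osc <- runPerturbationScreen(toyNegLoop(),
                               list(wt = character(0)), nRuns = 50, seed = 3)
  expect_true(osc$oscillatory)
  expect_equal(names(mir449aCircuitScreen())[1], "ATM KO / p53-MAIN E1 / Wip1 KO")
  expect_length(mir449aCircuitScreen(), 10L)
  expect_true(all(vapply(mir449aCircuitScreen(), function(x)
    all(x[c("miR-449a", "IR")] == "ON"), TRUE)))
})
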