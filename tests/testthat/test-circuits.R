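test_that("elementary circuits are canonical, deduplicated and complete", {
  two <- booleanNetwork(c(a = "b", b = "a"))
  expect_identical(elementaryCircuits(two), list(c("a", "b")))
  # self-loop counts as a length-1 circuit
  selfy <- booleanNetwork(c(a = "a AND b", b = "NOT a"))
  cyc <- elementaryCircuits(selfy)
  expect_true(any(vapply(cyc, identical, TRUE, y = "a")))
  # complete on a known graph: a 3-clique of mutual activation has
  # 3 two-cycles and 2 three-cycles
  tri <- booleanNetwork(c(a = "b OR c", b = "a OR c", c = "a OR b"))
  expect_equal(lengths(elementaryCircuits(tri)), c(2, 2, 2, 3, 3))
  # the LNCaP graph carries the expected feedback loops
  cycL <- elementaryCircuits(lncapNetwork())
  has <- function(nodes) any(vapply(cycL, setequal, TRUE, y = nodes))
  expect_true(has(c("p53-Killer", "p53-Arrest")))
  expect_true(has(c("ATM", "p53-MAIN", "p53-Arrest", "Wip1")))
  # circuit cap is an explicit failure
  expect_error(elementaryCircuits(tri, maxCircuits = 2), "cap")
})

test_that("edge derivatives match direct rule evaluation", {
  net <- lncapNetwork()
  expect_identical(edgeDerivative(net, "p53-Arrest", "Wip1", logical(0)), 1L)
  expect_identical(
    edgeDerivative(net, "miR-449a", "c-Myc", c(E2F1 = TRUE, RB = FALSE)), -1L)
  expect_identical(
    edgeDerivative(net, "E2F1", "c-Myc", c(`miR-449a` = TRUE, RB = FALSE)), 0L)
  expect_identical(
    edgeDerivative(net, "E2F1", "c-Myc", c(`miR-449a` = TRUE, RB = TRUE)), 0L)
  expect_error(edgeDerivative(net, "IR", "Wip1", logical(0)), "not a regulator")
  expect_error(edgeDerivative(net, "p53-Arrest", "Wip1", c(ATM = TRUE)), "exactly")
})

test_that("functionality contexts equal brute-force scans over full states", {
  for (seed in c(1, 4, 8, 13)) {
    net <- randomNetwork(6, maxInDegree = 3, pNegative = 0.5, nInputs = 0, seed = seed)
    for (circuit in elementaryCircuits(net)) {
      st <- circuitFunctionality(net, circuit, scope = "state")
      bf <- bruteForceStateContext(net, circuit)
      expect_equal(st$contextSize, bf$contextSize,
                   info = paste("seed", seed, paste(circuit, collapse = "/")))
      ci <- circuitFunctionality(net, circuit, scope = "circuit")
      expect_equal(ci$contextSize, bruteForceCircuitContext(net, circuit),
                   info = paste("seed", seed, paste(circuit, collapse = "/")))
    }
  }
})

test_that("example circuits carry their expected signs", {
  net <- lncapNetwork()
  pm <- circuitFunctionality(net, c("p53-MAIN", "Mdm2"))
  expect_true(pm$functional)
  expect_identical(pm$sign, "negative")
  ka <- circuitFunctionality(net, c("p53-Arrest", "p53-Killer"))
  expect_true(ka$functional)
  expect_identical(ka$sign, "positive")
  wip <- circuitFunctionality(net, c("ATM", "p53-MAIN", "p53-Arrest", "Wip1"))
  expect_true(wip$functional)
  expect_identical(wip$sign, "negative")
  # sign parity: a circuit's sign is the parity of its negative edges when
  # all edges are sign-pure
  edges <- inferSignedEdges(net)
  esign <- function(s, t) edges$sign[edges$source == s & edges$target == t]
  for (circuit in list(c("p53-MAIN", "Mdm2"), c("p53-Arrest", "p53-Killer"),
                       c("ATM", "Cdc25ABC", "E2F1"))) {
    f <- circuitFunctionality(net, circuit)
    signs <- mapply(esign, circuit, c(circuit[-1], circuit[1]))
    if (all(signs != "dual"))
      expect_identical(f$sign,
                       if (sum(signs == "negative") %% 2 == 0) "positive" else "negative")
  }
})

test_that("clamping any member silences a circuit", {
  net <- lncapNetwork()
  tab <- functionalCircuits(net)
  members <- attr(tab, "members")[tab$functional]
  for (circuit in members) {
    for (nm in circuit) {
      cl <- applyPerturbation(net, setNames("ON", nm))
      expect_false(circuitFunctionality(cl, circuit)$functional,
                   info = paste(paste(circuit, collapse = "/"), "clamp", nm))
    }
  }
})

test_that("the LNCaP functional-circuit table reflects the network's feedback structure", {
  tab <- functionalCircuits(lncapNetwork(), marker = "miR-449a")
  fun <- subset(tab, functional)
  # the circuit-scope criterion leaves 12 of the 255 elementary cycles
  # functional: the ten reference loops (two of them via both p53 effector routes)
  # plus ATM/Mdm2/RB/E2F1
  expect_equal(nrow(fun), 12L)
  expect_setequal(fun$circuit[fun$length == 2],
                  c("ATM/E2F1", "c-Myc/E2F1", "Mdm2/RB", "p53-Arrest/p53-INP1",
                    "p53-Arrest/p53-Killer", "p53-MAIN/Mdm2", "Sirt-1/E2F1"))
  expect_true(all(c("p53-MAIN/p53-Arrest/14-3-3s", "p53-MAIN/p53-Killer/14-3-3s",
                    "ATM/Cdc25ABC/E2F1") %in% fun$circuit))
  # every functional circuit intersects at least one miR-449a half-space
  expect_true(all(fun$markerOn | fun$markerOff))
  # the permissive per-state notion is a superset of the circuit-level one
  tabState <- functionalCircuits(lncapNetwork(), scope = "state")
  expect_true(all(fun$circuit %in% subset(tabState, functional)$circuit))
  expect_gt(sum(tabState$functional), nrow(fun))
})
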