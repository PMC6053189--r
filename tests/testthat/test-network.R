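test_that("the LNCaP checkpoint network matches its published logical rules", {
  net <- lncapNetwork()
  expect_length(networkNodes(net), 21L)
  expect_identical(networkInputs(net), "IR")
  expect_identical(networkOutputs(net),
                   c("Proliferation", "G2/M-Arrest", "G2/M-Apoptosis"))
  rules <- networkRules(net)
  expect_identical(rules[["ATR"]], "IR")
  expect_identical(rules[["miR-449a"]], "IR")
  expect_identical(rules[["Wip1"]], "p53-Arrest")
  expect_identical(rules[["G2/M-Apoptosis"]], "p53-Killer")
  # restored parenthesis in the Cdc25ABC rule: c-Myc can rescue Cdc25ABC
  # only when the kinases and 14-3-3s are off
  cdc <- parseRule(rules[["Cdc25ABC"]])
  expect_true(evaluateRule(cdc, c(`miR-449a` = TRUE, `c-Myc` = TRUE,
                                  ATM = FALSE, ATR = FALSE, `14-3-3s` = FALSE)))
  expect_false(evaluateRule(cdc, c(`miR-449a` = TRUE, `c-Myc` = TRUE,
                                   ATM = TRUE, ATR = FALSE, `14-3-3s` = FALSE)))
})

test_that("validity catches undeclared variables and duplicated nodes", {
  expect_error(booleanNetwork(c(a = "b AND c", b = "a")), "undeclared")
  expect_error(booleanNetwork(setNames(c("b", "a", "a"), c("a", "b", "a"))),
               "duplicated|unique")
  expect_error(booleanNetwork(c(a = "b", b = "a"), outputs = "z"), "outputs")
})

test_that("signed edge inference matches a direct double-evaluation oracle", {
  net <- lncapNetwork()
  edges <- inferSignedEdges(net)
  expect_equal(nrow(edges), 60L)
  expect_equal(nrow(inferSignedEdges(net, includeInputLoops = TRUE)), 61L)

  # independent oracle: scan every assignment of each target's regulators
  rules <- networkRules(net)
  nodes <- networkNodes(net)
  oracle <- list()
  for (tgt in setdiff(nodes, networkInputs(net))) {
    e <- parseRule(rules[[tgt]])
    regs <- ruleVariables(e)
    for (src in regs) {
      others <- setdiff(regs, src)
      ds <- integer(0)
      for (s in 0:(2^length(others) - 1)) {
        ctx <- setNames(as.list(bitwAnd(s, bitwShiftL(1L, seq_along(others) - 1L)) != 0L), others)
        v1 <- ctx; v1[[src]] <- TRUE
        v0 <- ctx; v0[[src]] <- FALSE
        ds <- c(ds, as.integer(evaluateRule(e, v1)) - as.integer(evaluateRule(e, v0)))
      }
      if (any(ds != 0))
        oracle[[length(oracle) + 1L]] <- data.frame(
          source = src, target = tgt,
          sign = if (all(ds >= 0)) "positive" else if (all(ds <= 0)) "negative" else "dual")
    }
  }
  oracle <- do.call(rbind, oracle)
  key <- function(d) sort(paste(d$source, d$target, d$sign))
  expect_identical(key(edges), key(oracle))

  # arc directions stated for the wiring diagram
  sgn <- function(s, t) edges$sign[edges$source == s & edges$target == t]
  for (t in c("c-Myc", "E2F1", "Cdc25ABC", "Sirt-1"))
    expect_identical(sgn("miR-449a", t), "negative")
  expect_identical(sgn("p53-Arrest", "Wip1"), "positive")
  expect_identical(sgn("p53-Arrest", "p21"), "positive")
  expect_identical(sgn("p53-Killer", "14-3-3s"), "positive")
  expect_identical(sgn("p53-Arrest", "p53-INP1"), "positive")
})

test_that("perturbations clamp nodes immutably and idempotently", {
  net <- lncapNetwork()
  ko <- applyPerturbation(net, c("miR-449a" = "OFF"))
  expect_identical(networkClamps(ko), c(`miR-449a` = FALSE))
  # original untouched; clamping twice equals clamping once
  expect_length(networkClamps(net), 0L)
  expect_identical(applyPerturbation(ko, c("miR-449a" = "OFF")), ko)
  # clamped node never unstable
  st <- setNames(rep(FALSE, 21), networkNodes(net))
  st["miR-449a"] <- FALSE
  succs <- asynchronousSuccessors(ko, st)
  if (nrow(succs)) expect_true(all(succs[, "miR-449a"] == FALSE))
  # empty spec is the identity
  expect_identical(applyPerturbation(net, character(0)), net)
  # errors
  expect_error(applyPerturbation(net, c(nope = "ON")), "unknown node")
  expect_error(applyPerturbation(net, setNames(c("ON", "OFF"), c("ATM", "ATM"))),
               "contradictory")
  expect_error(applyPerturbation(net, setNames("maybe", "ATM")), "ON/OFF")
})
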