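---
title: "Boolean dynamics of the miR-449a G2/M checkpoint model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean dynamics of the miR-449a G2/M checkpoint model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g2mLogic)
```

# The model and its assumptions

The package centres on a logical model of the G2/M DNA-damage checkpoint in
LNCaP prostate carcinoma cells. Twenty-one molecular species — the
ATM/ATR kinases, a three-node representation of p53 (`p53-MAIN` for the
ATM/ATR-phosphorylated form, `p53-Arrest` and `p53-Killer` for the arrest-
and apoptosis-promoting phosphoforms), their regulators Mdm2, Wip1,
p53-INP1, 14-3-3s and p21, the proliferative module c-Myc / E2F1 / RB /
Cdc25ABC / Cdc2-CycB with Sirt-1, the microRNA miR-449a, the input `IR`
and three readout nodes (`Proliferation`, `G2/M-Arrest`,
`G2/M-Apoptosis`) — are binarized: a node is ON when its activity suffices
to exert its downstream effect. One logical rule per node encodes the
combinatorial regulation; `IR` has no rule and keeps its initial value (the
standard input convention, equivalent to a self-activation). miR-449a is
induced by IR and represses c-Myc, E2F1, Cdc25ABC and Sirt-1.

Boolean discretization and the asynchronous scheme are strong
abstractions: no rates, no graded dosage, and every unstable node is
equally likely to fire next. What the model resolves is the *qualitative*
repertoire (which fates exist, which feedback loops gate them) and
*relative* basin sizes under the uniform kernel — not kinetics.

Three printed-source irregularities were resolved when transcribing the
rules, as the package's own modeling choices:

* the Cdc25ABC rule is read as
  `(NOT miR-449a OR c-Myc) AND NOT ATM AND NOT ATR AND NOT 14-3-3s`
  (restoring an unbalanced opening parenthesis; the only reading consistent
  with c-Myc inducing, and miR-449a repressing, Cdc25A);
* the level annotation `p53-MAIN:1` is plain `p53-MAIN` (all nodes binary);
* node identifiers are case-normalized (`Mdm2`) and kept verbatim
  otherwise, hyphens included (`14-3-3s`, `Cdc2-CycB`); the rule tokenizer
  therefore never splits identifiers on hyphens.

# Update semantics

With rules $K_i$ and state $g$, the asynchronous scheme moves one unstable
node per transition, $g_i \mapsto g_i + \mathrm{sign}(K_i(g) - g_i)$,
giving up to $n$ successors per state; a state with none is a stable state
(fixed point). The synchronous map (all nodes jump to $K_i(g)$ at once) is
provided for completeness but all analyses use the asynchronous scheme.
Attractors are the terminal strongly connected components of the
asynchronous STG: fixed points, or complex attractors (sustained
oscillations) with two or more states.

```{r attractors}
net <- lncapNetwork()
stableStates(net)[, c("IR", "Proliferation", "G2/M-Arrest", "G2/M-Apoptosis")]
```

The wild type has exactly three stable states — proliferative (`IR = 0`)
and an arrest/apoptosis bistable pair (`IR = 1`) — and no oscillation; some
perturbations (for instance miR-449a GoF, which exposes the
p53-Arrest/p53-INP1 negative loop when Sirt-1 falls) do create complex
attractors, which the engine detects and flags.

# Engine design and numerical choices

* **State encoding.** A state is an integer whose bit $k$ is node $k{+}1$
  in declaration order; under clamps the dynamics is restricted to the
  sub-space of free nodes. All rule evaluation is bit-parallel: each rule
  is evaluated once over the whole sub-space as a logical vector, so the
  full 2^21 image map of the LNCaP model costs seconds.
* **Exhaustive guard.** Exhaustive operations refuse state spaces above
  `guard` (default 2^24 states) and point to the sampling path instead.
* **Attractor search.** Below 2^16 states the full STG is decomposed into
  SCCs (igraph). Above, fixed points are enumerated directly and a
  vectorized backward closure marks every state that can reach one; only
  the residual — states provably unable to reach any fixed point, which is
  forward-closed and usually empty — is SCC-decomposed. Both routes are
  cross-checked against each other and against a mutual-reachability
  brute-force oracle in the tests.
* **Random walks.** The transition kernel is uniform over the current
  asynchronous successors (equivalently, a uniformly chosen unstable node
  flips). Walks stop at a fixed point, on entering a precomputed attractor,
  or at `maxSteps` (default 1000 × node count; capped walks are reported as
  non-converged, never folded into a phenotype). Without a precomputed
  attractor set, a revisited state triggers a terminal-SCC test of the
  forward-reachable subgraph, so oscillations are recognized on the fly.
* **Reproducibility.** Every walk draws from a substream seeded by
  `(seed, walk index)`; estimates are therefore identical regardless of
  execution order, and each screen row derives its own substream from
  `(seed, row index)`.
* **Initial-state policies.** `uniform_all` samples every free node,
  inputs included, by a fair coin — for the wild-type estimate this is what
  makes the proliferative basin come out near 50%, since the `IR = 0` half
  of the space is wholly absorbed by the proliferative state.
  `fixed_inputs` holds named inputs and samples the rest; clamped nodes are
  fixed by their clamps in either policy. The preset circuit screen models
  the irradiated condition by clamping `IR` ON outright (recorded in each
  row's clamp string), since its reference outcomes contain no
  proliferative mass.
* **Exact absorption oracle.** The same STG viewed as a Markov chain
  (uniform over successors — deliberately the walker's exact kernel, so
  any disagreement isolates an implementation bug rather than a semantic
  difference) is solved for absorption probabilities: a dense direct solve
  below 4096 transient states, and sparse value-iteration sweeps above
  (tolerance 1e-9; direct sparse factorization is avoided because the
  hypercube-like STG fills in catastrophically). Probabilities must sum to
  1 within 1e-9 or the solver aborts.

# Feedback-circuit functionality

Edges of the regulatory graph are inferred from the rules by discrete
derivatives: source $u$ regulates target $t$ iff $K_t$ differs between
$u{=}0$ and $u{=}1$ in at least one context of $t$'s other regulators; the
sign is positive/negative when all nonzero derivatives agree, `dual`
otherwise. On the LNCaP rules this yields 60 dependencies (61 counting the
input's self-maintenance loop, which `inferSignedEdges` can include on
request but which is excluded from circuit analysis — it would otherwise
count as a trivially functional positive self-loop).

Elementary cycles are enumerated with Johnson's blocked search (igraph's
installed version lacks a cycle enumerator), in canonical rotation and
deterministic order, with a hard cap that fails loudly rather than
truncating. Two functionality notions are exposed:

* `scope = "circuit"` (default): the context is a set of states of the
  *complement* of the circuit; an assignment qualifies iff every circuit
  edge has a nonzero derivative for **all** values of circuit members
  appearing among the edge contexts. Functionality is thus a property of
  the rest of the network, independent of the circuit's own state — the
  convention under which positive/negative circuits are necessary
  conditions for multistationarity/oscillation.
* `scope = "state"`: the context is the set of full states whose local
  interaction graph contains every circuit edge. Strictly more permissive
  (94 of the 255 elementary LNCaP cycles qualify, against 12 for the
  default notion).

```{r circuits}
subset(functionalCircuits(net), functional)[, c("circuit", "sign", "contextSize")]
```

The default criterion was chosen because the per-state notion degenerates
into near-vacuous breadth on densely coupled rules, while the circuit-level
notion reproduces the classical short list for this model. Two points are
worth flagging for anyone comparing against the reference account of this
network, which lists ten functional circuits in a 5 positive / 5 negative
split. First, that account names circuits by shorthand: its
"ATM/p53-MAIN/Wip1" is really the four-cycle through p53-Arrest (Wip1 is
regulated only by p53-Arrest), and its "p53-MAIN/14-3-3s" corresponds to
two three-cycles, one through each p53 effector. Second, the two counts
genuinely differ: the criterion here additionally finds the negative
four-cycle ATM/Mdm2/RB/E2F1 functional, and it assigns the Mdm2/RB
two-cycle a negative sign (Mdm2 represses RB; RB activates Mdm2 — the
parity of one negative edge), where the reference account lists "RB/Mdm2"
as positive. Both differences follow mechanically from the printed rules
and are asserted as such in the test suite rather than adjusted away.
Clamping any circuit member zeroes its derivatives and silences the
circuit, which is how the screens connect circuits to phenotypes; a
`marker` argument reports whether each circuit's context intersects the
marker-ON and marker-OFF half-spaces (for miR-449a, this is what "the
circuit's functionality is controlled by the microRNA" means
operationally).

# Synthetic fixtures and what the tests show

`randomNetwork()` generates random boolean networks that emulate this
model's structural envelope — bounded in-degree, AND/OR folds of possibly
negated regulators (`pNegative`, default 0.3), a designated input —
reproducibly from a seed. They exist to test the engine, not to be
biological: they have no output semantics, no modular structure, and their
rules are not canalizing in any curated sense. The test suite runs, on
fifty 8-node fixtures, (i) Monte Carlo estimates (10,000 walks) against the
exact absorption solver within three binomial standard errors per
attractor, and (ii) SCC attractor detection against a mutual-reachability
oracle built solely from the public successor API; parser round-trips and
the single-flip update contract are property-checked on the same fixtures.
Problem sizes were chosen so the whole suite exercises every code path —
including the full 2^21-state enumeration and the 2^16–2^20-state
perturbed sub-spaces — in a few minutes on one core.

Passing these tests shows the engine implements its stated semantics
exactly; it does not show that the uniform kernel, or the boolean
abstraction itself, is the right model of LNCaP cells.

# Known limitations

* Probabilities are defined by the uniform asynchronous kernel.
  Rate-weighted or continuous-time semantics are out of scope, and
  quantities that depend on the kernel (the arrest/apoptosis split, the
  screen probabilities) would shift under a different one. Notably, with
  Wip1 and p53-MAIN both clamped ON the printed rules make the
  p53-Arrest/p53-Killer race exactly symmetric, so any node-symmetric
  kernel gives exactly 50/50 for those screen rows; reference values for
  them that differ from 50/50 cannot be reproduced in this semantics.
* Attractor search is explicit-state (bounded by the 2^24 guard), not
  symbolic; this is ample at the model's scale but not for networks with
  hundreds of nodes.
* The miR-449a KO network retains, besides the proliferative state, an
  irradiated apoptotic fixed point (with Sirt-1 locked ON the arrest
  branch is disabled but `p53-Killer = p53-MAIN` can latch). The knockout
  therefore eliminates *arrest*, not every non-proliferative fate; the
  validation tests state both the attractor inventory and this reading.
* GoF/LoF clamps fix a node from the first instant; the transient in which
  a freshly perturbed node still carries its pre-perturbation value is not
  modeled.
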