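Package: g2mLogic
Title: Asynchronous Boolean Dynamics of the miR-449a G2/M Checkpoint Network
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Logical (boolean) modeling of the G2/M DNA-damage checkpoint in
    LNCaP prostate carcinoma cells under ionizing radiation, centred on the
    microRNA miR-449a. Provides a general engine for boolean regulatory
    networks under the asynchronous update scheme: rule parsing and
    evaluation, signed regulatory-graph inference, exhaustive stable-state
    enumeration, state transition graphs, attractor detection (fixed points
    and complex attractors via strongly connected components), Monte Carlo
    estimation of phenotype probabilities, gain/loss-of-function perturbation
    screens, and feedback-circuit functionality analysis. Ships the 21-node
    LNCaP checkpoint model as a built-in network, random boolean network
    generators for testing, and an exact Markov-chain absorption solver used
    as an oracle for the stochastic estimators. Models are read and written
    in the plain-text .bnet ("targets, factors") dialect and JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, igraph, Matrix, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: SystemsBiology, NetworkInference, GraphAndNetwork, CellCycle
RoxygenNote: 7.3.3
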