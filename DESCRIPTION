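Package: runtumble
Title: Agent-Based Simulation of Escherichia coli Chemotaxis in Ligand Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A multi-scale agent-based simulator of Escherichia coli chemotaxis.
    Each simulated cell carries an intracellular signalling cascade (mixed
    Tar/Tsr Monod-Wyman-Changeux receptor teams, methylation adaptation and
    CheA/CheB/CheY phosphorylation dynamics), maps its CheY-P level to a
    clockwise flagellar bias through a Hill law, and executes a run-and-tumble
    velocity-jump random walk in static exponential chemoattractant fields.
    Includes the two population experiments the simulator was built for --
    scaling all total signalling-protein concentrations across gradient
    steepnesses, and competition between spatially distinct MeAsp and serine
    gradients -- together with population accumulation metrics and Hill-curve
    fitting of attraction against ligand scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
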