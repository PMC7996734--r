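Package: rnalikin
Title: Consensus RNA Folding Kinetics via Helix-Index Shape Abstraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates the consensus secondary-structure folding space of a
    multiple alignment of homologous RNAs under a combined mean free energy and
    covariation (pseudo free energy) score, classifies structures into
    position-aware helix-index shapes (hishapes) and reports the k best class
    representatives, estimates refolding barriers between representatives with
    a width-limited breadth-first heuristic, and simulates folding kinetics by
    integrating the master equation over Arrhenius transition rates. Includes
    a synthetic alignment generator with controlled covariation and exact
    brute-force oracles for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    seqinr,
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
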