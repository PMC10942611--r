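Package: barnet
Title: Barcode-Sharing Network Analysis for Barcoded Rabies Virus Tracing
Version: 0.1.0
Authors@R:
    person("barnet", "developers", email = "barnet@example.org", role = c("aut", "cre"))
Description: Tools for analysing barcoded rabies-virus neuroanatomy
    experiments. Builds barcode-library frequency tables from virus-library
    sequencing reads (UMI-based counting), matches in situ barcode
    observations to injected libraries, applies per-cell barcode quality
    control (count thresholds, linguistic sequence complexity, within-cell
    error correction), groups barcoded cells into barcode-sharing networks
    under the single-source / multi-source / no-source / lost-source
    taxonomy, estimates the number of independent infection events with a
    Bayesian occupancy posterior, quantifies synaptic convergence between
    neuronal subclasses with a permutation test, and analyses multiplexed
    retrograde projections including a cubelet-level variance decomposition.
    A synthetic-experiment generator with full ground truth makes every
    stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
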