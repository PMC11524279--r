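Package: tcep
Title: Quantification of CRISPR/Cas9 Cutting Efficiency from Transient-Editing qPCR Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating Cas9 cutting efficiency at genomic target
    sites from quantitative PCR cycle-threshold (Ct) data collected after
    transient CRISPR/Cas transformation of plant tissue. Broken target DNA
    does not amplify, so the Ct shift of an amplicon spanning the cut site,
    referenced against an internal control amplicon and untreated plants,
    measures the broken-DNA fraction; normalising by Cas9 transcript
    abundance gives a relative cutting efficiency comparable across target
    sites and treatments. The package provides the delta-delta-Ct
    estimators (in vivo and in vitro variants), fold-normalisation to the
    weakest target, replicate aggregation with Student's t-tests, an NGG
    PAM scanner that predicts blunt cut positions for candidate guide
    sequences, amplicon validation for assay design, a three-state
    cut-and-repair kinetics simulator with a noisy qPCR readout for
    end-to-end validation by parameter recovery, and a command-line
    interface tying the steps into a pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
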