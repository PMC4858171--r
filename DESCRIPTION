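Package: coexscreen
Title: Candidate-Gene Co-Expression Screening for Nitrogen-Signalling Mutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the candidate-gene co-expression screen used
    to find regulators of ammonium and nitric-oxide signalling in
    Chlamydomonas reinhardtii. Relative expression measured by qRT-PCR across
    a factorial mutant x nitrogen-condition x time-course design is
    mean-centred within each condition/time cell, log2-transformed, and
    screened by exclusion-aware Pearson correlation against a reference gene
    (CYG56), with optional leave-strain-out recomputation. A companion
    misregulation screen flags genes whose per-mutant mean fold change
    crosses a threefold cutoff. Includes delta-Ct quantification against an
    internal-standard transcript, percent-of-control and Student t reporting
    helpers, and a synthetic-data generator that emulates the factorial
    design (insertional knockouts, shared-regulator genotype effects,
    condition and time effects, multiplicative noise) so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
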