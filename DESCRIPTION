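Package: multimotif
Title: Multi-Model de Novo Motif Discovery and ChIP-Seq Peak Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains four structurally different transcription factor binding
    site models (position weight matrix, dinucleotide PWM, inhomogeneous
    Markov model, and an order-pruned Markov variant) de novo from ChIP-seq
    peak sequences, calibrates all model thresholds to a common empirical
    false positive rate on a promoter background, scans peaks for sites, and
    classifies peaks by which models detect sites and whether the predicted
    sites positionally intersect. Includes cross-validated partial-AUC model
    evaluation, a permutation-based frequency-matrix similarity filter, a
    synthetic peak-set generator with planted motifs, and an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
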