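Package: kanneal
Title: Reference-Free Tuning of k for Genomic Error-Correction Tools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects the k-mer length parameter of a black-box sequencing-read
    error-correction tool without a reference genome. A non-directional
    transformer language model (or an N-gram baseline) is trained on word
    tokens of the uncorrected reads; candidate corrections produced at
    different k are scored by corpus perplexity, which acts as a
    reference-free proxy for downstream alignment rate; the k minimizing
    perplexity is located by simulated annealing. Includes FASTA/FASTQ
    plumbing, a read simulator with recorded ground truth, a built-in
    k-spectrum toy corrector, and an exact alignment-rate oracle for
    validation on synthetic data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
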