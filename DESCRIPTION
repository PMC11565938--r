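Package: asmtune
Title: Sample-Specific Parameter Advising for Transcript Assemblers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns, from per-sample Bayesian-optimization traces, an
    embedding of RNA-seq samples in which samples with similar optimal
    assembler parameters lie close together, and predicts sample-specific
    advisor sets of parameter vectors for transcript assemblers such as
    Scallop and StringTie2. Includes mixed-space Gaussian-process Bayesian
    optimization with a coordinate-ascent warmup, transcript-assembly
    evaluation (intron-chain matching and the abundance-ranked
    precision-sensitivity AUC), MinHash sketch representations of RNA-seq
    samples with Mash distances, a trace-derived normrank similarity with
    shortest-path metric repair, a permutation-invariant set encoder
    trained by contrastive regression, and nearest-neighbor parameter
    advising. Ships a synthetic-data generator so the full pipeline runs
    end-to-end with no external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
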