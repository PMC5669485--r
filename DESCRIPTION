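Package: ppidstk
Title: Distributed Smoothed Tree Kernels for Protein-Protein Interaction
    Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sentence-level extraction of protein-protein interactions from
    annotated biomedical corpora using kernel methods. Implements a lexical
    feature-based kernel (protein-name words, context windows, inter-entity
    word-distance bins), a distributed smoothed tree kernel over lexicalized
    constituency parse trees (random structural vectors composed by shuffled
    circular convolution, paired with PPMI+SVD distributional head-word
    vectors), and their composite kernel trained with a support vector
    machine on precomputed Gram matrices under stratified 10-fold
    cross-validation. Includes readers and writers for the unified PPI XML
    corpus dialect and Penn-Treebank bracketed parses, an exact brute-force
    smoothed tree kernel used as an oracle for the distributed
    approximation, and a deterministic synthetic corpus generator so the
    whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    kernlab,
    pROC,
    stats,
    tools,
    utils,
    xml2,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
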