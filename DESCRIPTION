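Package: florafam
Title: MADS-Box Gene Family Mining, Divergence and Co-Expression Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining MIKC-type MADS-box transcription factor genes from
    plant transcriptome unigenes and characterising the family: six-frame
    translation with position-specific log-odds domain scanning, greedy
    redundancy clustering at a sequence-identity cutoff, neighbor-joining clade
    classification against a labelled reference panel, per-site divergence and
    Nei-Gojobori Ka/Ks statistics on domain codon blocks, qRT-PCR relative
    expression (2^-dCt) and stage fold-change summaries, and family-anchored
    co-expression networks built with a density-minimising Pearson correlation
    threshold, including hub connectivity, tissue-specificity calls and
    hypergeometric GO-term enrichment. A synthetic-data module generates all
    inputs with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
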