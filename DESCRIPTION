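Package: cladiv
Title: Clade-Partitioned Codon Models, Proteotyping and Codon Usage Bias
    for Intra-Species Divergent Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting divergent evolution between subclades of a
    virus species from aligned coding sequences: consensus proteotyping of
    protein alignments with a 10 percent divergence rule and genome-ordered
    assortment scans for recombination; a Goldman-Yang codon substitution
    model with Clade model C site classes, Felsenstein-pruning likelihoods
    on clade-labeled trees, nested-model fitting and chi-square likelihood
    ratio tests; relative synonymous codon usage (RSCU) over the 59
    informative codons with correspondence analysis; distance-based
    neighbor-joining trees with bootstrap support; and a seeded simulator
    that generates codon alignments with planted site-class structure,
    divergent windows and group-specific codon bias so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    cluster,
    stats,
    utils
Suggests:
    MASS,
    mclust,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
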