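Package: bpps
Title: Bayesian Partitioning with Pattern Selection for Protein Subgroup
    Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint classification of aligned protein sequences into
    functionally divergent subgroups and selection of the residue patterns
    that discriminate each subgroup's foreground from its background.
    A hyperpartition table (or a rooted phylogenetic tree converted into
    one) defines multiple foreground-versus-background contrast categories;
    a Gibbs sampler reassigns non-seed sequences among subgroups and
    resamples per-category patterns under a beta-binomial column contrast
    model, with automatic rejection of aberrant sequences. Outputs include
    contrast alignments, per-position pattern strengths in nats, and
    predictive membership probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Classification, MultipleSequenceAlignment, Bayesian, Proteomics
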