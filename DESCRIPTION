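Package: trnadyn
Title: Evolutionary Dynamics of the Bacterial tRNA Repertoire
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the presence/absence dynamics of tRNA
    species across bacterial genomes. Implements wobble-rule based
    classification of anticodon species into mandatory and auxiliary sets,
    codon-bias statistics (effective number of codons with
    background-composition correction), phylogenetically controlled
    maximum-likelihood regression of tRNA presence on genomic traits with
    Pagel's lambda, a two-state gain/loss model with ancestral posteriors
    and stochastic mapping, permutation tests for co-gain and co-loss,
    sequence-similarity based inference of the origin of newly gained tRNA
    genes (horizontal transfer, anticodon mutation, duplication), operon
    co-occurrence counting, and a fully seeded synthetic-data generator
    that emulates every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    nlme,
    knitr
Config/testthat/edition: 3
biocViews: Phylogenetics, Genetics, SequenceMatching, Software
RoxygenNote: 7.3.3
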