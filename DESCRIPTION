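Package: ppdtools
Title: Synteny-Based Analysis of Post-Polyploid Diploidization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reconstructing and quantifying post-polyploid
    diploidization (PPD) from gene orders and homology. Provides a forward
    simulator of gene-order evolution along a phylogeny (allopolyploidy,
    biased fractionation, dysploidal rearrangements, divergence
    accumulation), collinear anchor chaining with an orthology index,
    relative-ploidy estimation from synteny depth, subgenome phasing,
    ancestral-karyotype reconstruction with classification of end-to-end
    joinings, nested chromosome fusions, reciprocal translocations and
    fissions, and PPD indices (chromosome dysploidy rate, gene loss rate)
    with phylogenetic generalized least squares correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
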