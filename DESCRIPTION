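Package: wgdinfer
Title: Total-Evidence Inference and Phylogenetic Placement of Ancient
    Whole-Genome Duplications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers ancient whole-genome duplications (paleopolyploidy)
    from transcriptome-scale data and places them on a species phylogeny
    using three complementary lines of evidence. Builds gene-age (Ks)
    distributions from duplicate-pair filtering, single-linkage gene
    families and per-node synonymous-divergence estimates; detects WGD
    peaks with a simulated null, Kolmogorov-Smirnov tests and Gaussian
    mixture models; places peaks relative to lineage divergences via
    reciprocal-best-hit ortholog Ks; and corroborates placements with a
    gene-tree-sorting analysis (MAPS) backed by birth-death gene-family
    simulations and Fisher exact tests against null and positive
    simulation sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    ape,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    phangorn,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
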