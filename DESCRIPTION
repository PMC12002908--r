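Package: phyloMarkers
Title: Phylogeny-Guided Marker Selection and Clonal Tracking for Circulating Tumor DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing small high-precision liquid-biopsy marker
    panels guided by tumor phylogenies. Estimates an empirical density over
    candidate clonal trees from bootstrap replicates, selects marker subsets
    that either maximally discriminate candidate tree structures or maximally
    track weighted subclone fractions (exact branch-and-bound subset
    optimization), refines the tree density from high-precision marker read
    counts via Bayesian pairwise-relationship updates, and quantifies per-clone
    fractions longitudinally from marker variant allele frequencies. Includes
    CASet and DISC tree distances, a synthetic-data generator emulating
    multi-sample bulk sequencing with bootstrap tree building, a PhyloWGS-style
    adapter, and VCF/TSV/JSON interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
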