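Package: phylofiltr
Title: Alignment Filtration and Gene Tree Curation for Phylogenomic
    Species-Tree Workflows
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for curating sequence-capture phylogenomic data sets
    before species-tree estimation: per-marker alignment quality control
    (reference-divergence screening, external trimming, reading-frame
    selection, window-based misalignment masking), alignment summary
    statistics (parsimony-informative sites, taxon sampling, missing
    data), threshold-series filtration of alignments and paired gene
    trees, supermatrix concatenation with codon-aware partitions, gene
    jackknifing, clade monophyly and support scoring, low-support branch
    collapsing, gene concordance factors, configuration-file generation
    for downstream species-tree programs, and a synthetic marker-set
    generator for end-to-end testing of filtration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    phangorn,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite,
    withr
Config/testthat/edition: 3
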