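Package: scMiRNet
Title: Cell-Specific miRNA-mRNA Regulatory Network Inference from
    Matched Single-Cell Co-Sequencing Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers a miRNA-mRNA regulatory network for every individual
    cell from small-scale matched single-cell miRNA and mRNA expression
    profiles. Small datasets are enlarged by interpolating pseudo-cells
    (uniform resampling of whole-cell profiles with replacement) and a
    bootstrap ensemble of augmented datasets; for each putative binding
    pair and each real cell a neighborhood co-occupancy statistic is
    computed and aggregated by the bootstrap median, yielding one
    significance-filtered bipartite network per cell. Downstream analytics
    cover hub miRNAs, conserved and rewired regulation, cell-cell
    similarity and crosstalk networks, Markov clustering of cells,
    maximal-biclique regulatory modules and hypergeometric disease
    enrichment, plus a seeded synthetic-data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, NetworkInference, GeneRegulation
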