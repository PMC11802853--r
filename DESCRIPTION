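Package: immunoclone
Title: Single-Cell Immune Repertoire and Microenvironment Analytics
Version: 0.1.0
Authors@R:
    person("PancrImmune", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for single-cell immune analyses of paired blood and
    tumour samples: VDJ chain assignment per droplet, dual-criterion B- and
    T-cell clone calling via somatic-hypermutation networks and union-find,
    depth-normalised intra- and inter-subset clonality by repeated fixed-depth
    subsampling, clonal transition and recirculation analysis, cell-count
    independent receptor-ligand interaction scoring, signature module scoring
    with a learned professional-APC threshold, declarative threshold gating,
    per-sample gene-correlation modules, SVM-based reference cell-type label
    transfer, and MANOVA group comparisons. A seeded synthetic-data generator
    emulates contig tables, count matrices and metadata so every analysis is
    testable without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    withr,
    methods,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
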