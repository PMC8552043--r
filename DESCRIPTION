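Package: airtraffic
Title: B-Cell Repertoire Trafficking Analysis Across Airway Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of adaptive immune receptor repertoire (AIRR-seq)
    B-cell receptor data from multiple tissue sites, centred on
    maximum-parsimony tissue phylogeography of clonal lineage trees with a
    within-tree permutation null for directional trafficking. Includes AIRR
    Rearrangement TSV input/output with quality-control filtering and full
    accounting, junction-based clonal inference, germline-rooted parsimony
    lineage trees, Hill-number diversity profiles with depth resampling and
    rarefaction, BASELINe-style estimation of somatic-hypermutation
    selection strength, CDR3 physicochemical property analysis, IgD-only
    clone characterisation, and a seeded multi-tissue repertoire simulator
    with plantable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
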