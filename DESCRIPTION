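Package: metacaspase
Title: Survey of Prokaryotic Caspase Homologs from Profile-HMM Domain Hits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-scale surveys of prokaryotic metacaspases
    (bacterial Peptidase C14 caspase homologs). Screens profile-HMM domain
    hits with E-value and score/bias thresholds, resolves overlapping Pfam
    domains into N- to C-terminal domain architectures, integrates predicted
    transmembrane topology, classifies conservation of the catalytic
    cysteine-histidine dyad by global alignment to an annotated reference,
    curates non-redundant training sets by greedy identity clustering,
    assigns function and localization categories, maps metacaspases into
    predicted operons, and aggregates per-genome and per-taxon abundance
    statistics. A synthetic survey generator with a planted ground-truth
    manifest supports end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
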