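Package: pksline
Title: Modular Type I Polyketide Synthase Annotation and Colinearity-Based
    Product Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates modular type I polyketide synthase (PKS) proteins by
    locating catalytic domains (KS, AT, DH, ER, KR, ACP, TE) with
    alignment-anchored windows validated by degenerate catalytic-motif
    scanning; classifies acyltransferase extender-unit specificity
    (malonyl-CoA vs methylmalonyl-CoA) by diagnostic residues and by
    neighbor-joining phylogenetic placement with bootstrap support;
    stereo-types ketoreductases (A-type vs B-type via Trp and LDD/LED
    signatures); partitions domains into loading and extension modules
    across multiple open reading frames; and applies the colinearity rule
    to predict the per-carbon chemotype of the macrolactone backbone
    (hydroxyl configuration, E-double bonds, methyl branches), including
    reconciliation of the prediction against an observed structure. Ships
    a synthetic assembly-line simulator with known ground truth, including
    a fixture reproducing the reedsmycin (RDM) PKS organization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
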