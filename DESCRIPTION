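Package: acidforest
Title: Genotype-to-Phenotype Prediction of Milk Acidification Rates with
    Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for predicting the maximum hourly milk acidification
    rate (Vmax) of Lactococcus lactis strains from genome content.
    Extracts Vmax from microplate pH or hue kinetic curves via sliding-window
    slopes and a degree-4 hue-to-pH calibration, builds four genomic feature
    representations (gene presence/absence, Pfam domain copy numbers,
    canonical 8-mer and 9-mer counts) with pruning and co-occurrence
    collapsing, trains and evaluates random-forest regressors of Vmax under
    experimental conditions, tests reliance on genomic signal with two
    permutation schemes, and performs TreeSHAP feature-importance and
    cross-representation consensus analysis. Includes a clade-structured
    synthetic population generator with planted causal loci so the whole
    pipeline can be exercised and validated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ranger,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
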