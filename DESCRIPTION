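Package: mirhairpin
Title: Classification of MicroRNA Precursor Hairpins with Imbalance-Aware
    SVM Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Separates real microRNA precursor hairpins from pseudo
    hairpins using 65 sequence, secondary-structure and thermodynamic
    features (including four multi-loop features), F-score feature
    ranking, and an imbalance-aware ensemble of radial-basis-function
    support vector machines aggregated by majority vote or mean-distance
    dispatch. Includes a self-contained dynamic-programming folding
    engine (minimum free energy and partition function under an additive
    base-pair energy model), a dinucleotide-preserving shuffle null
    model, stratified outer 3-fold cross-validation with
    geometric-mean-based metrics, and synthetic fixture generators for
    hairpin-like positives and multi-branched pseudo negatives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    e1071,
    methods,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
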