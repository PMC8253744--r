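Package: vlamy
Title: Amyloidogenicity Prediction for Antibody Light-Chain Variable Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of the amyloidogenic potential of
    antibody light-chain variable domains (VL). Computes region-aware
    physicochemical features (hydrophobicity of the CDRs, gatekeeper-residue
    content of the frameworks, intrinsic-disorder propensity, beta-sheet
    propensity, charge-transfer capability, transfer free energy to surface)
    from IMGT-segmented sequences, trains an interpretable separate-and-conquer
    rule classifier in the style of PART with an imbalance-aware decision
    threshold, and evaluates it with ROC/AUC, leave-one-out and k-fold
    cross-validation and repeated stratified resampling. Also provides Shannon
    entropy / occupancy / consensus profiling of multiple sequence alignments,
    gatekeeper analysis of the flanks of aggregation-prone regions, and a
    seeded generator of synthetic kappa/lambda-like VL datasets with planted
    class effects for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    Rcpp,
    methods,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    bio3d,
    pROC,
    withr
Config/testthat/edition: 3
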