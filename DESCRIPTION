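Package: sweepnet
Title: Selective Sweep Inference from Local Genealogies with Recurrent Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects selective sweeps and infers selection coefficients and
    allele-frequency trajectories from the local genealogies of an ancestral
    recombination graph. Genealogies are encoded as ancestral/derived lineage
    counts on a fixed grid of discretized time points, together with total
    lineage counts of flanking genealogies, and the resulting fixed-dimension
    feature vectors are fed to a stacked long short-term memory (LSTM) network
    trained on coalescent simulations. Includes a conditioned Wright-Fisher
    trajectory sampler and a structured coalescent-with-recombination simulator
    for generating labeled training data, Monte Carlo dropout uncertainty
    intervals, classical haplotype summary statistics (Tajima's D, Fay and Wu's
    theta_H, Garud's H statistics, ZnS, omega, iHS) as baselines, and an
    evaluation harness with ROC/AUROC, regression error metrics, stratified
    reports and parameter-mismatch robustness experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vcfR,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
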