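Package: teflow
Title: Transfer Entropy and Information Flow in Evolved Boolean Neural Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to study how well pairwise transfer entropy recovers
    directed information flow in small cognitive circuits built from binary
    neurons and deterministic 2-to-1 logic gates (Markov Brains). Provides
    exact Shannon information measures on discrete joint distributions
    (entropy, mutual information, transfer entropy, co-information and the
    associated entropy decompositions), an analytic catalog of all sixteen
    2-to-1 Boolean gates with their transfer-entropy misestimates, a
    deterministic Markov Brain simulator with ground-truth influence maps,
    motion-detection and sound-localization task environments, a genetic
    algorithm that evolves circuits to solve them, gate-knockout essentiality
    assays, and detection scoring (hit/false-alarm counts and ROC curves with
    a binormal fit) of empirical transfer-entropy matrices against the
    ground-truth influence map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
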