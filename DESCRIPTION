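Package: emovista
Title: Phase-Resolved Emotion Surveillance of Short Social-Media Posts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for infoveillance of public emotion in
    short social-media posts across defined time phases. Implements
    Plutchik eight-emotion scoring with embedding-expanded lexicons,
    negation flipping and valence modifiers; normalized per-phase emotion
    intensity profiles; first-order Markov emotion-transition models over
    conversation threads; latent Dirichlet allocation topic models with
    RAKE keyphrase extraction and cross-phase topic association; growing
    self-organizing map (GSOM) behavior profiling of users; and
    between-phase two-proportion comparisons with Pearson chi-square tests
    and Newcombe hybrid Wilson-score confidence intervals. A synthetic
    tweet-stream generator with full ground truth makes every stage
    testable without access to any platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tibble,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
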