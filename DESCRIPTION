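Package: perspectr
Title: Collective-Intelligence Tailoring of Motivational Health Messages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Collaborative-filtering selection of motivational smoking-cessation
    messages from explicit user ratings, in the style of the PERSPeCT
    (Patient Experience Recommender System for Persuasive Communication
    Tailoring) system. Implements Bayesian probabilistic matrix factorization
    with Gibbs sampling and cold-start user inference, MAP probabilistic
    matrix factorization, user-based K-nearest-neighbour and mean baselines,
    the strong-generalization algorithm-selection protocol (user folds,
    per-user rating folds, observed-rating budgets, grid search with boundary
    extension, RMSE / Kendall tau-b / NDCG metrics, Bonferroni-corrected
    paired comparisons), a daily message scheduler for both the
    recommender policy and a rule-based stage-matched comparator, a two-arm
    block-randomized trial simulator, and the trial's statistical analysis
    (daily mean ratings, days-agreed proportions, chi-square contingency
    tests, windowed t tests, readiness-ladder movement).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
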