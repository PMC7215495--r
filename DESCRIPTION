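Package: tailormsg
Title: Collaborative-Filtering Message Tailoring and Trial Analysis for
    Smoking-Cessation Messaging Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for collective-intelligence tailoring of motivational
    smoking-cessation messages and for analysing the trials that deploy
    them. Implements user-based k-nearest-neighbour, probabilistic matrix
    factorization (ALS), and Bayesian probabilistic matrix factorization
    (Gibbs sampling) recommenders over a sparse Likert rating matrix, with
    cold-start inference of user factors under frozen item-side
    parameters; a strong-generalization evaluation protocol (disjoint
    test users, nested support levels, RMSE / Kendall tau-b / NDCG,
    grid search with iterative range extension, Bonferroni-corrected
    paired comparisons); a daily message scheduler with a rating feedback
    loop; trial statistics (daily group rating means, dichotomized impact
    items, chi-square and trend tests, odds ratios, logistic models, and
    quasi-Bayesian causal mediation with percent-of-effect-mediated); and
    a synthetic two-group cohort generator with planted latent preference
    structure and a known mediated fraction for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
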