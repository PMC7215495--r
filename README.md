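# tailormsg

Collective-intelligence tailoring of motivational smoking-cessation
messages, and the statistics of the trials that deploy it.

Computer-tailored health communication systems send each smoker messages
matched to them personally. Instead of hand-written "if female and not
ready to quit, send message 12" rules, a collective-intelligence system
uses the pooled 1–5 ratings that earlier smokers gave a bank of expert-
and peer-written messages: a collaborative-filtering model learns latent
message and user factors from those ratings, infers a new user's factors
from the few ratings they provide, and each day sends the unsent message
with the highest predicted rating. `tailormsg` implements that machinery
end to end, together with the analysis chain used to evaluate such a
trial (group rating comparisons, engagement, dichotomized impact items,
cessation odds ratios, and causal mediation), and a synthetic cohort
generator with known ground truth so every estimator can be validated by
parameter recovery.

It is aimed at researchers in health communication and biostatistics who
want to simulate, run, or analyse message-tailoring trials.

## Models

**Recommenders.** Three engines over a sparse users × messages Likert
matrix `R`:

- *user-kNN*: Pearson similarity on co-rated items (minimum overlap 2),
  prediction by the mean-centered similarity-weighted neighbour average;
- *PMF*: the MAP estimate of `R_ij ≈ μ + u_i·v_j` with Gaussian priors,
  i.e. minimising `Σ(R_ij − μ − u_i·v_j)² + λ_u‖U‖² + λ_v‖V‖²` by
  alternating least squares;
- *BPMF*: the fully Bayesian version — Gaussian priors on `u_i` and `v_j`
  whose means and precisions carry Gaussian–Wishart hyperpriors
  (`μ₀ = 0, β₀ = 2, ν₀ = D, W₀ = I`), fit by Gibbs sampling. A rating is
  predicted by the expected value of `u_i·v_j` over the retained
  posterior draws, clipped to `[1, 5]`.

**Cold start.** New users are handled under the *strong generalization*
contract: all item-side parameters stay frozen and only the user's
factors are inferred from their support ratings (ridge solve for PMF,
conditional Gaussian draws per posterior sample for BPMF). The
evaluation harness (`make_strong_gen_splits()`,
`run_strong_generalization()`) separates test users from training users
entirely, gives each test user nested support sets of 5 ⊂ 10 ⊂ 16
ratings plus a fixed 4-rating test set, and scores RMSE, Kendall's
tau-b, and NDCG, with grid search (iteratively extended ranges) for
hyperparameters and Bonferroni-corrected paired t tests between models.

**Scheduler.** One unsent message per user per day, at most 30 messages
within a 65-day window; an incoming rating immediately re-infers the
user's factors, so later sends are better personalized.

**Trial statistics.** Daily group rating means, agree/strongly-agree
dichotomization (rating ≥ 4), Pearson chi-square (no continuity
correction), Mantel-extension trend tests, cross-product odds ratios
with Wald CIs, logistic outcome models, and quasi-Bayesian causal
mediation: a linear model for the mediator, a logistic model for the
outcome, Monte-Carlo draws from both sampling distributions, and the
decomposition total effect = ACME + ADE with
`percent mediated = 100 · ACME / total`.

## Worked example

```r
library(tailormsg)

# a synthetic two-group cohort: 55 + 64 smokers, 261 messages, 30
# message-days inside a 65-day window
co  <- generate_cohort(cohort_spec(seed = 1))
mat <- rating_matrix(co$events, co$profiles$user_id, co$bank$message_id)
mat
#> rating_matrix: 119 users x 261 items, 2514 observed (density 0.081)

# Bayesian PMF on the observed ratings
model <- fit_bpmf(mat, rank = 4, n_burn = 30, n_samples = 60, seed = 1)

# a new user arrives with five ratings; item factors stay frozen
view <- infer_user_factors(model, c(m001 = 5, m002 = 4, m010 = 2,
                                    m017 = 5, m030 = 4), seed = 2)
head(rank_messages(model, view,
                   setdiff(co$bank$message_id, names(view$ratings))), 3)
#>   message_id predicted
#> 1       m092  4.205067
#> 2       m180  4.202210
#> 3       m171  4.199612
```

The top-ranked rows are the messages the scheduler would send this user
first: their predicted 1–5 agreement with "this message influenced me to
quit".

```r
# follow-up quit table (counts 30/51 vs 19/50)
tab <- contingency_2x2(30, 21, 19, 31)
odds_ratio_2x2(tab)   # OR 2.33 (95% CI 1.05-5.18)
chi_square_2x2(tab)   # chi2 4.38, p = 0.036

# did the rating experience mediate the cessation difference?
rated <- co$events[!is.na(co$events$value), ]
d <- as.data.frame(co$trial)
d$treat <- as.numeric(d$group == "african_american")
d$mean_rating <- as.numeric(tapply(rated$value, rated$user_id,
                                   mean)[d$user_id])
mediation_analysis(d, "treat", "mean_rating", "quit_30day",
                   n_sims = 1000, seed = 3)
#> Causal mediation (quasi-Bayesian, 1000 sims, n=119)
#>   ACME    0.0633 [-0.0080, 0.1451]
#>   ADE     0.1791 [-0.0131, 0.3528]
#>   Total   0.2425 [0.0628, 0.4076]
#>   Percent mediated 26.1%
```

Here the total group effect on 30-day cessation is 0.24 on the
probability scale, of which roughly a quarter flows through the rating
path in this single simulated cohort (the generator's true mediated
fraction is ~40%; single-cohort estimates at n = 119 scatter widely —
see the methods vignette).

A command-line wrapper (`inst/cli/tailormsg`) exposes `simulate`,
`evaluate`, `schedule`, and `analyze` subcommands over the same
functions.

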