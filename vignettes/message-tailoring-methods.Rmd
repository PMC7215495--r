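---
title: "Methods: collaborative-filtering message tailoring and trial analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collaborative-filtering message tailoring and trial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tailormsg)
```

This vignette records the models, the numerical choices, and the design
decisions behind `tailormsg`, in the spirit of a statistical methods
appendix. Nothing here is an empirical claim beyond what the package's
test suite and `scripts/acceptance.R` themselves compute.

## The tailoring problem

A message-tailoring system holds a bank of a few hundred short
motivational messages (expert-written and peer-written, tagged with
content such as reasons-to-quit, tips and strategies, NRT use,
distraction/substitution). Each enrolled smoker receives one message a
day for up to 30 messages within a 65-day window and may reply with a
1–5 Likert rating of how much the message influenced their motivation to
quit. Ratings are optional; the more a user rates, the better the
system can personalize. The statistical task is collaborative filtering
on a sparse users × messages matrix, with the twist that every live user
is a *cold-start* user: the model is trained on a historical corpus and
only the user-specific parameters may be learned during the trial.

## Recommenders

All three engines treat the global mean rating `μ` as a fixed offset and
model centered ratings.

**User-kNN.** Pairwise user similarity is the Pearson correlation over
co-rated items. Pairs with fewer than `min_overlap = 2` co-rated items,
or with a constant rating vector on the overlap, get similarity 0: one
shared item always yields ±1 and carries no evidence. Prediction is the
user's mean plus the similarity-weighted average of the k most similar
raters' mean-centered ratings of the item, falling back to the item
mean, then the global mean. The weighting denominator uses `Σ|w|` so
negative similarities cannot inflate the estimate.

**PMF (MAP, ALS).** `R_ij ≈ μ + u_i·v_j` with ridge penalties
`λ_u, λ_v` (default 0.1). We fit by alternating least squares rather
than stochastic gradient descent because each half-sweep is an exact
ridge solve: the objective is provably non-increasing, the fit is
deterministic given the initialisation seed, and convergence is easy to
test. Iteration stops when the relative objective change drops below
`tol = 1e-6` (the remaining movement is far below rating noise);
exhausting `n_iter` sweeps flags `converged = FALSE` with a warning,
never silently. Centering matters: with it, the infinite-regularization
limit shrinks every prediction to the global mean rather than to an
out-of-scale zero.

**BPMF (Gibbs).** Gaussian priors on user and item factors whose means
and precision matrices carry Gaussian–Wishart hyperpriors with the
standard weakly-informative settings `μ₀ = 0`, `β₀ = 2`, `ν₀ = D`,
`W₀ = I`. The sampler alternates hyperparameter draws (conjugate
Gaussian–Wishart updates) with row-wise conditional Gaussian draws of
the factors, after a 5-sweep ALS warm start. Defaults are rank `D = 8`,
100 burn-in sweeps, 200 retained draws; tests and the acceptance script
use smaller chains (rank 2–4, 25–60 burn-in, 40–100 draws) on matrices
of 20–119 users × 30–261 items, sizes at which the posterior summaries
they assert are already stable. The observation precision `α`
(default 2, i.e. rating noise SD ≈ 0.7) is a fixed hyperparameter; when
the true noise is much smaller, `α` should be selected on validation
data like any other hyperparameter — the acceptance checks do exactly
that with `grid_search()`. A user or item with no ratings is drawn from
its prior rather than raising an error, because a live system must
always be able to rank a message for anyone.

**Prediction and ranking.** BPMF predicts with the posterior-mean dot
product; all predictions are clipped to `[1, 5]` after averaging, since
an unbounded dot product is meaningless against a Likert scale. Ranking
sorts by predicted value with ties broken by ascending message id, so a
fixed model induces a deterministic total order — reruns of the
scheduler are reproducible.

**Cold start.** `infer_user_factors()` never touches the model object:
PMF solves one ridge regression against the frozen item factors; BPMF
makes one conditional Gaussian draw of the user factor per retained
posterior sample (using that sample's item factors and user-side
hyperparameter draw); kNN computes the new user's similarities to the
training users. An empty rating set falls back to the prior-mean factor
(zero in the centered parameterisation, so predictions equal the global
mean) with a warning.

## Strong-generalization evaluation

Test users are wholly disjoint from training users. Users need at least
20 observed ratings to serve as test users — 16 for the largest support
set plus the constant 4-rating test set; everyone else still contributes
to training. Each of 5 user folds carries 3 validation partitions over
the train users (each holding out 10% of every train user's ratings — a
fraction we fixed as a design choice) for hyperparameter selection.
Support sets are nested (5 ⊂ 10 ⊂ 16) so the support-level curve is a
within-user comparison.

Metrics: RMSE pools all test predictions in a fold; Kendall's tau-b
(tie-corrected, `(C−D)/√((n₀−n₁)(n₀−n₂))`) and NDCG are computed per
test user over their 4 test ratings and averaged. NDCG uses the common
exponential-gain convention `(2^rel − 1)/log₂(rank+1)`; a user whose
test ratings are entirely tied has no defined tau and is skipped in that
average (any ordering of an all-tied set is perfect, so NDCG returns 1).

Grid search evaluates every point of the hyperparameter grid on mean
validation RMSE, then iteratively extends any interval whose optimum
sits on an end point — geometrically for scale parameters
(regularizers, precisions), arithmetically for counts (k, rank) — up to
`max_extensions` (default 3), returning a flagged best point if
extensions run out. Model comparison runs two-sided paired t tests on
fold-level metric values matched on (fold, support), multiplying each
raw p by the number of model pairs (Bonferroni), capped at 1;
zero-variance differences are reported degenerate rather than given a
fake p.

The harness returns an `audit` attribute listing every (user, item)
pair consumed in fitting and cold-start inference per fold; the test
suite asserts these are disjoint from the test pairs, so "no test
rating is ever seen" is an instrumented property, not a convention.

## Scheduler

One message per user per day, drawn from the bank minus the sent set by
`rank_messages()`; the state deactivates at 30 sends or day 65,
whichever comes first, and a send-day pattern with gaps still terminates
within the window. A reply rating immediately re-infers the user's
factors (one conditional solve — cheap enough that there is no reason to
batch nightly); an unrated send is recorded with a missing value and
changes nothing. We freeze item factors during scheduling, mirroring the
cold-start contract; retraining item factors online is a deliberate
non-feature, since it would let one user's replies shift every other
user's predictions mid-trial.

The personalization property — sends in days 21–30 have higher true
ratings than sends in days 1–10 for users who rate daily — holds in the
deployment regime the tests simulate: a bank much larger than the
30-send horizon and noisy discrete replies. With a small bank or
noiseless replies a greedy scheduler learns the user almost immediately
and then *descends* the preference ranking, so the late window is worse
by construction. This is a real property of greedy tailoring, worth
knowing when configuring bank sizes.

## Trial statistics

- Daily group rating = mean of the ratings given by the group's members
  that day; days with no raters are missing, never zero. Group series
  are compared by counting days one group exceeds the other, the
  proportion of days with mean ≥ 4 (agree/strongly agree), and a
  two-sample t test on the daily means (pooled-variance by default,
  Welch optional).
- Impact items dichotomize at rating ≥ 4; missing responses stay
  missing and drop out of denominators (complete-case, which is why
  item denominators can differ).
- 2×2 tables: Pearson chi-square without continuity correction
  (df = 1); the cross-product odds ratio with Wald CI, applying the
  Haldane–Anscombe 0.5 correction (flagged) only when a cell is zero.
  Zero-margin tables return missing with a warning rather than a
  statistic.
- Trend across ordered categories uses the Mantel-extension /
  Cochran–Armitage score test on 1 df (`stats::prop.trend.test`); with
  two categories it reduces exactly to the Pearson chi-square.
- Logistic models are maximum-likelihood fits via `stats::glm`, with
  exponentiated coefficients and Wald CIs; separation (divergent
  coefficients) is an error naming the variable.

**Causal mediation.** Binary treatment (group), continuous mediator
(the user's mean rating — the only per-subject scalar compatible with a
subject-level outcome model; the day-level series is the alternative we
considered and rejected), binary outcome (30-day cessation). The
quasi-Bayesian algorithm draws `n_sims = 1000` parameter vectors from
the asymptotic normal distributions of the fitted linear mediator model
and logistic outcome model (mediator residual SD held at its estimate),
simulates potential mediator values under treatment and control with a
shared error draw, forms the four potential outcome probabilities
`p(t, M(t'))`, and averages ACME and ADE over both treatment arms —
which makes `ACME + ADE = total effect` an exact identity per draw.
Intervals are percentile intervals of the draws.

Percent mediated (`100·ACME/total`) is a ratio statistic: in a dataset
whose estimated total effect lands near zero the ratio explodes, and
such runs carry an `unstable` flag (total-effect CI spanning 0). When
the acceptance machinery averages recovery across 20 replicate cohorts
it therefore pools the ACME and total-effect estimates first and forms
the ratio of means, the standard stable summary for ratio quantities.

## The synthetic cohort generator

`cohort_spec()` defaults encode the trial the package emulates: two
groups of 55 and 64 smokers, a 261-message bank, 30 message-days inside
a 65-day window, Likert replies `clip(round(base + b_i + u_i·v_j +
δ·group + ε))` with base 3.95, a per-user rating-style intercept `b_i ~
N(0, 0.5)` (real raters differ systematically in leniency; without this
the mean-rating mediator has too little between-user variance to be
identifiable at n ≈ 120), planted rank-3 factors scaled so `sd(u·v) ≈
0.4`, group shift δ = 0.6 (≈ 0.4 after clipping attenuation, matching a
half-point observed gap), noise σ = 0.55, group-specific
rating-completion probabilities (0.9 vs 0.55) and website-visit rates
(5.5 vs 1.5), and a cessation outcome
`Bernoulli(logit⁻¹(α + β·group + γ·mean rating))` with
(α, β, γ) = (−3.444, 0.52, 0.72) — calibrated once against the
potential-outcome oracle so the true mediated fraction is ≈ 40% and
quit rates fall near 0.57/0.37, then frozen. Rounding to the Likert
grid happens after noise and before clipping, mimicking discrete
replies. A `regime = "cluster"` switch replaces the latent-factor
preferences with item-cluster preferences to probe recommender
robustness under misspecification. Ground truth (factors, biases, true
mean ratings, the spec) is emitted separately from the observables so
pipeline code cannot accidentally read it.

`true_mediation()` computes the ground-truth ACME/total/percent-mediated
by brute-force potential-outcome simulation: each simulated subject
keeps the same latent affinities, rating noise, and engagement draws
under both arms, so `M(1)` and `M(0)` are properly coupled; outcome
probabilities come straight from the spec's logistic model. At
`n_mc = 10⁶` the truth is stable to well under a tenth of a point
across oracle seeds.

**What the generator does not emulate.** Message text semantics; NRT
message avoidance dynamics; time trends within the window; missing
follow-up mechanisms beyond item-level missingness-at-random; and any
dependence of engagement on message content. Passing recovery tests
therefore show the estimators are correct under a realistic but
well-specified world; they do not validate the substantive model of any
particular trial's data.

**A known limitation the tests surface.** The group-dependent
engagement makes the mediator's variance arm-dependent (fewer averaged
replies → noisier mean), while the prescribed mediation analysis pools
the residual SD. Under the generator's conditions this produces a
modest bias in the estimated total effect at large n even though the
generator and oracle agree exactly; at the emulated n = 119 the pooled
20-cohort recovery stays within ±6 points of the truth. Arm-specific
mediator variances would remove this at the cost of departing from the
standard algorithm.

## Problem sizes

The test suite and acceptance script run recommender checks on planted
matrices of 20–40 users × 30–261 items with short Gibbs chains, the
mediation recovery on 20 cohorts of n = 119 with 500 Monte-Carlo draws
each, the oracle at 10⁵–10⁶ simulated subjects, and scheduler
personalization on 5 cohorts × 5 fresh users — sizes chosen so the whole
suite completes in a few minutes while every asserted property is
comfortably away from its noise floor.
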