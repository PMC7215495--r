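# Synthetic two-group messaging-trial cohorts with planted latent
# preference structure, group-dependent engagement, and a cessation
# outcome whose effect is partly mediated by the per-user mean rating.
# The generator is the test bed for every other module: its parameters
# are known, so recovery can be checked against ground truth.

TAG_VOCABULARY <- c("reasons-to-quit", "tips-strategies", "nrt",
                    "distraction-substitution", "support", "quit-date")

#' Specify a synthetic cohort
#'
#' Defaults emulate a two-group messaging trial: 55 + 64 participants, a
#' 261-message bank, up to 30 messages within a 65-day window, Likert
#' ratings around a base level of ~4 with an additive between-group shift,
#' group-dependent rating-completion probabilities and website-visit
#' rates, and a 30-day cessation outcome generated from a logistic model
#' on group and the user's mean rating. The outcome parameters default to
#' values calibrated (against [true_mediation()]) so that roughly 40% of
#' the group effect on cessation is transmitted through the ratings path
#' and the two arms quit at roughly 0.59 / 0.38.
#'
#' @param n_per_group named integer pair: users per group; the first group
#'   is the "treated" level (coded 1) in outcome and mediation models.
#' @param n_messages bank size (must cover the 30-message horizon).
#' @param latent_rank rank of the planted user/item factor structure.
#' @param base_rating intercept of the rating model, Likert units.
#' @param group_shift additive mean-rating gap of group 1 over group 2.
#' @param user_sd SD of the per-user rating-style intercept (systematic
#'   leniency/severity of a rater, shared across that user's ratings).
#' @param rating_noise SD of the per-message rating noise (before
#'   rounding/clipping).
#' @param engagement named per-group probability a sent message is rated.
#' @param visit_rate named per-group mean website visits (Poisson).
#' @param outcome_params `c(alpha, beta, gamma)`: logit intercept, direct
#'   group effect, and mean-rating effect on 30-day cessation.
#' @param horizon `c(messages, days)` window caps.
#' @param impact_missing probability an impact item is missing at
#'   follow-up.
#' @param regime `"latent"` (ratings follow the factor model the
#'   recommenders assume) or `"cluster"` (misspecified: item-cluster
#'   preferences) for robustness checks.
#' @param seed RNG seed; everything downstream is reproducible from it.
#' @return validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(african_american = 55, white = 64),
                        n_messages = 261,
                        latent_rank = 3,
                        base_rating = 3.95,
                        group_shift = 0.6,
                        user_sd = 0.5,
                        rating_noise = 0.55,
                        engagement = c(african_american = 0.9, white = 0.55),
                        visit_rate = c(african_american = 5.5, white = 1.5),
                        outcome_params = c(alpha = -3.444, beta = 0.52,
                                           gamma = 0.72),
                        horizon = c(messages = 30, days = 65),
                        impact_missing = 0.05,
                        regime = c("latent", "cluster"),
                        seed = 1) {
  regime <- match.arg(regime)
  if (length(n_per_group) != 2 || is.null(names(n_per_group))) {
    stop_invalid("n_per_group must be a named pair of group sizes")
  }
  if (n_messages < horizon[["messages"]]) {
    stop_invalid("n_messages (%d) must cover the %d-message horizon",
                 n_messages, horizon[["messages"]])
  }
  if (rating_noise <= 0) stop_invalid("rating_noise must be > 0")
  if (any(engagement < 0 | engagement > 1)) {
    stop_invalid("engagement probabilities must lie in [0, 1]")
  }
  groups <- names(n_per_group)
  engagement <- engagement[groups]; visit_rate <- visit_rate[groups]
  if (anyNA(engagement) || anyNA(visit_rate)) {
    stop_invalid("engagement and visit_rate must be named by group")
  }
  structure(list(n_per_group = n_per_group, n_messages = n_messages,
                 latent_rank = latent_rank, base_rating = base_rating,
                 group_shift = group_shift, user_sd = user_sd,
                 rating_noise = rating_noise,
                 engagement = engagement, visit_rate = visit_rate,
                 outcome_params = outcome_params, horizon = horizon,
                 impact_missing = impact_missing, regime = regime,
                 seed = seed),
            class = "cohort_spec")
}

factor_sd <- function(spec) {
  # su = sv chosen so sd(u.v) ~ 0.4 Likert units regardless of rank
  sqrt(0.4 / sqrt(spec$latent_rank))
}

likert <- function(x) pmin(pmax(round(x), 1), 5)

# Observed Likert replies given planted affinities, the rater's style
# intercept, the group shift and fresh noise; rounding happens after
# noise, clipping last (discrete replies).
observed_ratings <- function(spec, affinity, bias, g) {
  likert(spec$base_rating + bias + affinity + spec$group_shift * g +
           stats::rnorm(length(affinity), 0, spec$rating_noise))
}

#' Generate a synthetic cohort
#'
#' Draws planted user/item latent factors, schedules 30 random messages
#' per user on days 1..30 of the 65-day window, emits a rating for each
#' sent message with the group's engagement probability
#' (`rating = clip(round(base + u.v + shift*group + noise))`), website
#' visits (Poisson), seven impact items, and a cessation flag drawn from
#' `Bernoulli(plogis(alpha + beta*group + gamma*mean_rating))`. Ground
#' truth (factors, true per-user mean rating, the spec) is returned in a
#' separate `truth` element so pipeline code cannot accidentally consume
#' it.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `synthetic_cohort`: `profiles`, `bank`,
#'   `events`, `trial`, `truth`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- names(spec$n_per_group)
  n <- sum(spec$n_per_group)
  group <- rep(groups, spec$n_per_group)
  g <- as.numeric(group == groups[1])
  user_id <- sprintf("u%03d", seq_len(n))

  profiles <- user_profiles(data.frame(
    user_id = user_id,
    group = group,
    gender = sample(c("female", "male"), n, TRUE, prob = c(0.61, 0.39)),
    age_band = sample(AGE_BANDS, n, TRUE, prob = c(0.32, 0.26, 0.42)),
    education = sample(c("other", "advanced_degree"), n, TRUE,
                       prob = c(0.79, 0.21)),
    ethnicity = sample(c("not_hispanic", "hispanic"), n, TRUE,
                       prob = c(0.96, 0.04)),
    allow_smoking_home = stats::runif(n) <
      ifelse(g == 1, 0.65, 0.37),
    visited_cessation_site = stats::runif(n) < 0.16,
    past_year_quit_attempt = stats::runif(n) < 0.45,
    smoking_status = sample(c("not_actively_quitting", "actively_quitting"),
                            n, TRUE, prob = c(0.8, 0.2)),
    readiness = sample(READINESS_STAGES, n, TRUE,
                       prob = c(0.25, 0.45, 0.12, 0.05, 0.13)),
    stringsAsFactors = FALSE))

  m <- spec$n_messages
  bank <- message_bank(data.frame(
    message_id = sprintf("m%03d", seq_len(m)),
    text = sprintf("synthetic motivational message %03d", seq_len(m)),
    source = sample(c("expert", "peer"), m, TRUE, prob = c(0.6, 0.4)),
    tags = vapply(seq_len(m), function(i) {
      paste(sample(TAG_VOCABULARY, sample(1:2, 1)), collapse = ";")
    }, ""),
    stringsAsFactors = FALSE))

  sd_f <- factor_sd(spec)
  D <- spec$latent_rank
  U <- matrix(stats::rnorm(n * D, 0, sd_f), n, D, dimnames = list(user_id))
  V <- matrix(stats::rnorm(m * D, 0, sd_f), m, D,
              dimnames = list(bank$message_id))
  n_clusters <- 3
  item_cluster <- sample(n_clusters, m, TRUE)
  cluster_pref <- matrix(stats::rnorm(n * n_clusters, 0, 0.4), n, n_clusters)
  user_bias <- stats::rnorm(n, 0, spec$user_sd)

  n_send <- spec$horizon[["messages"]]
  events <- vector("list", n)
  mean_rating <- numeric(n)
  for (i in seq_len(n)) {
    sent <- sample(m, n_send)
    affinity <- if (spec$regime == "latent") {
      drop(V[sent, , drop = FALSE] %*% U[i, ])
    } else {
      cluster_pref[i, item_cluster[sent]]
    }
    values <- observed_ratings(spec, affinity, user_bias[i], g[i])
    rated <- stats::runif(n_send) < spec$engagement[[group[i]]]
    values[!rated] <- NA_real_
    events[[i]] <- data.frame(
      user_id = user_id[i], message_id = bank$message_id[sent],
      day_index = seq_len(n_send), value = values,
      stringsAsFactors = FALSE)
    mean_rating[i] <- if (any(rated)) mean(values[rated]) else
      spec$base_rating + user_bias[i] + spec$group_shift * g[i]
  }
  events <- do.call(rbind, events)

  op <- spec$outcome_params
  quit_p <- stats::plogis(op[["alpha"]] + op[["beta"]] * g +
                            op[["gamma"]] * mean_rating)
  quit <- stats::runif(n) < quit_p
  visits <- stats::rpois(n, spec$visit_rate[group])

  impact_base <- c(3.3, 3.5, 3.6, 3.4, 3.6, 3.2, 3.0)
  impact_shift <- c(0.35, 0.35, 0.35, 0.35, -0.5, 0.35, 0.35)
  impact <- sapply(1:7, function(j) {
    v <- likert(impact_base[j] + impact_shift[j] * g + stats::rnorm(n))
    v[stats::runif(n) < spec$impact_missing] <- NA_real_
    v
  })
  colnames(impact) <- paste0("impact_", 1:7)

  trial <- trial_records(data.frame(
    user_id = user_id, group = group, website_visits = visits,
    impact, quit_30day = quit, stringsAsFactors = FALSE))

  structure(list(
    profiles = profiles, bank = bank, events = events, trial = trial,
    truth = list(user_factors = U, item_factors = V,
                 item_cluster = item_cluster, user_bias = user_bias,
                 true_mean_rating = stats::setNames(mean_rating, user_id),
                 quit_probability = stats::setNames(quit_p, user_id),
                 spec = spec)),
    class = "synthetic_cohort")
}

#' Write the observable parts of a cohort to a directory
#'
#' Emits `messages.json`, `profiles.csv`, `ratings.csv`, `trial.csv`, and
#' the ground truth separately as `truth.json`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_message_bank(cohort$bank, file.path(dir, "messages.json"))
  write_profiles(cohort$profiles, file.path(dir, "profiles.csv"))
  write_ratings(cohort$events, file.path(dir, "ratings.csv"))
  write_trial(cohort$trial, file.path(dir, "trial.csv"))
  truth <- cohort$truth
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE, na = "null")
  invisible(dir)
}

#' Ground-truth mediation quantities of a cohort spec
#'
#' Brute-force potential-outcome simulation under the spec's known
#' generative model: for each simulated subject the potential mediator
#' values `M(1)` and `M(0)` share the same latent affinities, engagement
#' draws and rating noise and differ only through the group shift (and
#' through group-dependent engagement); outcome probabilities are read off
#' the spec's logistic model. Returns the true ACME, total effect (both on
#' the probability scale, averaged over arms) and percent mediated.
#'
#' @param spec a [cohort_spec()].
#' @param n_mc simulated subjects (>= 1e5).
#' @param seed RNG seed.
#' @return list `acme`, `ade`, `total`, `percent_mediated`, `n_mc`.
#' @export
true_mediation <- function(spec, n_mc = 1e5, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (n_mc < 1e5) stop_invalid("n_mc must be >= 1e5")
  op <- spec$outcome_params
  sd_f <- factor_sd(spec)
  D <- spec$latent_rank
  n_send <- spec$horizon[["messages"]]
  eng <- spec$engagement
  set.seed(seed)
  chunk <- 1e5
  sums <- c(acme = 0, ade = 0, total = 0)
  done <- 0
  while (done < n_mc) {
    nc <- min(chunk, n_mc - done)
    U <- matrix(stats::rnorm(nc * D, 0, sd_f), nc, D)
    bias <- stats::rnorm(nc, 0, spec$user_sd)
    M1_sum <- M0_sum <- numeric(nc)
    n1 <- n0 <- numeric(nc)
    for (j in seq_len(n_send)) {
      v <- matrix(stats::rnorm(nc * D, 0, sd_f), nc, D)
      aff <- bias + rowSums(U * v)
      eps <- stats::rnorm(nc, 0, spec$rating_noise)
      r1 <- likert(spec$base_rating + aff + spec$group_shift + eps)
      r0 <- likert(spec$base_rating + aff + eps)
      udraw <- stats::runif(nc)
      rated1 <- udraw < eng[[1]]
      rated0 <- udraw < eng[[2]]
      M1_sum <- M1_sum + r1 * rated1
      M0_sum <- M0_sum + r0 * rated0
      n1 <- n1 + rated1
      n0 <- n0 + rated0
    }
    M1 <- ifelse(n1 > 0, M1_sum / n1,
                 spec$base_rating + bias + spec$group_shift)
    M0 <- ifelse(n0 > 0, M0_sum / n0, spec$base_rating + bias)
    p <- function(t, mv) stats::plogis(op[["alpha"]] + op[["beta"]] * t +
                                         op[["gamma"]] * mv)
    p11 <- p(1, M1); p10 <- p(1, M0); p01 <- p(0, M1); p00 <- p(0, M0)
    sums["acme"] <- sums["acme"] + sum((p11 - p10) + (p01 - p00)) / 2
    sums["ade"] <- sums["ade"] + sum((p11 - p01) + (p10 - p00)) / 2
    sums["total"] <- sums["total"] + sum(p11 - p00)
    done <- done + nc
  }
  est <- sums / n_mc
  list(acme = unname(est["acme"]), ade = unname(est["ade"]),
       total = unname(est["total"]),
       percent_mediated = unname(100 * est["acme"] / est["total"]),
       n_mc = n_mc)
}
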