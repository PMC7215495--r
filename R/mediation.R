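# Quasi-Bayesian causal mediation for a continuous mediator and a binary
# outcome: linear mediator model, logistic outcome model, Monte-Carlo
# integration over the estimated sampling distribution of both parameter
# vectors and over simulated potential mediator values.

#' Causal mediation analysis (quasi-Bayesian Monte Carlo)
#'
#' Decomposes the total effect of a binary treatment on a binary outcome
#' into the part transmitted through a continuous mediator (ACME, the
#' average causal mediation effect, on the probability scale) and the
#' direct remainder (ADE). The algorithm:
#'
#' 1. Fit the mediator model `lm(mediator ~ treatment + covariates)` and
#'    the outcome model
#'    `glm(outcome ~ treatment + mediator + covariates, binomial)`.
#' 2. Draw `n_sims` parameter vectors from each model's asymptotic normal
#'    sampling distribution (residual SD of the mediator model held at
#'    its estimate).
#' 3. Per draw, simulate each subject's potential mediator values under
#'    treatment and control, `M(1)` and `M(0)`, including the residual
#'    error draw, then form outcome probabilities for the four
#'    treatment-by-mediator combinations `p(t, M(t'))`.
#' 4. `ACME(t) = mean[p(t, M(1)) - p(t, M(0))]`,
#'    `ADE(t') = mean[p(1, M(t')) - p(0, M(t'))]`, total effect
#'    `= mean[p(1, M(1)) - p(0, M(0))]`; ACME and ADE are averaged over
#'    the two treatment arms, which makes `ACME + ADE = total` an exact
#'    identity per draw.
#' 5. Point estimates are the means over draws; confidence intervals are
#'    percentile intervals of the draws. Percent mediated is
#'    `100 * ACME / total`; if the total-effect interval spans zero the
#'    ratio is unstable and is flagged.
#'
#' @param data data frame.
#' @param treatment name of the binary (0/1 or logical) treatment column.
#' @param mediator name of the continuous mediator column.
#' @param outcome name of the binary outcome column.
#' @param covariates character vector of covariate names.
#' @param n_sims Monte-Carlo draws (default 1000).
#' @param seed RNG seed.
#' @param conf_level confidence level for the percentile intervals.
#' @return object of class `mediation_result`: `acme`, `ade`,
#'   `total_effect`, `percent_mediated`, matching `ci` entries,
#'   `unstable` flag, `n_sims`, `n` (subjects used).
#' @export
mediation_analysis <- function(data, treatment, mediator, outcome,
                               covariates = character(), n_sims = 1000,
                               seed = 1, conf_level = 0.95) {
  cols <- c(treatment, mediator, outcome, covariates)
  use <- stats::complete.cases(data[, cols, drop = FALSE])
  d <- data[use, , drop = FALSE]
  d[[treatment]] <- as.numeric(d[[treatment]])
  d[[outcome]] <- as.numeric(d[[outcome]])
  n <- nrow(d)
  if (length(unique(d[[treatment]])) != 2) {
    stop_invalid("treatment must take exactly two values")
  }

  m_fml <- stats::reformulate(c(treatment, covariates), response = mediator)
  y_fml <- stats::reformulate(c(treatment, mediator, covariates),
                              response = outcome)
  m_fit <- stats::lm(m_fml, data = d)
  y_fit <- stats::glm(y_fml, data = d, family = stats::binomial())
  sigma_m <- summary(m_fit)$sigma

  set.seed(seed)
  m_draws <- MASS::mvrnorm(n_sims, stats::coef(m_fit), stats::vcov(m_fit))
  y_draws <- MASS::mvrnorm(n_sims, stats::coef(y_fit), stats::vcov(y_fit))

  # design matrices with the treatment column set to 1 / 0
  Xm1 <- Xm0 <- stats::model.matrix(m_fit)
  Xm1[, treatment] <- 1; Xm0[, treatment] <- 0
  Xy <- stats::model.matrix(y_fit)
  t_col <- match(treatment, colnames(Xy))
  m_col <- match(mediator, colnames(Xy))

  acme_d <- ade_d <- tot_d <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    eps <- stats::rnorm(n, 0, sigma_m)
    M1 <- drop(Xm1 %*% m_draws[s, ]) + eps
    M0 <- drop(Xm0 %*% m_draws[s, ]) + eps
    p <- function(t_val, m_val) {
      X <- Xy
      X[, t_col] <- t_val
      X[, m_col] <- m_val
      stats::plogis(drop(X %*% y_draws[s, ]))
    }
    p11 <- p(1, M1); p10 <- p(1, M0); p01 <- p(0, M1); p00 <- p(0, M0)
    acme_d[s] <- mean((p11 - p10) + (p01 - p00)) / 2
    ade_d[s] <- mean((p11 - p01) + (p10 - p00)) / 2
    tot_d[s] <- mean(p11 - p00)
  }
  alpha <- (1 - conf_level) / 2
  qs <- c(alpha, 1 - alpha)
  pct_d <- 100 * acme_d / tot_d
  tot_ci <- stats::quantile(tot_d, qs, names = FALSE)
  unstable <- tot_ci[1] <= 0 && tot_ci[2] >= 0
  if (unstable) {
    warning("total-effect CI spans 0: percent mediated is unstable")
  }
  res <- list(
    acme = mean(acme_d), ade = mean(ade_d), total_effect = mean(tot_d),
    percent_mediated = 100 * mean(acme_d) / mean(tot_d),
    ci = list(acme = stats::quantile(acme_d, qs, names = FALSE),
              ade = stats::quantile(ade_d, qs, names = FALSE),
              total_effect = tot_ci,
              percent_mediated = stats::quantile(pct_d, qs, names = FALSE)),
    unstable = unstable, n_sims = n_sims, n = n,
    mediator_model = m_fit, outcome_model = y_fit)
  class(res) <- "mediation_result"
  res
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "Causal mediation (quasi-Bayesian, %d sims, n=%d)\n  ACME  %8.4f [%.4f, %.4f]\n  ADE   %8.4f [%.4f, %.4f]\n  Total %8.4f [%.4f, %.4f]\n  Percent mediated %.1f%%%s\n",
    x$n_sims, x$n, x$acme, x$ci$acme[1], x$ci$acme[2],
    x$ade, x$ci$ade[1], x$ci$ade[2],
    x$total_effect, x$ci$total_effect[1], x$ci$total_effect[2],
    x$percent_mediated, if (x$unstable) " (unstable: total CI spans 0)" else ""))
  invisible(x)
}
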