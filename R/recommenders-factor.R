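# Latent-factor recommenders over the centered rating matrix:
#   PMF  — MAP estimate by alternating least squares (deterministic),
#   BPMF — Gibbs sampling under Gaussian-Wishart hyperpriors; predictions
#          average the user-item dot product over retained posterior draws.

clip_rating <- function(x) pmin(pmax(x, 1), 5)

als_solve_side <- function(S, Fixed, lambda) {
  # Solve one side of the ALS sweep: rows of S regressed on Fixed factors.
  D <- ncol(Fixed)
  out <- matrix(0, nrow(S), D)
  for (i in seq_len(nrow(S))) {
    obs <- which(!is.na(S[i, ]))
    if (!length(obs)) next
    Fo <- Fixed[obs, , drop = FALSE]
    A <- crossprod(Fo) + diag(lambda, D)
    out[i, ] <- solve(A, crossprod(Fo, S[i, obs]))
  }
  out
}

pmf_objective <- function(S, U, V, lambda_u, lambda_v) {
  E <- S - tcrossprod(U, V)
  sum(E^2, na.rm = TRUE) + lambda_u * sum(U^2) + lambda_v * sum(V^2)
}

#' Fit probabilistic matrix factorization (MAP, alternating least squares)
#'
#' Ratings are centered on the global mean; user and item factors minimise
#' the L2-regularized squared reconstruction error over observed cells.
#' ALS makes each sweep a pair of exact ridge solves, so the objective is
#' non-increasing and the fit is deterministic given `seed` (used only for
#' the random initialisation).
#'
#' @param matrix a [rating_matrix()].
#' @param rank latent dimension D (>= 1).
#' @param lambda_u,lambda_v ridge penalties (> 0) on user and item factors.
#' @param n_iter maximum ALS sweeps.
#' @param tol relative objective change declaring convergence.
#' @param seed RNG seed for initialisation.
#' @return object of class `pmf_model`; field `converged` is `FALSE` (with
#'   a warning) if `n_iter` sweeps did not reach `tol`.
#' @export
fit_pmf <- function(matrix, rank = 8, lambda_u = 0.1, lambda_v = 0.1,
                    n_iter = 100, tol = 1e-6, seed = 1) {
  stopifnot(inherits(matrix, "rating_matrix"))
  if (rank < 1) stop("rank must be >= 1", call. = FALSE)
  if (lambda_u <= 0 || lambda_v <= 0) stop("regularizers must be > 0", call. = FALSE)
  mu <- mean(matrix$R, na.rm = TRUE)
  S <- matrix$R - mu
  set.seed(seed)
  U <- matrix(stats::rnorm(nrow(S) * rank, sd = 0.1), nrow(S), rank)
  V <- matrix(stats::rnorm(ncol(S) * rank, sd = 0.1), ncol(S), rank)
  obj <- numeric(0)
  converged <- FALSE
  for (it in seq_len(n_iter)) {
    U <- als_solve_side(S, V, lambda_u)
    V <- als_solve_side(t(S), U, lambda_v)
    obj[it] <- pmf_objective(S, U, V, lambda_u, lambda_v)
    if (it > 1 && abs(obj[it - 1] - obj[it]) <=
          tol * max(abs(obj[it - 1]), 1e-12)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("PMF ALS did not converge in ", n_iter, " sweeps")
  rownames(U) <- matrix$users
  rownames(V) <- matrix$items
  structure(list(rank = rank, users = matrix$users, items = matrix$items,
                 U = U, V = V, global_mean = mu,
                 lambda_u = lambda_u, lambda_v = lambda_v,
                 objective = obj, converged = converged, seed = seed),
            class = "pmf_model")
}

# Gaussian-Wishart posterior update for one side's hyperparameters given the
# current factor matrix, followed by a draw of (mu, Lambda).
sample_hyper <- function(Fm, hp) {
  N <- nrow(Fm)
  D <- ncol(Fm)
  xbar <- colMeans(Fm)
  Sc <- crossprod(sweep(Fm, 2, xbar)) / N
  beta_star <- hp$beta0 + N
  nu_star <- hp$nu0 + N
  mu_star <- (hp$beta0 * hp$mu0 + N * xbar) / beta_star
  dm <- xbar - hp$mu0
  W_inv <- solve(hp$W0) + N * Sc +
    (hp$beta0 * N / beta_star) * tcrossprod(dm)
  W_star <- solve((W_inv + t(W_inv)) / 2)
  Lambda <- stats::rWishart(1, nu_star, W_star)[, , 1]
  mu <- MASS::mvrnorm(1, mu_star, solve(beta_star * Lambda))
  list(mu = mu, Lambda = Lambda)
}

# Draw factor rows conditional on the other side and the hyperparameters.
sample_factors <- function(S, Other, hp_draw, alpha) {
  D <- ncol(Other)
  out <- matrix(0, nrow(S), D)
  base <- hp_draw$Lambda %*% hp_draw$mu
  for (i in seq_len(nrow(S))) {
    obs <- which(!is.na(S[i, ]))
    if (length(obs)) {
      Oo <- Other[obs, , drop = FALSE]
      Prec <- hp_draw$Lambda + alpha * crossprod(Oo)
      mean_i <- solve(Prec, base + alpha * crossprod(Oo, S[i, obs]))
      out[i, ] <- MASS::mvrnorm(1, mean_i, solve(Prec))
    } else {
      # user/item with no ratings: sampled from the prior, by design
      out[i, ] <- MASS::mvrnorm(1, hp_draw$mu, solve(hp_draw$Lambda))
    }
  }
  out
}

#' Fit Bayesian probabilistic matrix factorization by Gibbs sampling
#'
#' Latent user and item factors get Gaussian priors whose means and
#' precision matrices themselves carry Gaussian-Wishart hyperpriors
#' (`mu0 = 0`, `beta0 = 2`, `nu0 = rank`, `W0 = I`); the sampler
#' alternates hyperparameter draws and conditional factor draws. Ratings
#' are centered on the global mean with fixed observation precision
#' `alpha`. A user or item with no observed ratings is sampled from its
#' prior rather than raising an error. Predictions later average the
#' user-item dot product over the retained posterior draws.
#'
#' @param matrix a [rating_matrix()].
#' @param rank latent dimension D.
#' @param n_burn burn-in Gibbs sweeps (discarded).
#' @param n_samples posterior draws retained after burn-in (>= 1).
#' @param alpha observation precision of the rating noise model.
#' @param seed RNG seed; the whole chain is reproducible from it.
#' @return object of class `bpmf_model` with `samples`, a list of draws
#'   each holding `U`, `V` and the user-side hyperparameter draw.
#' @export
fit_bpmf <- function(matrix, rank = 8, n_burn = 100, n_samples = 200,
                     alpha = 2, seed = 1) {
  stopifnot(inherits(matrix, "rating_matrix"))
  if (rank < 1) stop("rank must be >= 1", call. = FALSE)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  mu <- mean(matrix$R, na.rm = TRUE)
  S <- matrix$R - mu
  St <- t(S)
  D <- rank
  hp <- list(mu0 = rep(0, D), beta0 = 2, nu0 = D, W0 = diag(D))
  set.seed(seed)
  # short ALS warm start stabilises early sweeps
  U <- matrix(stats::rnorm(nrow(S) * D, sd = 0.1), nrow(S), D)
  V <- matrix(stats::rnorm(ncol(S) * D, sd = 0.1), ncol(S), D)
  for (it in 1:5) {
    U <- als_solve_side(S, V, 0.1)
    V <- als_solve_side(St, U, 0.1)
  }
  samples <- vector("list", n_samples)
  kept <- 0
  for (sweep_i in seq_len(n_burn + n_samples)) {
    hp_u <- sample_hyper(U, hp)
    hp_v <- sample_hyper(V, hp)
    U <- sample_factors(S, V, hp_u, alpha)
    V <- sample_factors(St, U, hp_v, alpha)
    if (sweep_i > n_burn) {
      kept <- kept + 1
      samples[[kept]] <- list(U = U, V = V, mu_u = hp_u$mu,
                              Lambda_u = hp_u$Lambda)
    }
  }
  structure(list(rank = rank, users = matrix$users, items = matrix$items,
                 samples = samples, global_mean = mu, alpha = alpha,
                 hyperprior = hp, n_burn = n_burn, n_samples = n_samples,
                 seed = seed),
            class = "bpmf_model")
}
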