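test_that("PMF recovers an exactly low-rank (centered) matrix", {
  # complete matrix whose centered form is exactly rank 1: mean-zero user
  # factor so the global mean equals the additive constant
  set.seed(11)
  a <- scale(rnorm(12), center = TRUE, scale = FALSE)[, 1]
  b <- runif(9, -0.5, 0.5)
  R <- 3.5 + outer(a, b)
  dimnames(R) <- list(sprintf("u%02d", 1:12), sprintf("m%02d", 1:9))
  mat <- structure(list(users = rownames(R), items = colnames(R), R = R),
                   class = "rating_matrix")
  fit <- suppressWarnings(fit_pmf(mat, rank = 1, lambda_u = 1e-8,
                                  lambda_v = 1e-8, n_iter = 200,
                                  tol = 1e-15, seed = 2))
  recon <- fit$global_mean + tcrossprod(fit$U, fit$V)
  expect_lt(rmse(as.vector(recon), as.vector(R)), 1e-6)
})

test_that("PMF objective is non-increasing and the fit is deterministic", {
  pm <- planted_matrix(20, 25, rank = 2, noise = 0.3, seed = 4)
  f1 <- suppressWarnings(fit_pmf(pm$matrix, rank = 2, n_iter = 30, seed = 9))
  f2 <- suppressWarnings(fit_pmf(pm$matrix, rank = 2, n_iter = 30, seed = 9))
  expect_identical(f1$U, f2$U)
  expect_identical(f1$V, f2$V)
  expect_true(all(diff(f1$objective) <= 1e-8))
  expect_error(fit_pmf(pm$matrix, rank = 0), "rank")
  expect_error(fit_pmf(pm$matrix, rank = 2, lambda_u = 0), "regularizers")
  # hitting the sweep cap warns and flags, never fails silently
  expect_warning(short <- fit_pmf(pm$matrix, rank = 2, n_iter = 2, seed = 1),
                 "converge")
  expect_false(short$converged)
})

test_that("huge regularization shrinks predictions to the global mean", {
  pm <- planted_matrix(15, 20, rank = 2, noise = 0.3, seed = 5)
  fit <- suppressWarnings(fit_pmf(pm$matrix, rank = 2, lambda_u = 1e8,
                                  lambda_v = 1e8, n_iter = 20, seed = 1))
  expect_lt(max(abs(fit$U)), 1e-3)
  pred <- fit$global_mean + tcrossprod(fit$U, fit$V)
  expect_equal(as.vector(pred), rep(fit$global_mean, length(pred)),
               tolerance = 1e-4)
})

test_that("BPMF recovers planted structure on held-out cells", {
  pm <- planted_matrix(30, 40, rank = 2, noise = 0.01, seed = 6)
  R_full <- pm$matrix$R
  set.seed(20)
  held <- which(matrix(runif(length(R_full)) < 0.2, nrow(R_full)))
  R_train <- R_full
  R_train[held] <- NA
  mat <- structure(list(users = pm$matrix$users, items = pm$matrix$items,
                        R = R_train), class = "rating_matrix")
  fit <- fit_bpmf(mat, rank = 2, n_burn = 30, n_samples = 40, seed = 3)
  # posterior mean reconstruction on the held-out cells
  recon <- Reduce(`+`, lapply(fit$samples, function(s) tcrossprod(s$U, s$V))) /
    length(fit$samples) + fit$global_mean
  expect_lt(rmse(recon[held], R_full[held]), 0.3)

  base_rmse <- rmse(rep(mean(R_train, na.rm = TRUE), length(held)),
                    R_full[held])
  expect_lt(rmse(recon[held], R_full[held]), base_rmse)
})

test_that("BPMF is reproducible and tolerates empty rows", {
  pm <- planted_matrix(10, 12, rank = 2, noise = 0.2, seed = 8)
  R <- pm$matrix$R
  R[3, ] <- NA  # user with zero ratings: drawn from the prior, not an error
  mat <- structure(list(users = pm$matrix$users, items = pm$matrix$items,
                        R = R), class = "rating_matrix")
  f1 <- fit_bpmf(mat, rank = 2, n_burn = 0, n_samples = 1, seed = 5)
  f2 <- fit_bpmf(mat, rank = 2, n_burn = 0, n_samples = 1, seed = 5)
  expect_identical(f1$samples[[1]]$U, f2$samples[[1]]$U)
  expect_identical(f1$samples[[1]]$V, f2$samples[[1]]$V)
  expect_true(all(is.finite(f1$samples[[1]]$U)))
  expect_error(fit_bpmf(mat, rank = 2, n_samples = 0), "n_samples")
})

test_that("BPMF held-out error is within 0.05 of PMF and both beat the mean", {
  res <- sapply(1:3, function(s) {
    pm <- planted_matrix(25, 30, rank = 3, noise = 0.25, seed = 100 + s)
    R_full <- pm$matrix$R
    set.seed(s)
    held <- which(matrix(runif(length(R_full)) < 0.2, nrow(R_full)))
    R_train <- R_full; R_train[held] <- NA
    mat <- structure(list(users = pm$matrix$users, items = pm$matrix$items,
                          R = R_train), class = "rating_matrix")
    pfit <- suppressWarnings(fit_pmf(mat, rank = 3, n_iter = 60, seed = s))
    # observation precision matched to the planted noise (1 / sigma^2)
    bfit <- fit_bpmf(mat, rank = 3, n_burn = 40, n_samples = 60,
                     alpha = 1 / 0.25^2, seed = s)
    p_recon <- pfit$global_mean + tcrossprod(pfit$U, pfit$V)
    b_recon <- Reduce(`+`, lapply(bfit$samples,
                                  function(x) tcrossprod(x$U, x$V))) /
      length(bfit$samples) + bfit$global_mean
    c(pmf = rmse(p_recon[held], R_full[held]),
      bpmf = rmse(b_recon[held], R_full[held]),
      base = rmse(rep(mean(R_train, na.rm = TRUE), length(held)),
                  R_full[held]))
  })
  means <- rowMeans(res)
  expect_lte(means["bpmf"], means["pmf"] + 0.05)
  expect_lt(means["bpmf"], means["base"])
  expect_lt(means["pmf"], means["base"])
})
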