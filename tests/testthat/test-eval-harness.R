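harness_matrix <- function(seed = 1) {
  # planted-factor Likert matrix, 25 ratings per user so all are eligible
  pm <- planted_matrix(20, 30, rank = 2, noise = 0.3, mu = 3.5,
                       density = 1, discrete = TRUE, seed = seed)
  R <- pm$matrix$R
  set.seed(seed + 1000)
  for (i in seq_len(nrow(R))) {
    R[i, sample(ncol(R), 5)] <- NA  # 25 observed per user
  }
  structure(list(users = pm$matrix$users, items = pm$matrix$items, R = R),
            class = "rating_matrix")
}

test_that("the harness evaluates cold-start users without touching test ratings", {
  mat <- harness_matrix()
  report <- suppressWarnings(run_strong_generalization(
    mat, methods = c("baseline", "pmf"), supports = c(5, 16), seed = 3,
    params = list(pmf = list(rank = 2, n_iter = 30))))
  expect_s3_class(report, "eval_report")
  expect_equal(nrow(report), 2 * 2 * 5)  # models x supports x folds
  expect_true(all(report$rmse >= 0))
  expect_true(all(report$ndcg >= 0 & report$ndcg <= 1))
  expect_true(all(report$tau_b >= -1 & report$tau_b <= 1, na.rm = TRUE))

  # leakage audit: test pairs never appear in fitting or support sets
  audit <- attr(report, "audit")
  expect_length(audit, 5)
  for (fold in audit) {
    fit_keys <- paste(fold$fit_pairs$user_id, fold$fit_pairs$message_id)
    for (u in names(fold$test_pairs)) {
      test_keys <- paste(u, fold$test_pairs[[u]])
      expect_length(intersect(test_keys, fit_keys), 0)
      sup <- fold$support_pairs[grep(paste0("^", u, " "),
                                     names(fold$support_pairs))]
      sup_keys <- paste(u, unlist(sup))
      expect_length(intersect(test_keys, sup_keys), 0)
    }
  }
})

test_that("grid search finds interior optima and extends endpoint ranges", {
  # 1-point grid: returned untouched
  one <- grid_search(function(p) p$k, grid = list(k = 7))
  expect_equal(one$best$k, 7)
  expect_equal(one$n_extensions, 0)

  # convex validation curve with an interior optimum
  quad <- grid_search(function(p) (p$lambda - 3)^2 + 1,
                      grid = list(lambda = c(1, 2, 3, 4, 5)))
  expect_equal(quad$best$lambda, 3)
  expect_equal(quad$n_extensions, 0)
  expect_false(quad$at_endpoint)

  # optimum at the right endpoint of (1, 2, 4): geometric extension to 8
  calls <- new.env(); calls$seen <- numeric(0)
  res <- grid_search(function(p) {
    calls$seen <- c(calls$seen, p$lambda)
    -p$lambda * (p$lambda < 10)  # improves until 8, worse at >= 10
  }, grid = list(lambda = c(1, 2, 4)), scale_params = "lambda")
  expect_true(8 %in% calls$seen)
  expect_equal(res$best$lambda, 8)
  expect_gte(res$n_extensions, 1)

  # monotone score exhausts extensions and warns
  expect_warning(
    mono <- grid_search(function(p) -p$k, grid = list(k = c(1, 2)),
                        max_extensions = 2),
    "end point")
  expect_true(mono$at_endpoint)
  expect_equal(mono$n_extensions, 2)
})

test_that("validation scorer refits on masked train ratings only", {
  mat <- harness_matrix(seed = 7)
  splits <- make_strong_gen_splits(mat, seed = 2)
  scorer <- validation_scorer(mat, splits[[1]], "pmf", seed = 1,
                              fixed = list(rank = 2, n_iter = 20))
  s1 <- suppressWarnings(scorer(list(lambda_u = 0.1, lambda_v = 0.1)))
  expect_true(is.finite(s1) && s1 > 0)
})

test_that("paired model comparison applies Bonferroni over all pairs", {
  base <- expand.grid(support = c(5, 16), fold = 1:5)
  rep3 <- rbind(
    cbind(base, model = "a", rmse = 1.00 + base$fold / 100),
    cbind(base, model = "b", rmse = 1.02 + base$fold / 90),
    cbind(base, model = "c", rmse = 1.00 + base$fold / 100))
  cmp <- compare_models(rep3, "rmse")
  expect_equal(nrow(cmp), 3)
  ab <- cmp[cmp$model_a == "a" & cmp$model_b == "b", ]
  # raw p times the 3 comparisons, capped at 1
  expect_equal(ab$p_bonferroni, min(1, ab$p_raw * 3))
  ac <- cmp[cmp$model_a == "a" & cmp$model_b == "c", ]
  expect_equal(ac$t, 0)
  expect_equal(ac$p_bonferroni, 1)

  # constant nonzero difference is degenerate
  rep2 <- rbind(cbind(base, model = "a", rmse = 1),
                cbind(base, model = "b", rmse = 1.3))
  cmp2 <- compare_models(rep2, "rmse")
  expect_true(is.na(cmp2$p_raw))
  expect_match(cmp2$note, "zero-variance")
})

test_that("support-level monotonicity: more support ratings, lower RMSE", {
  errs <- sapply(1:2, function(s) {
    mat <- harness_matrix(seed = 200 + s)
    report <- suppressWarnings(run_strong_generalization(
      mat, methods = "pmf", supports = c(5, 16), seed = s,
      params = list(pmf = list(rank = 2, n_iter = 30))))
    c(s5 = mean(report$rmse[report$support == 5]),
      s16 = mean(report$rmse[report$support == 16]))
  })
  means <- rowMeans(errs)
  expect_lte(means["s16"], means["s5"] + 0.02)
})
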