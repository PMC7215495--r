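# Strong-generalization evaluation runner, hyperparameter grid search with
# iterative range extension, and Bonferroni-corrected paired comparisons.

fit_method <- function(matrix, method, params, seed) {
  switch(method,
    knn = fit_knn(matrix, k = params$k %||% 20,
                  min_overlap = params$min_overlap %||% 2),
    pmf = fit_pmf(matrix, rank = params$rank %||% 8,
                  lambda_u = params$lambda_u %||% 0.1,
                  lambda_v = params$lambda_v %||% 0.1,
                  n_iter = params$n_iter %||% 60, seed = seed),
    bpmf = fit_bpmf(matrix, rank = params$rank %||% 8,
                    n_burn = params$n_burn %||% 100,
                    n_samples = params$n_samples %||% 200,
                    alpha = params$alpha %||% 2, seed = seed),
    baseline = structure(list(global_mean = mean(matrix$R, na.rm = TRUE),
                              items = matrix$items, users = matrix$users),
                         class = "baseline_model"),
    stop_invalid("unknown method: %s", method)
  )
}

#' @export
infer_user_factors.baseline_model <- function(model, ratings, seed = 1) {
  structure(list(method = "baseline", ratings = ratings), class = "user_view")
}

baseline_predict <- function(model, items) {
  stats::setNames(rep(clip_rating(model$global_mean), length(items)), items)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# NDCG of the 4-item test set: order test items by predicted value
# (descending, ties by ascending id), relevance = true rating at each rank.
ndcg_from_predictions <- function(pred, actual) {
  ord <- order(-pred, names(pred))
  ndcg(actual[ord])
}

#' Run the strong-generalization evaluation protocol
#'
#' For each fold: fit each model on the train users' ratings only; for each
#' test user and support level, infer user factors from the support ratings
#' alone ([infer_user_factors()], item-side parameters frozen) and predict
#' that user's held-out test ratings. RMSE pools all test predictions in
#' the fold; Kendall tau-b and NDCG are computed per test user over their
#' test set and averaged (users whose test ratings are entirely tied have
#' no defined tau and are skipped in the tau average).
#'
#' The returned report carries an `audit` attribute recording, per fold,
#' every (user, item) pair consumed by fitting and by cold-start inference
#' plus the test pairs, so leakage of test ratings is checkable after the
#' fact.
#'
#' @param matrix a [rating_matrix()].
#' @param methods subset of `c("baseline", "knn", "pmf", "bpmf")`.
#' @param supports support levels to evaluate (subset of the split's).
#' @param seed RNG seed (drives the splits and all model fits).
#' @param params named list of per-method hyperparameter lists, e.g.
#'   `list(bpmf = list(rank = 4, n_burn = 30, n_samples = 50))`.
#' @param splits optional precomputed [make_strong_gen_splits()] result.
#' @return data frame of class `eval_report` with one row per
#'   (model, support, fold) and columns `rmse`, `tau_b`, `ndcg`.
#' @export
run_strong_generalization <- function(matrix,
                                      methods = c("knn", "pmf", "bpmf"),
                                      supports = c(5, 10, 16),
                                      seed = 1, params = list(),
                                      splits = NULL) {
  if (is.null(splits)) {
    splits <- make_strong_gen_splits(matrix, seed = seed,
                                     support_sizes = supports)
  }
  rows <- list()
  audit <- list()
  for (split in splits) {
    f <- split$fold_id
    train_mat <- subset_matrix(matrix, split$train_users)
    obs <- which(!is.na(train_mat$R), arr.ind = TRUE)
    audit_fold <- list(
      fit_pairs = data.frame(
        user_id = train_mat$users[obs[, 1]],
        message_id = train_mat$items[obs[, 2]],
        stringsAsFactors = FALSE),
      support_pairs = list(), test_pairs = list())
    models <- lapply(stats::setNames(methods, methods), function(m) {
      fit_method(train_mat, m, params[[m]] %||% list(), seed = seed + f)
    })
    for (u in split$test_users) {
      info <- split$users[[u]]
      actual <- matrix$R[u, info$test_items]
      audit_fold$test_pairs[[u]] <- info$test_items
      for (s in as.character(supports)) {
        sup_items <- info$support[[s]]
        sup_ratings <- matrix$R[u, sup_items]
        audit_fold$support_pairs[[paste(u, s)]] <- sup_items
        for (m in methods) {
          view <- infer_user_factors(models[[m]], sup_ratings,
                                     seed = seed + f)
          pred <- if (m == "baseline") {
            baseline_predict(models[[m]], info$test_items)
          } else {
            predict_for_user(models[[m]], view, info$test_items)
          }
          rows[[length(rows) + 1]] <- data.frame(
            model = m, support = as.integer(s), fold = f, user_id = u,
            sq_err = mean((pred - actual)^2),
            tau_b = suppressWarnings(kendall_tau_b(pred, actual)),
            ndcg = ndcg_from_predictions(pred, actual),
            stringsAsFactors = FALSE)
        }
      }
    }
    audit[[f]] <- audit_fold
  }
  per_user <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(
    split(per_user, per_user[, c("model", "support", "fold")], drop = TRUE),
    function(d) data.frame(
      model = d$model[1], support = d$support[1], fold = d$fold[1],
      rmse = sqrt(mean(d$sq_err)),
      tau_b = mean(d$tau_b, na.rm = TRUE),
      ndcg = mean(d$ndcg),
      n_users = nrow(d), stringsAsFactors = FALSE)))
  agg <- agg[order(agg$model, agg$support, agg$fold), ]
  rownames(agg) <- NULL
  structure(agg, class = c("eval_report", "data.frame"),
            audit = audit, seed = seed, per_user = per_user)
}

#' Exhaustive grid search with iterative range extension
#'
#' Evaluates `score_fn` (lower is better; typically mean validation RMSE
#' over a split's validation partitions — see [validation_scorer()]) at
#' every point of the hyperparameter grid. If the selected value of any
#' hyperparameter with more than one candidate sits at an end point of its
#' search interval, that interval is extended in that direction —
#' geometrically for parameters named in `scale_params` (regularizers,
#' precisions), arithmetically otherwise (counts like `k` or rank) — and
#' the search repeats, up to `max_extensions` times. If extensions are
#' exhausted with the optimum still on an end point the best point is
#' returned with `at_endpoint = TRUE` and a warning.
#'
#' @param score_fn function taking a named list of hyperparameter values,
#'   returning a scalar score to minimise.
#' @param grid named list of sorted numeric candidate vectors.
#' @param scale_params names of parameters extended geometrically.
#' @param max_extensions maximum number of range extensions (default 3).
#' @return list with `best` (named list), `score`, `n_extensions`,
#'   `at_endpoint`, and the final `grid`.
#' @export
grid_search <- function(score_fn, grid, scale_params = character(),
                        max_extensions = 3) {
  stopifnot(length(grid) >= 1, all(lengths(grid) >= 1))
  grid <- lapply(grid, sort)
  cache <- new.env(parent = emptyenv())
  eval_point <- function(p) {
    key <- paste(names(p), vapply(p, format, "", digits = 15),
                 collapse = ";")
    if (is.null(cache[[key]])) cache[[key]] <- score_fn(p)
    cache[[key]]
  }
  extend <- function(values, side, geometric) {
    if (geometric) {
      ratio <- if (length(values) >= 2) {
        max(values[length(values)] / values[length(values) - 1], 1.5)
      } else 2
      if (side == "right") c(values, values[length(values)] * ratio)
      else c(values[1] / ratio, values)
    } else {
      step <- if (length(values) >= 2) {
        max(values[length(values)] - values[length(values) - 1], 1)
      } else 1
      if (side == "right") c(values, values[length(values)] + step)
      else c(max(values[1] - step, 1), values)
    }
  }
  n_ext <- 0
  repeat {
    combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
    scores <- apply(combos, 1, function(row) {
      eval_point(as.list(stats::setNames(as.numeric(row), names(grid))))
    })
    best_i <- which.min(scores)
    best <- as.list(stats::setNames(as.numeric(combos[best_i, ]),
                                    names(grid)))
    on_edge <- list()
    for (p in names(grid)) {
      v <- grid[[p]]
      if (length(v) < 2) next
      if (best[[p]] == v[1]) on_edge[[p]] <- "left"
      else if (best[[p]] == v[length(v)]) on_edge[[p]] <- "right"
    }
    if (!length(on_edge) || n_ext >= max_extensions) {
      if (length(on_edge)) {
        warning("grid search exhausted extensions with optimum on an end point")
      }
      return(list(best = best, score = scores[best_i], n_extensions = n_ext,
                  at_endpoint = length(on_edge) > 0, grid = grid))
    }
    for (p in names(on_edge)) {
      grid[[p]] <- extend(grid[[p]], on_edge[[p]],
                          geometric = p %in% scale_params)
    }
    n_ext <- n_ext + 1
  }
}

#' Validation scorer for hyperparameter search
#'
#' Returns a closure suitable as `score_fn` for [grid_search()]: given a
#' hyperparameter point it refits `method` on the fold's train users with
#' each validation partition's ratings masked out, predicts the held-out
#' cells, and returns the mean RMSE over the partitions.
#'
#' @param matrix full [rating_matrix()].
#' @param split one `strong_gen_split`.
#' @param method `"knn"`, `"pmf"` or `"bpmf"`.
#' @param seed RNG seed for the refits.
#' @param fixed named list of hyperparameters not being searched.
#' @export
validation_scorer <- function(matrix, split, method, seed = 1,
                              fixed = list()) {
  force(matrix); force(split); force(method); force(seed); force(fixed)
  function(params) {
    params <- utils::modifyList(fixed, params)
    errs <- vapply(split$validation, function(held) {
      train_mat <- subset_matrix(matrix, split$train_users, mask = held)
      model <- fit_method(train_mat, method, params, seed = seed)
      pred <- mapply(function(u, it) predict_rating(model, u, it),
                     held$user_id, held$message_id)
      actual <- matrix$R[cbind(match(held$user_id, matrix$users),
                               match(held$message_id, matrix$items))]
      rmse(pred, actual)
    }, numeric(1))
    mean(errs)
  }
}

#' Pairwise paired-t model comparison with Bonferroni correction
#'
#' Pairs fold-level metric values (matched on fold and support level) for
#' every pair of models in an [run_strong_generalization()] report, runs a
#' two-sided paired t test on the differences, and multiplies each raw p
#' by the number of pairwise comparisons (capped at 1). A pair with
#' zero-variance differences is degenerate: identical values give t = 0,
#' p = 1; a constant nonzero difference gives `p = NA` with a note.
#'
#' @param report an `eval_report`.
#' @param metric one of `"rmse"`, `"tau_b"`, `"ndcg"`.
#' @return data frame with one row per model pair: `t`, `p_raw`,
#'   `p_bonferroni`, `mean_diff`, `note`.
#' @export
compare_models <- function(report, metric = "rmse") {
  stopifnot(metric %in% c("rmse", "tau_b", "ndcg"))
  models <- sort(unique(report$model))
  if (length(models) < 2) stop("need >= 2 models to compare", call. = FALSE)
  pairs <- utils::combn(models, 2, simplify = FALSE)
  n_cmp <- length(pairs)
  out <- lapply(pairs, function(pr) {
    a <- report[report$model == pr[1], c("support", "fold", metric)]
    b <- report[report$model == pr[2], c("support", "fold", metric)]
    merged <- merge(a, b, by = c("support", "fold"))
    if (nrow(merged) != nrow(a) || nrow(merged) != nrow(b)) {
      stop_invalid("models %s and %s were evaluated on different folds",
                   pr[1], pr[2])
    }
    d <- merged[[paste0(metric, ".x")]] - merged[[paste0(metric, ".y")]]
    note <- ""
    if (stats::sd(d) == 0) {
      if (all(d == 0)) {
        tstat <- 0; p <- 1
      } else {
        tstat <- NA_real_; p <- NA_real_
        note <- "zero-variance nonzero difference; t undefined"
      }
    } else {
      tt <- stats::t.test(d)
      tstat <- unname(tt$statistic); p <- tt$p.value
    }
    data.frame(model_a = pr[1], model_b = pr[2], metric = metric,
               mean_diff = mean(d), t = tstat, p_raw = p,
               p_bonferroni = pmin(1, p * n_cmp), note = note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
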