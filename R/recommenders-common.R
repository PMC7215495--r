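# Shared recommender surface: cold-start user inference under frozen
# item-side parameters, prediction, ranking, and model checkpoints.

#' Infer user-specific parameters for an unseen user
#'
#' Implements the strong-generalization contract: all non-user-specific
#' parameters (item factors, hyperparameters, similarity structure of the
#' training users) are frozen — the call never modifies `model` — and only
#' the new user's parameters are estimated from the supplied ratings.
#'
#' * `pmf_model`: ridge solve of the user factor against the frozen item
#'   factors (the ALS user update).
#' * `bpmf_model`: one conditional Gaussian draw of the user factor per
#'   retained posterior sample, given that sample's item factors and
#'   user-side hyperparameter draw.
#' * `knn_model`: Pearson similarities of the new rating vector to each
#'   training user.
#'
#' An empty rating set falls back to the prior-mean factor (zero in the
#' centered parameterisation, so predictions equal the global mean) with a
#' warning.
#'
#' @param model a fitted `pmf_model`, `bpmf_model` or `knn_model`.
#' @param ratings named numeric vector: names are message ids, values 1..5.
#' @param seed RNG seed (used by the BPMF conditional draws).
#' @return object of class `user_view` holding the inferred user-side
#'   parameters plus the ratings it was inferred from.
#' @export
infer_user_factors <- function(model, ratings, seed = 1) {
  UseMethod("infer_user_factors")
}

check_cold_ratings <- function(model, ratings) {
  if (length(ratings) == 0) {
    warning("empty rating set: falling back to prior mean factor")
    return(ratings)
  }
  unknown <- setdiff(names(ratings), model$items)
  if (length(unknown)) {
    stop_invalid("ratings reference unknown message_id(s): %s",
                 paste(unknown, collapse = ", "))
  }
  if (any(ratings < 1 | ratings > 5)) {
    stop_invalid("cold-start ratings outside 1..5")
  }
  ratings
}

#' @export
infer_user_factors.pmf_model <- function(model, ratings, seed = 1) {
  ratings <- check_cold_ratings(model, ratings)
  if (length(ratings) == 0) {
    u <- rep(0, model$rank)
  } else {
    idx <- match(names(ratings), model$items)
    Vo <- model$V[idx, , drop = FALSE]
    A <- crossprod(Vo) + diag(model$lambda_u, model$rank)
    u <- drop(solve(A, crossprod(Vo, ratings - model$global_mean)))
  }
  structure(list(method = "pmf", factors = u, ratings = ratings),
            class = "user_view")
}

#' @export
infer_user_factors.bpmf_model <- function(model, ratings, seed = 1) {
  ratings <- check_cold_ratings(model, ratings)
  D <- model$rank
  n_s <- length(model$samples)
  Udraws <- matrix(0, n_s, D)
  if (length(ratings) > 0) {
    idx <- match(names(ratings), model$items)
    s <- ratings - model$global_mean
    set.seed(seed)
    for (k in seq_len(n_s)) {
      smp <- model$samples[[k]]
      Vo <- smp$V[idx, , drop = FALSE]
      Prec <- smp$Lambda_u + model$alpha * crossprod(Vo)
      mean_k <- solve(Prec, smp$Lambda_u %*% smp$mu_u +
                        model$alpha * crossprod(Vo, s))
      Udraws[k, ] <- MASS::mvrnorm(1, mean_k, solve(Prec))
    }
  }
  structure(list(method = "bpmf", factors = Udraws, ratings = ratings),
            class = "user_view")
}

#' @export
infer_user_factors.knn_model <- function(model, ratings, seed = 1) {
  ratings <- check_cold_ratings(model, ratings)
  sims <- if (length(ratings)) knn_new_user_sims(model, ratings)
          else numeric(length(model$users))
  user_mean <- if (length(ratings)) mean(ratings) else model$global_mean
  structure(list(method = "knn", sims = sims, user_mean = user_mean,
                 ratings = ratings),
            class = "user_view")
}

#' Predict ratings for a cold-start user view
#'
#' For factor models the prediction is the expected value of the product of
#' the latent user and item factor vectors (for BPMF, averaged over the
#' posterior draws) plus the global mean, clipped to the 1..5 Likert range.
#'
#' @param model the fitted model the view was inferred from.
#' @param view a `user_view` from [infer_user_factors()].
#' @param items message ids to predict.
#' @return named numeric vector of predictions in `[1, 5]`.
#' @export
predict_for_user <- function(model, view, items) {
  stopifnot(inherits(view, "user_view"))
  unknown <- setdiff(items, model$items)
  if (length(unknown)) {
    stop_invalid("unknown message_id(s): %s", paste(unknown, collapse = ", "))
  }
  idx <- match(items, model$items)
  pred <- switch(view$method,
    pmf = model$global_mean +
      drop(model$V[idx, , drop = FALSE] %*% view$factors),
    bpmf = {
      acc <- numeric(length(items))
      for (k in seq_along(model$samples)) {
        acc <- acc + drop(model$samples[[k]]$V[idx, , drop = FALSE] %*%
                            view$factors[k, ])
      }
      model$global_mean + acc / length(model$samples)
    },
    knn = vapply(items, function(it) {
      knn_predict_core(model, view$sims, view$user_mean, it)
    }, numeric(1)),
    stop("unknown view method")
  )
  stats::setNames(clip_rating(pred), items)
}

#' Predict the rating of a training user for an item
#'
#' @param model fitted model.
#' @param user a training user id.
#' @param item a message id.
#' @return predicted rating in `[1, 5]`.
#' @export
predict_rating <- function(model, user, item) {
  UseMethod("predict_rating")
}

#' @export
predict_rating.knn_model <- function(model, user, item) {
  predict_knn(model, user, item)
}

#' @export
predict_rating.pmf_model <- function(model, user, item) {
  i <- match(user, model$users); j <- match(item, model$items)
  if (is.na(i)) stop_invalid("unknown user_id: %s", user)
  if (is.na(j)) stop_invalid("unknown message_id: %s", item)
  clip_rating(model$global_mean + sum(model$U[i, ] * model$V[j, ]))
}

#' @export
predict_rating.bpmf_model <- function(model, user, item) {
  i <- match(user, model$users); j <- match(item, model$items)
  if (is.na(i)) stop_invalid("unknown user_id: %s", user)
  if (is.na(j)) stop_invalid("unknown message_id: %s", item)
  dots <- vapply(model$samples,
                 function(s) sum(s$U[i, ] * s$V[j, ]), numeric(1))
  clip_rating(model$global_mean + mean(dots))
}

#' Rank candidate messages for a user view
#'
#' Candidates are sorted by predicted rating, descending; ties are broken
#' by ascending message id so the ordering is a deterministic total order
#' for a fixed model.
#'
#' @param model fitted model.
#' @param view a `user_view`.
#' @param candidates message ids to rank.
#' @return data frame with `message_id` and `predicted` in rank order.
#' @export
rank_messages <- function(model, view, candidates) {
  if (!length(candidates)) {
    return(data.frame(message_id = character(0), predicted = numeric(0)))
  }
  pred <- predict_for_user(model, view, candidates)
  ord <- order(-pred, candidates)
  data.frame(message_id = candidates[ord], predicted = unname(pred[ord]),
             stringsAsFactors = FALSE)
}

#' Save / load a model checkpoint
#'
#' JSON checkpoint carrying rank, factor matrices, hyperparameters, seed
#' and sample count — enough to reload the model and reproduce its
#' predictions.
#'
#' @param model a `pmf_model`, `bpmf_model` or `knn_model`.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  payload <- unclass(model)
  payload$.class <- class(model)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  cls <- raw$.class
  raw$.class <- NULL
  as_mat <- function(x) {
    if (is.matrix(x)) x
    else matrix(unlist(x), nrow = length(x), byrow = TRUE)
  }
  fix_named <- function(x, nm) {
    x <- as.numeric(x); names(x) <- nm; x
  }
  if (identical(cls, "bpmf_model")) {
    raw$samples <- lapply(raw$samples, function(s) {
      list(U = as_mat(s$U), V = as_mat(s$V), mu_u = as.numeric(s$mu_u),
           Lambda_u = as_mat(s$Lambda_u))
    })
    raw$hyperprior$W0 <- as_mat(raw$hyperprior$W0)
  }
  for (fld in c("U", "V", "R", "similarity")) {
    if (!is.null(raw[[fld]])) raw[[fld]] <- as_mat(raw[[fld]])
  }
  if (identical(cls, "knn_model")) {
    dimnames(raw$R) <- list(raw$users, raw$items)
    dimnames(raw$similarity) <- list(raw$users, raw$users)
    raw$user_means <- fix_named(raw$user_means, raw$users)
    raw$item_means <- fix_named(raw$item_means, raw$items)
  }
  structure(raw, class = cls)
}
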