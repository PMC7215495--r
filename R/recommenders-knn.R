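# User-based k-nearest-neighbour collaborative filtering: Pearson similarity
# over co-rated items, mean-centered weighted prediction.

#' Fit a user-based kNN rating model
#'
#' Pairwise user similarity is the Pearson correlation computed over the
#' items both users rated; pairs with fewer than `min_overlap` co-rated
#' items (or a degenerate constant overlap) get similarity 0 by convention.
#'
#' @param matrix a [rating_matrix()] with at least 2 users.
#' @param k number of neighbours used at prediction time (capped at
#'   number of users - 1).
#' @param min_overlap minimum number of co-rated items for a nonzero
#'   similarity (default 2).
#' @return object of class `knn_model`.
#' @export
fit_knn <- function(matrix, k = 20, min_overlap = 2) {
  stopifnot(inherits(matrix, "rating_matrix"))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  R <- matrix$R
  n <- nrow(R)
  if (n < 2) stop("kNN needs at least 2 users", call. = FALSE)
  sim <- diag(1, n)
  dimnames(sim) <- list(matrix$users, matrix$users)
  for (i in seq_len(n - 1)) {
    ri <- R[i, ]
    for (j in (i + 1):n) {
      co <- which(!is.na(ri) & !is.na(R[j, ]))
      s <- 0
      if (length(co) >= min_overlap) {
        a <- ri[co]; b <- R[j, co]
        if (stats::sd(a) > 0 && stats::sd(b) > 0) {
          s <- stats::cor(a, b)
        }
      }
      sim[i, j] <- sim[j, i] <- s
    }
  }
  structure(list(
    k = min(k, n - 1L),
    min_overlap = min_overlap,
    users = matrix$users,
    items = matrix$items,
    R = R,
    similarity = sim,
    user_means = rowMeans(R, na.rm = TRUE),
    item_means = colMeans(R, na.rm = TRUE),
    global_mean = mean(R, na.rm = TRUE)
  ), class = "knn_model")
}

# Core neighbourhood prediction given a centered query: user_mean plus the
# similarity-weighted average of neighbours' mean-centered ratings of the
# item, over the k most similar users who rated it. Fallbacks: item mean,
# then global mean. Always clipped to the Likert range.
knn_predict_core <- function(model, sims, user_mean, item) {
  j <- match(item, model$items)
  if (is.na(j)) stop_invalid("unknown message_id: %s", item)
  raters <- which(!is.na(model$R[, j]) & sims != 0)
  if (length(raters)) {
    ord <- raters[order(-abs(sims[raters]))]
    nb <- ord[seq_len(min(model$k, length(ord)))]
    w <- sims[nb]
    dev <- model$R[nb, j] - model$user_means[nb]
    pred <- user_mean + sum(w * dev) / sum(abs(w))
  } else if (!is.nan(model$item_means[j])) {
    pred <- model$item_means[j]
  } else {
    pred <- model$global_mean
  }
  clip_rating(pred)
}

#' Predict a rating with a fitted kNN model
#'
#' @param model a `knn_model`.
#' @param user a training user id.
#' @param item a message id.
#' @return predicted rating in `[1, 5]`.
#' @export
predict_knn <- function(model, user, item) {
  i <- match(user, model$users)
  if (is.na(i)) stop_invalid("unknown user_id: %s", user)
  sims <- model$similarity[i, ]
  sims[i] <- 0  # never one's own neighbour
  knn_predict_core(model, sims, model$user_means[i], item)
}

# Pearson similarity of an unseen user's rating vector against each
# training user, same overlap convention as fit_knn.
knn_new_user_sims <- function(model, ratings) {
  sims <- numeric(length(model$users))
  idx <- match(names(ratings), model$items)
  for (u in seq_along(model$users)) {
    ru <- model$R[u, idx]
    co <- which(!is.na(ru))
    if (length(co) >= model$min_overlap) {
      a <- ratings[co]; b <- ru[co]
      if (stats::sd(a) > 0 && stats::sd(b) > 0) sims[u] <- stats::cor(a, b)
    }
  }
  sims
}
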