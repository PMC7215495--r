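# Strong-generalization splits: test users are completely disjoint from
# train users; each test user contributes nested support sets (default
# 5 / 10 / 16 ratings) for cold-start inference and a constant set of 4
# test ratings.

#' Build strong-generalization cross-validation splits
#'
#' Users with at least `max(support_sizes) + n_test` observed ratings
#' (20 under the defaults — the minimum that can supply the largest
#' support set plus the held-out test set) are eligible as test users and
#' are divided into `n_folds` user folds. Within each fold every test
#' user's rated items are shuffled once: the first `n_test` become the
#' test set and the support sets are nested prefixes
#' (5 within 10 within 16) of the remainder. Users below the eligibility
#' threshold only ever serve as train users. Each fold additionally
#' carries `n_val` validation partitions over the train users, each
#' holding out `val_frac` of every train user's ratings for
#' hyperparameter selection. Deterministic given `seed`.
#'
#' @param matrix a [rating_matrix()].
#' @param seed RNG seed.
#' @param n_folds number of user folds (default 5).
#' @param support_sizes nested support-set sizes (default `c(5, 10, 16)`).
#' @param n_test held-out test ratings per test user (default 4).
#' @param n_val validation partitions per fold (default 3).
#' @param val_frac fraction of each train user's ratings held out per
#'   validation partition (default 0.1).
#' @return list of `strong_gen_split` objects, one per fold, each with
#'   `fold_id`, `train_users`, `test_users`, per-user `support` (named
#'   list by size) and `test_items`, and `validation` (list of data frames
#'   of held-out user/message pairs).
#' @export
make_strong_gen_splits <- function(matrix, seed = 1, n_folds = 5,
                                   support_sizes = c(5, 10, 16),
                                   n_test = 4, n_val = 3, val_frac = 0.1) {
  stopifnot(inherits(matrix, "rating_matrix"))
  support_sizes <- sort(support_sizes)
  need <- max(support_sizes) + n_test
  counts <- rowSums(!is.na(matrix$R))
  eligible <- matrix$users[counts >= need]
  if (length(eligible) < n_folds) {
    stop_invalid(paste0(
      "only %d users have >= %d ratings (%d support + %d test) but %d ",
      "folds of test users are required"),
      length(eligible), need, max(support_sizes), n_test, n_folds)
  }
  set.seed(seed)
  shuffled <- sample(eligible)
  fold_of <- rep(seq_len(n_folds), length.out = length(shuffled))
  lapply(seq_len(n_folds), function(f) {
    test_users <- sort(shuffled[fold_of == f])
    train_users <- setdiff(matrix$users, test_users)
    per_user <- lapply(test_users, function(u) {
      rated <- sample(matrix$items[!is.na(matrix$R[u, ])])
      test_items <- rated[seq_len(n_test)]
      pool <- rated[-seq_len(n_test)]
      support <- lapply(support_sizes, function(s) pool[seq_len(s)])
      names(support) <- as.character(support_sizes)
      list(test_items = test_items, support = support)
    })
    names(per_user) <- test_users
    validation <- lapply(seq_len(n_val), function(v) {
      held <- lapply(train_users, function(u) {
        rated <- matrix$items[!is.na(matrix$R[u, ])]
        n_hold <- max(1L, floor(val_frac * length(rated)))
        if (length(rated) - n_hold < 1L) return(NULL)
        data.frame(user_id = u,
                   message_id = sample(rated, n_hold),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, held)
    })
    structure(list(fold_id = f, train_users = train_users,
                   test_users = test_users, users = per_user,
                   support_sizes = support_sizes, n_test = n_test,
                   validation = validation),
              class = "strong_gen_split")
  })
}

subset_matrix <- function(matrix, users, mask = NULL) {
  R <- matrix$R[users, , drop = FALSE]
  if (!is.null(mask) && nrow(mask)) {
    R[cbind(match(mask$user_id, users), match(mask$message_id, matrix$items))] <- NA
  }
  structure(list(users = users, items = matrix$items, R = R),
            class = "rating_matrix")
}
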