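# Fixtures built in code: tiny event tables and planted-factor rating
# matrices shared across test files.

small_events <- function() {
  data.frame(
    user_id = c("u1", "u1", "u1", "u2", "u2", "u3", "u3"),
    message_id = c("m1", "m2", "m3", "m1", "m4", "m2", "m4"),
    day_index = c(1L, 2L, 3L, 1L, 2L, 1L, 2L),
    value = c(4, 5, 3, 4, 2, 5, 1),
    stringsAsFactors = FALSE)
}

# Complete or sparsified rating matrix with planted latent structure:
# R = mu + U V' + noise, rounded/clipped to the Likert grid optionally.
planted_matrix <- function(n_users = 30, n_items = 40, rank = 3,
                           noise = 0.25, mu = 3.5, density = 1,
                           discrete = FALSE, seed = 1,
                           factor_sd = 0.45) {
  set.seed(seed)
  U <- matrix(rnorm(n_users * rank, 0, factor_sd), n_users, rank)
  V <- matrix(rnorm(n_items * rank, 0, factor_sd), n_items, rank)
  R <- mu + tcrossprod(U, V) + matrix(rnorm(n_users * n_items, 0, noise),
                                      n_users, n_items)
  if (discrete) R <- pmin(pmax(round(R), 1), 5)
  users <- sprintf("u%02d", seq_len(n_users))
  items <- sprintf("m%02d", seq_len(n_items))
  if (density < 1) {
    drop_mask <- matrix(runif(n_users * n_items) > density, n_users, n_items)
    R[drop_mask] <- NA
  }
  dimnames(R) <- list(users, items)
  mat <- structure(list(users = users, items = items, R = R),
                   class = "rating_matrix")
  list(matrix = mat, U = U, V = V, mu = mu)
}

events_from_matrix <- function(mat) {
  obs <- which(!is.na(mat$R), arr.ind = TRUE)
  ord <- order(obs[, 1], obs[, 2])
  obs <- obs[ord, , drop = FALSE]
  day <- stats::ave(obs[, 1], obs[, 1], FUN = seq_along)
  data.frame(user_id = mat$users[obs[, 1]],
             message_id = mat$items[obs[, 2]],
             day_index = as.integer(day),
             value = mat$R[obs],
             stringsAsFactors = FALSE)
}

# Independent brute-force tau-b oracle: explicit loop over all pairs.
tau_b_oracle <- function(x, y) {
  n <- length(x)
  C <- D <- n1 <- n2 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0) n1 <- n1 + 1
    if (dy == 0) n2 <- n2 + 1
    if (dx * dy > 0) C <- C + 1
    if (dx * dy < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) return(NA_real_)
  (C - D) / denom
}

# Scheduler personalization probe: fit a recommender on a planted-factor
# training cohort, then simulate fresh daily-rating users with noisy
# Likert replies and return the true-rating gap between the late
# (days 21-30) and early (days 1-10) send windows.
gaps_for_seed <- function(s, n_users = 7, n_train = 40, n_items = 261,
                          rank = 3, base = 3.95, noise = 0.55) {
  sd_f <- sqrt(0.4 / sqrt(rank))
  set.seed(300 + s)
  U <- matrix(rnorm(n_train * rank, 0, sd_f), n_train, rank)
  V <- matrix(rnorm(n_items * rank, 0, sd_f), n_items, rank)
  R <- pmin(pmax(round(base + tcrossprod(U, V) +
                         matrix(rnorm(n_train * n_items, 0, noise),
                                n_train, n_items)), 1), 5)
  users <- sprintf("u%02d", seq_len(n_train))
  items <- sprintf("m%03d", seq_len(n_items))
  dimnames(R) <- list(users, items)
  mat <- structure(list(users = users, items = items, R = R),
                   class = "rating_matrix")
  model <- suppressWarnings(fit_pmf(mat, rank = rank, n_iter = 40, seed = s))
  bank <- message_bank(data.frame(message_id = items, text = "m",
                                  source = "expert",
                                  stringsAsFactors = FALSE))
  sapply(seq_len(n_users), function(ui) {
    set.seed(5000 * s + ui)
    u_true <- rnorm(rank, 0, sd_f)
    true_fn <- function(id) {
      j <- match(id, items)
      min(max(base + sum(u_true * V[j, ]), 1), 5)
    }
    log <- simulate_user_schedule(model, bank, true_fn, rate_prob = 1,
                                  reply_noise = noise, seed = ui)
    tr <- vapply(log$message_id, true_fn, numeric(1))
    mean(tr[log$day_index %in% 21:30]) - mean(tr[log$day_index %in% 1:10])
  })
}

# Independent NDCG oracle: literal formula evaluation.
ndcg_oracle <- function(rel_predicted_order, rel_ideal_order) {
  dcg <- function(r) sum((2^r - 1) / log2(seq_along(r) + 1))
  dcg(rel_predicted_order) / dcg(rel_ideal_order)
}
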