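# Rating-prediction and ranking metrics.

#' Root mean squared error
#'
#' @param predicted,actual equal-length nonempty numeric vectors.
#' @return `sqrt(mean((predicted - actual)^2))`.
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length", call. = FALSE)
  }
  if (!length(predicted)) stop("empty vectors", call. = FALSE)
  sqrt(mean((predicted - actual)^2))
}

#' Kendall's tau-b rank correlation
#'
#' Tau with the tie correction:
#' `(C - D) / sqrt((n0 - n1) (n0 - n2))` where `C`/`D` count concordant and
#' discordant pairs, `n0 = n(n-1)/2`, and `n1`, `n2` are the tied-pair
#' counts within `x` and `y`. When either vector is entirely tied the
#' coefficient is undefined: returns `NA` with a warning.
#'
#' @param x,y equal-length numeric vectors, `n >= 2`.
#' @return tau-b in `[-1, 1]`, or `NA` for an all-tied input.
#' @export
kendall_tau_b <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  up <- upper.tri(sx)
  conc <- sum(sx[up] * sy[up])          # C - D
  n0 <- n * (n - 1) / 2
  tie_pairs <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n1 <- tie_pairs(x); n2 <- tie_pairs(y)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) {
    warning("tau-b undefined: a vector is entirely tied")
    return(NA_real_)
  }
  conc / denom
}

#' Normalized discounted cumulative gain
#'
#' `DCG = sum((2^rel - 1) / log2(rank + 1))` over the predicted ordering,
#' normalized by the DCG of the ideal (descending-relevance) ordering.
#' Relevance here is the true rating of the item placed at each predicted
#' rank.
#'
#' @param ranked_relevances true relevances in predicted rank order.
#' @param ideal_relevances relevances in ideal order; defaults to
#'   `sort(ranked_relevances, decreasing = TRUE)`.
#' @param cutoff optional rank cutoff (NDCG@k).
#' @return NDCG in `[0, 1]`.
#' @export
ndcg <- function(ranked_relevances, ideal_relevances = NULL, cutoff = NULL) {
  if (!length(ranked_relevances)) stop("empty relevance list", call. = FALSE)
  if (is.null(ideal_relevances)) {
    ideal_relevances <- sort(ranked_relevances, decreasing = TRUE)
  }
  dcg <- function(rel) {
    if (!is.null(cutoff)) rel <- rel[seq_len(min(cutoff, length(rel)))]
    sum((2^rel - 1) / log2(seq_along(rel) + 1))
  }
  ideal <- dcg(ideal_relevances)
  if (ideal == 0) return(1)  # all-zero relevance: any order is ideal
  dcg(ranked_relevances) / ideal
}
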