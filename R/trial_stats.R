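# Trial analysis chain: daily group rating means and comparisons,
# dichotomized impact items, contingency-table tests, odds ratios, trend
# tests, and logistic outcome models.

#' Daily mean ratings by group
#'
#' The daily rating for a group is the mean of the ratings provided by all
#' its members that day; sent-but-unrated messages contribute nothing. A
#' day with no ratings in a group is reported as missing (`NA`), never 0.
#'
#' @param events rating-event data frame
#'   (`user_id`, `message_id`, `day_index`, `value`).
#' @param roster `user_profiles` (or data frame with `user_id`, `group`).
#' @param days day range to cover (default `1:30`).
#' @return data frame of class `daily_rating_series`: `group`,
#'   `day_index`, `mean_rating`, `n`.
#' @export
daily_group_means <- function(events, roster, days = 1:30) {
  events <- validate_events(events, roster = roster)
  events$group <- roster$group[match(events$user_id, roster$user_id)]
  rated <- events[!is.na(events$value), ]
  groups <- sort(unique(roster$group))
  out <- expand.grid(group = groups, day_index = days,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(rated$group, rated$day_index)
  means <- tapply(rated$value, key, mean)
  ns <- tapply(rated$value, key, length)
  k <- paste(out$group, out$day_index)
  out$mean_rating <- as.numeric(means[k])
  out$n <- as.integer(ns[k])
  out$n[is.na(out$n)] <- 0L
  out <- out[order(out$group, out$day_index), ]
  rownames(out) <- NULL
  structure(out, class = c("daily_rating_series", "data.frame"))
}

#' Compare two groups' daily rating series
#'
#' Counts the days on which group A's daily mean exceeds group B's,
#' reports each group's proportion of days with a daily mean of at least 4
#' (agree / strongly agree), and runs a two-sample t test on the paired
#' sets of daily means (pooled-variance by default, Welch optionally).
#'
#' @param series a `daily_rating_series` covering both groups.
#' @param group_a,group_b group labels; both must cover the same days.
#' @param var_equal pooled-variance t (default `TRUE`).
#' @return list: `days_a_higher`, `days_b_higher`, `prop_days_ge4` (named
#'   by group), `t`, `p`, `df`, `n_days`.
#' @export
compare_daily_ratings <- function(series, group_a, group_b,
                                  var_equal = TRUE) {
  a <- series[series$group == group_a, ]
  b <- series[series$group == group_b, ]
  if (!nrow(a) || !nrow(b)) stop_invalid("group not present in series")
  if (!identical(a$day_index, b$day_index)) {
    stop_invalid("groups cover different day ranges")
  }
  ok <- !is.na(a$mean_rating) & !is.na(b$mean_rating)
  ma <- a$mean_rating[ok]; mb <- b$mean_rating[ok]
  tt <- if (stats::sd(ma) == 0 && stats::sd(mb) == 0) {
    list(statistic = c(t = 0), p.value = 1, parameter = c(df = NA_real_))
  } else {
    stats::t.test(ma, mb, var.equal = var_equal)
  }
  list(days_a_higher = sum(ma > mb),
       days_b_higher = sum(mb > ma),
       prop_days_ge4 = stats::setNames(
         c(mean(ma >= 4), mean(mb >= 4)), c(group_a, group_b)),
       t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n_days = sum(ok))
}

#' Dichotomize intervention-impact items
#'
#' Agree or strongly agree (rating >= 4) versus other; missing responses
#' stay missing and drop out of any denominator downstream.
#'
#' @param records a `trial_records` frame (or any frame with
#'   `impact_1`..`impact_7`).
#' @return logical matrix, one row per participant, one column per item.
#' @export
dichotomize_impact <- function(records) {
  cols <- paste0("impact_", 1:7)
  stopifnot(all(cols %in% names(records)))
  m <- as.matrix(records[, cols]) >= 4
  rownames(m) <- records$user_id
  m
}

#' Build a 2x2 contingency table
#'
#' Rows are groups, columns outcome yes/no.
#' @param a,b,c,d cell counts: `a` = group 1 yes, `b` = group 1 no,
#'   `c` = group 2 yes, `d` = group 2 no.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_invalid("cell counts must be nonnegative integers")
  }
  if (sum(cells) == 0) stop_invalid("empty table")
  matrix(as.numeric(cells), 2, 2, byrow = TRUE,
         dimnames = list(group = c("g1", "g2"), outcome = c("yes", "no")))
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction, df = 1. A table with a zero margin has no
#' defined statistic: returns `NA`s with a warning.
#'
#' @param table 2x2 matrix of counts (see [contingency_2x2()]).
#' @return list `chi2`, `p`, `df`.
#' @export
chi_square_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("zero margin: chi-square undefined")
    return(list(chi2 = NA_real_, p = NA_real_, df = 1L))
  }
  ct <- stats::chisq.test(table, correct = FALSE)
  list(chi2 = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter))
}

#' Odds ratio of a 2x2 table with Wald confidence interval
#'
#' Cross-product ratio `ad / bc`;
#' `CI = exp(log(OR) +- z * sqrt(1/a + 1/b + 1/c + 1/d))`. A zero cell
#' triggers the Haldane-Anscombe correction (0.5 added to every cell),
#' flagged in the result.
#'
#' @param table 2x2 matrix of counts.
#' @param conf_level confidence level (default 0.95).
#' @return list `or`, `ci` (length 2), `corrected`.
#' @export
odds_ratio_2x2 <- function(table, conf_level = 0.95) {
  stopifnot(is.matrix(table), all(dim(table) == 2))
  corrected <- any(table == 0)
  t2 <- if (corrected) table + 0.5 else table
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  se <- sqrt(sum(1 / t2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = or, ci = exp(log(or) + c(-1, 1) * z * se),
       corrected = corrected)
}

#' Trend test across ordered categories of a 2xk table
#'
#' Score test for a linear trend in proportions (equivalently log-odds)
#' across k ordered categories — the Mantel-extension / Cochran-Armitage
#' trend statistic on 1 df, delegated to [stats::prop.trend.test()]. With
#' k = 2 it reduces to the Pearson chi-square on the 2x2 table.
#'
#' @param table 2 x k matrix: row 1 = events, row 2 = non-events, columns
#'   in category order.
#' @param scores category scores (default `1:k`).
#' @return list `statistic`, `p`, `df`.
#' @export
trend_test_2xk <- function(table, scores = NULL) {
  stopifnot(is.matrix(table), nrow(table) == 2)
  k <- ncol(table)
  if (k < 2) stop_invalid("trend test needs k >= 2 categories")
  if (is.null(scores)) scores <- seq_len(k)
  # prop.trend.test's internal anova emits a spurious F-test warning when
  # the trend fit is saturated (k = 2); the score statistic is unaffected
  tt <- suppressWarnings(
    stats::prop.trend.test(table[1, ], colSums(table), score = scores))
  list(statistic = unname(tt$statistic), p = tt$p.value, df = 1L)
}

#' Logistic regression with odds ratios and Wald intervals
#'
#' Maximum-likelihood logistic fit (IRLS Newton-type, via
#' [stats::glm()]) of a binary outcome on an exposure and optional
#' covariates, reporting exponentiated coefficients with 95% Wald CIs.
#' Complete or quasi-complete separation (divergent coefficients) is an
#' error naming the offending variable; non-convergence is an error.
#'
#' @param data data frame.
#' @param outcome name of the binary outcome column (logical or 0/1).
#' @param exposure name of the exposure column.
#' @param covariates character vector of adjustment columns.
#' @param conf_level confidence level (default 0.95).
#' @return data frame, one row per coefficient: `term`, `estimate`, `se`,
#'   `or`, `ci_lo`, `ci_hi`, `p`.
#' @export
fit_logistic <- function(data, outcome, exposure, covariates = character(),
                         conf_level = 0.95) {
  vars <- c(exposure, covariates)
  fml <- stats::reformulate(vars, response = outcome)
  use <- stats::complete.cases(data[, c(outcome, vars), drop = FALSE])
  fit <- suppressWarnings(stats::glm(fml, data = data[use, , drop = FALSE],
                                     family = stats::binomial()))
  if (!fit$converged) stop_invalid("logistic fit did not converge")
  co <- summary(fit)$coefficients
  big <- setdiff(rownames(co)[abs(co[, "Estimate"]) > 12], "(Intercept)")
  if (length(big)) {
    stop_invalid("separation detected for: %s", paste(big, collapse = ", "))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = rownames(co),
             estimate = co[, "Estimate"],
             se = co[, "Std. Error"],
             or = exp(co[, "Estimate"]),
             ci_lo = exp(co[, "Estimate"] - z * co[, "Std. Error"]),
             ci_hi = exp(co[, "Estimate"] + z * co[, "Std. Error"]),
             p = co[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}
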