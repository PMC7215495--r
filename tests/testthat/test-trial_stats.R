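roster2 <- function() {
  data.frame(user_id = c("a1", "a2", "b1", "b2"),
             group = c("g1", "g1", "g2", "g2"),
             stringsAsFactors = FALSE)
}

test_that("daily group means average raters only and flag empty days", {
  ev <- data.frame(
    user_id = c("a1", "a2", "a1", "b1", "b2", "b1"),
    message_id = paste0("m", 1:6),
    day_index = c(1L, 1L, 2L, 1L, 1L, 3L),
    value = c(4, 5, 3, 2, NA, 4))
  s <- daily_group_means(ev, roster2(), days = 1:3)
  g1 <- s[s$group == "g1", ]
  g2 <- s[s$group == "g2", ]
  expect_equal(g1$mean_rating, c(4.5, 3, NA))   # hand-computed
  expect_equal(g1$n, c(2L, 1L, 0L))
  expect_equal(g2$mean_rating, c(2, NA, 4))     # the NA rating is excluded
  expect_equal(g2$n, c(1L, 0L, 1L))
})

test_that("daily series comparison counts days and runs the t test", {
  base <- data.frame(group = rep(c("g1", "g2"), each = 30),
                     day_index = rep(1:30, 2),
                     mean_rating = c(rep(4.2, 30), rep(4.0, 30)),
                     n = 5L)
  identical_series <- base
  identical_series$mean_rating <- rep(4, 60)
  res0 <- compare_daily_ratings(identical_series, "g1", "g2")
  expect_equal(res0$days_a_higher, 0)
  expect_equal(res0$t, 0)

  set.seed(2)
  shifted <- base
  shifted$mean_rating <- c(rnorm(30, 4.2, 0.05),
                           rep(0, 30))
  shifted$mean_rating[31:60] <- shifted$mean_rating[1:30] - 0.2
  res <- compare_daily_ratings(shifted, "g1", "g2")
  expect_equal(res$days_a_higher, 30)
  expect_equal(unname(res$prop_days_ge4), c(1, mean(shifted$mean_rating[31:60] >= 4)))
  expect_lt(res$p, 0.001)

  mismatch <- shifted[shifted$day_index <= 29 | shifted$group == "g2", ]
  expect_error(compare_daily_ratings(mismatch, "g1", "g2"), "day ranges")
})

test_that("a group gap of 0.17 at sd 0.1 is detected at alpha=.001", {
  # Monte-Carlo power oracle for the two-sample t on 30 daily means
  set.seed(10)
  hits <- replicate(500, {
    a <- rnorm(30, 4.27, 0.1)
    b <- rnorm(30, 4.10, 0.1)
    s <- data.frame(group = rep(c("g1", "g2"), each = 30),
                    day_index = rep(1:30, 2), mean_rating = c(a, b), n = 5L)
    compare_daily_ratings(s, "g1", "g2")$p < 0.001
  })
  expect_gt(mean(hits), 0.9)
})

test_that("impact items dichotomize at agree-or-strongly-agree", {
  rec <- data.frame(user_id = "x", t(setNames(c(4, 3, 5, NA, 1, 2, 4),
                                              paste0("impact_", 1:7))))
  d <- dichotomize_impact(rec)
  expect_equal(as.vector(d), c(TRUE, FALSE, TRUE, NA, FALSE, FALSE, TRUE))
})

test_that("chi-square matches the expected-count formula and handles margins", {
  quit <- contingency_2x2(30, 21, 19, 31)
  res <- chi_square_2x2(quit)
  expect_equal(res$chi2, 4.38, tolerance = 0.01)
  expect_equal(res$p, 0.036, tolerance = 0.01)

  balanced <- contingency_2x2(10, 10, 10, 10)
  expect_equal(chi_square_2x2(balanced)$chi2, 0)

  # brute-force oracle on random tables: chi2 = sum (O-E)^2 / E
  set.seed(31)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 12) + 1, 2, 2)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chi_square_2x2(tab)$chi2, sum((tab - E)^2 / E),
                 tolerance = 1e-10)
  }

  degenerate <- matrix(c(0, 0, 5, 7), 2, 2, byrow = TRUE)
  expect_warning(res0 <- chi_square_2x2(matrix(c(0, 5, 0, 7), 2, 2)),
                 "zero margin")
  expect_true(is.na(res0$chi2))
})

test_that("odds ratios use the cross-product with Wald intervals", {
  quit <- contingency_2x2(30, 21, 19, 31)
  res <- odds_ratio_2x2(quit)
  expect_equal(res$or, (30 * 31) / (21 * 19), tolerance = 1e-12)
  expect_equal(round(res$or, 1), 2.3)
  expect_false(res$corrected)
  expect_lt(res$ci[1], res$or); expect_gt(res$ci[2], res$or)

  expect_equal(odds_ratio_2x2(contingency_2x2(10, 10, 10, 10))$or, 1)

  zero <- odds_ratio_2x2(contingency_2x2(5, 0, 3, 4))
  expect_true(zero$corrected)
  expect_true(is.finite(zero$or))
})

test_that("trend test detects monotone proportions and reduces to chi-square", {
  flat <- rbind(events = c(20, 20, 20), nonevents = c(30, 30, 30))
  expect_lt(trend_test_2xk(flat)$statistic, 1e-10)

  mono <- rbind(events = c(20, 50, 80), nonevents = c(80, 50, 20))
  expect_lt(trend_test_2xk(mono)$p, 0.01)

  tab22 <- contingency_2x2(30, 21, 19, 31)
  by_cat <- rbind(events = tab22[, 1], nonevents = tab22[, 2])
  expect_equal(trend_test_2xk(by_cat)$statistic,
               chi_square_2x2(tab22)$chi2, tolerance = 1e-10)
  expect_error(trend_test_2xk(rbind(1, 2)), "k >= 2")
})

test_that("logistic regression agrees with the 2x2 odds ratio algebraically", {
  tab <- contingency_2x2(30, 21, 19, 31)
  d <- data.frame(
    quit = rep(c(1, 0, 1, 0), times = c(30, 21, 19, 31)),
    exposed = rep(c(1, 1, 0, 0), times = c(30, 21, 19, 31)))
  fit <- fit_logistic(d, "quit", "exposed")
  expect_equal(fit$or[fit$term == "exposed"], odds_ratio_2x2(tab)$or,
               tolerance = 1e-6)

  # null case: outcome independent of predictors
  set.seed(8)
  d0 <- data.frame(y = rbinom(4000, 1, 0.4), x = rbinom(4000, 1, 0.5),
                   z = rnorm(4000))
  fit0 <- fit_logistic(d0, "y", "x", "z")
  expect_equal(fit0$or[fit0$term == "x"], 1, tolerance = 0.25)

  # an independent covariate leaves the exposure OR essentially unchanged
  set.seed(9)
  n <- 4000
  x <- rbinom(n, 1, 0.5); w <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  d1 <- data.frame(y = y, x = x, w = w)
  or_crude <- fit_logistic(d1, "y", "x")$or[2]
  or_adj <- fit_logistic(d1, "y", "x", "w")$or[2]
  expect_equal(or_adj, or_crude, tolerance = 0.05)

  sep <- data.frame(y = c(rep(0, 20), rep(1, 20)),
                    x = c(rep(0, 20), rep(1, 20)))
  expect_error(fit_logistic(sep, "y", "x"), "separation")
})
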