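test_that("count aggregation is a conservation-preserving binning with zeros", {
  base <- as.POSIXct("2019-11-01 00:00:00", tz = "UTC")
  tw <- tweet_corpus(id = c("a", "b", "c"), created_at = base + c(10, 5000, 90000),
                     text = rep("x", 3))
  s <- aggregate_counts(tw, "day", c("2019-11-01", "2019-12-01"))
  expect_equal(nrow(s), 30L)
  expect_equal(s$count, c(2, 1, rep(0, 28)))
  expect_equal(sum(s$count), 3)

  h <- aggregate_counts(tw, "hour", c("2019-11-01", "2019-12-01"))
  expect_equal(nrow(h), 720L)  # 30 days x 24 hours
  expect_equal(sum(h$count), 3)
  expect_equal(h$count[[1]], 1)
  expect_equal(h$count[[2]], 1)
  expect_equal(h$count[[26]], 1)  # 90000 s = day 2, hour 26

  # conservation on a generated corpus
  s2 <- generate_corpus(small_sim(seed = 2, days = 5))
  in_a <- s2$tweets$created_at < as.POSIXct("2020-01-01", tz = "UTC")
  day <- aggregate_counts(s2$tweets, "day", c("2019-11-01", "2019-11-06"))
  hour <- aggregate_counts(s2$tweets, "hour", c("2019-11-01", "2019-11-06"))
  expect_equal(sum(day$count), sum(in_a))
  expect_equal(sum(hour$count), sum(in_a))
  expect_error(aggregate_counts(tw, "week", c("2019-11-01", "2019-12-01")))
})

test_that("normality testing attains nominal type-I error and detects heavy tails", {
  p_normal <- vapply(1:100, function(seed) {
    withr::with_seed(seed, normality_test(rnorm(30, 50, 5))$p_value)
  }, numeric(1))
  expect_gte(sum(p_normal > 0.05), 90)

  p_lnorm <- vapply(1:100, function(seed) {
    withr::with_seed(1000 + seed, normality_test(rlnorm(720, 3, 1))$p_value)
  }, numeric(1))
  expect_gte(sum(p_lnorm < 0.05), 90)

  expect_error(normality_test(rep(5, 10)), "constant")
  expect_error(normality_test(c(1, 2)), "at least 3")
})

test_that("two-group ANOVA matches closed-form sums of squares", {
  res <- compare_groups(c(1, 2, 3), c(3, 4, 5))
  expect_equal(res$F, 6.0, tolerance = 1e-12)
  expect_equal(res$df_between, 1L)
  expect_equal(res$df_within, 4L)

  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$F, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  expect_false(same$significant)

  expect_error(compare_groups(c(2, 2), c(2, 2)), "undefined")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("ANOVA equals the squared pooled t statistic and is scale invariant", {
  withr::with_seed(67, {
    for (rep in 1:200) {
      na <- sample(3:40, 1); nb <- sample(3:40, 1)
      a <- rnorm(na, 10, 3); b <- rnorm(nb, 11, 3)
      res <- compare_groups(a, b)
      tt <- stats::t.test(a, b, var.equal = TRUE)
      expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
      expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
      # multiplying all counts by a constant leaves F unchanged
      res_c <- compare_groups(7 * a, 7 * b)
      expect_equal(res_c$F, res$F, tolerance = 1e-9)
    }
  })
})

test_that("ratio reporting reproduces the percent summaries", {
  r <- ratio_report(17674, 32530)
  expect_equal(r$ratio_pct, 184.06)
  expect_gt(r$ratio_pct, 184)
  expect_equal(r$change_headline, 84)

  expect_equal(ratio_report(12223, 11785)$ratio_pct, 96.42)
  expect_equal(ratio_report(500, 500),
               list(ratio_pct = 100, change_pct = 0, change_headline = 0))
  expect_error(ratio_report(0, 5), "positive")
})

test_that("polynomial trends interpolate, reduce to the mean, and satisfy normal equations", {
  y <- c(3, 9, 1, 7, 2, 8, 5)
  fit <- trend_fit(y, degree = 6)
  expect_lt(max(abs(fit$residuals)), 1e-8)  # 7 points, degree 6: interpolation
  expect_equal(fit$fitted, y, tolerance = 1e-8)

  fit0 <- trend_fit(y, degree = 0)
  expect_equal(unique(round(fit0$fitted, 10)), round(mean(y), 10))

  withr::with_seed(19, {
    for (rep in 1:10) {
      n <- sample(10:60, 1)
      yy <- rpois(n, 20)
      f <- trend_fit(yy, degree = 6)
      basis <- cbind(1, stats::poly(seq_len(n) - 1, 6))
      # residuals orthogonal to every basis polynomial
      expect_lt(max(abs(crossprod(basis, f$residuals))), 1e-8)
    }
  })
  expect_error(trend_fit(y[1:6], degree = 6), "points")
})

test_that("period-effect recovery: the day-count ratio tracks the configured factor", {
  # generation + aggregation route (no classifier): ratio estimates across
  # seeds concentrate on the configured period effect
  ratios <- vapply(1:10, function(seed) {
    s <- generate_corpus(sim_config(seed = seed, base_hourly_rate = 8,
                                    period_a = c("2019-11-01", "2019-11-16"),
                                    period_b = c("2020-11-01", "2020-11-16"),
                                    period_ratio = 1.84, duplicate_rate = 0))
    sa <- aggregate_counts(s$tweets, "day", c("2019-11-01", "2019-11-16"))
    sb <- aggregate_counts(s$tweets, "day", c("2020-11-01", "2020-11-16"))
    sum(sb$count) / sum(sa$count)
  }, numeric(1))
  mc_se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 1.84), 3 * mc_se)
})
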