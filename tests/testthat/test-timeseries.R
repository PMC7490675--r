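test_that("daily counts aggregate by UTC day and fill gaps with zeros", {
  d1 <- as.POSIXct("2018-03-01 10:00:00", tz = "UTC")
  corpus <- make_labeled(c("positive", "negative", "neutral"),
                         created_at = rep(d1, 3))
  dc <- daily_counts(corpus)
  expect_equal(nrow(dc), 1L)
  expect_equal(unlist(dc[1, c("n_positive", "n_neutral", "n_negative", "n_total")]),
               c(n_positive = 1L, n_neutral = 1L, n_negative = 1L, n_total = 3L))

  gap <- make_labeled(c("positive", "negative"),
                      created_at = as.POSIXct(c("2018-03-01", "2018-03-03"), tz = "UTC"))
  dcg <- daily_counts(gap)
  expect_equal(dcg$date, as.Date(c("2018-03-01", "2018-03-02", "2018-03-03")))
  expect_equal(dcg$n_total[2], 0L)

  x <- generate_corpus(small_corpus_config(seed = 13))
  x$pred_sentiment <- x$true_sentiment
  expect_equal(sum(daily_counts(x)$n_total), nrow(x))
  expect_error(daily_counts(make_labeled(character())), "empty")
})

test_that("the rolling index matches degenerate closed forms", {
  base <- tibble::tibble(
    date = seq(as.Date("2018-01-01"), by = "day", length.out = 10),
    n_positive = rep(3L, 10), n_neutral = rep(1L, 10), n_negative = rep(0L, 10)
  )
  base$n_total <- base$n_positive + base$n_neutral + base$n_negative
  expect_true(all(sentiment_index(base)$s == 1))

  bal <- base
  bal$n_negative <- bal$n_positive
  bal$n_total <- bal$n_positive + bal$n_neutral + bal$n_negative
  expect_true(all(sentiment_index(bal)$s == 0))

  quiet <- base
  quiet$n_positive <- quiet$n_negative <- rep(0L, 10)
  quiet$n_total <- quiet$n_neutral
  expect_true(all(is.na(sentiment_index(quiet)$s)))
  expect_true(all(sentiment_index(quiet)$a == 1))

  expect_error(sentiment_index(base, window = 4), "odd")
})

test_that("the rolling index equals the brute-force window oracle", {
  withr::with_seed(19, {
    for (rep in 1:25) {
      n <- 30
      df <- tibble::tibble(
        date = seq(as.Date("2018-01-01"), by = "day", length.out = n),
        n_positive = stats::rpois(n, 2), n_neutral = stats::rpois(n, 2),
        n_negative = stats::rpois(n, 1)
      )
      df$n_total <- df$n_positive + df$n_neutral + df$n_negative
      got <- sentiment_index(df)
      want <- index_oracle(df$n_positive, df$n_negative, df$n_total)
      expect_equal(got$s, want$s)
      expect_equal(got$a, want$a)
    }
  })
})

test_that("swapping positive and negative counts negates the index exactly", {
  x <- generate_corpus(small_corpus_config(seed = 23))
  x$pred_sentiment <- x$true_sentiment
  dc <- daily_counts(x)
  swapped <- dc
  swapped$n_positive <- dc$n_negative
  swapped$n_negative <- dc$n_positive
  expect_equal(sentiment_index(swapped)$s, -sentiment_index(dc)$s)
})

test_that("the trend fit recovers exact lines and flags thin input", {
  dates <- seq(as.Date("2015-01-01"), by = "day", length.out = 400)
  t_years <- as.numeric(dates - dates[1]) / 365.25
  idx <- tibble::tibble(date = dates, s = 0.5 - 0.1 * t_years)
  fit <- fit_linear_trend(idx)
  expect_equal(fit$slope, -0.1, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-10)
  expect_equal(fit$stderr, 0, tolerance = 1e-8)

  flat <- tibble::tibble(date = dates, s = 0.3)
  fit0 <- fit_linear_trend(flat)
  expect_equal(fit0$slope, 0, tolerance = 1e-12)
  expect_equal(fit0$stderr, 0, tolerance = 1e-12)

  expect_error(fit_linear_trend(tibble::tibble(date = dates[1:5],
                                               s = c(0.1, NA, NA, NA, 0.2))),
               "at least 3")
})

test_that("welch_t matches the textbook formulas and the pooled limit", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5)
  got <- welch_t(a, b)
  want <- welch_oracle(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # equal n, equal variances: df collapses to the pooled 2n - 2
  expect_equal(welch_t(c(1, 2, 3, 4), c(5, 6, 7, 8))$df, 6, tolerance = 1e-12)

  # degenerate variance
  expect_equal(welch_t(c(2, 2, 2), c(2, 2))$p, 1)
  expect_equal(welch_t(c(2, 2, 2), c(3, 3))$p, 0)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("yearly sentiment means, SDs, and Welch tests match direct computation", {
  ts1 <- as.POSIXct("2016-06-01", tz = "UTC") + (0:99) * 3600
  ts2 <- as.POSIXct("2017-06-01", tz = "UTC") + (0:99) * 3600
  lab1 <- rep(c("positive", "negative"), c(90, 10))
  lab2 <- rep(c("positive", "negative"), c(70, 30))
  corpus <- make_labeled(c(lab1, lab2), created_at = c(ts1, ts2))
  out <- yearly_sentiment_tests(corpus)
  w1 <- sentiment_weight(lab1); w2 <- sentiment_weight(lab2)
  expect_equal(out$yearly$mean, c(mean(w1), mean(w2)))
  expect_equal(out$yearly$sd, c(sd(w1), sd(w2)))
  want <- welch_oracle(w1, w2)
  expect_equal(out$tests$t, want$t, tolerance = 1e-12)
  expect_equal(out$tests$p, want$p, tolerance = 1e-12)

  # identical weight multisets across years: no difference
  corpus_same <- make_labeled(c(lab1, lab1), created_at = c(ts1, ts2))
  expect_equal(yearly_sentiment_tests(corpus_same)$tests$p, 1)

  # a degenerate all-positive year still yields mean 1, sd 0
  corpus_deg <- make_labeled(c(rep("positive", 50), lab2),
                             created_at = c(ts1[1:50], ts2))
  deg <- yearly_sentiment_tests(corpus_deg)
  expect_equal(deg$yearly$mean[1], 1)
  expect_equal(deg$yearly$sd[1], 0)

  expect_error(yearly_sentiment_tests(make_labeled(rep("positive", 5))),
               "2 years")
})
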