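#' Daily sentiment counts
#'
#' Counts records per UTC calendar day by predicted sentiment, filling days
#' without records with zeros so the series is contiguous.
#'
#' @param corpus Labeled corpus tibble with `created_at` and
#'   `pred_sentiment`.
#' @return Tibble with `date`, `n_positive`, `n_neutral`, `n_negative`,
#'   `n_total`, one row per day.
#' @export
daily_counts <- function(corpus) {
  if (nrow(corpus) == 0) stop("empty corpus", call. = FALSE)
  day <- as.Date(corpus$created_at, tz = "UTC")
  dates <- seq(min(day), max(day), by = "day")
  tab <- table(factor(as.character(day), levels = as.character(dates)),
               factor(corpus$pred_sentiment, levels = sentiment_levels()))
  out <- tibble::tibble(
    date = dates,
    n_positive = as.integer(tab[, "positive"]),
    n_neutral = as.integer(tab[, "neutral"]),
    n_negative = as.integer(tab[, "negative"])
  )
  out$n_total <- out$n_positive + out$n_neutral + out$n_negative
  out
}

# windowed sums with truncation at the series edges
.window_sum <- function(x, half) {
  n <- length(x)
  cs <- cumsum(x)
  hi <- pmin(seq_len(n) + half, n)
  lo <- pmax(seq_len(n) - half, 1L)
  cs[hi] - c(0, cs)[lo]
}

#' Rolling sentiment index and smoothed activity
#'
#' For each day \eqn{d}, the sentiment index is the count-weighted mean of
#' the +1/-1 weights of positive and negative posts over a centered window
#' (default 7 days, i.e. +/- 3 days): \eqn{s(d) = (P - N)/(P + N)} with
#' \eqn{P, N} the windowed positive/negative counts. Neutral posts are
#' excluded from the index; the index is undefined (`NA`) when a window
#' holds no polar posts. Windows truncate at the series edges. The smoothed
#' activity `a` is the mean of total daily counts over the same window.
#'
#' @param series Output of [daily_counts()].
#' @param window Odd window length in days (default 7).
#' @return `series` with columns `s` and `a` appended.
#' @export
sentiment_index <- function(series, window = 7) {
  stopifnot(window >= 1)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  half <- (window - 1L) / 2L
  P <- .window_sum(series$n_positive, half)
  N <- .window_sum(series$n_negative, half)
  tot <- .window_sum(series$n_total, half)
  n <- nrow(series)
  width <- pmin(seq_len(n) + half, n) - pmax(seq_len(n) - half, 1L) + 1L
  series$s <- ifelse(P + N > 0, (P - N) / (P + N), NA_real_)
  series$a <- tot / width
  series
}

#' Linear trend of the sentiment index
#'
#' Ordinary least squares of the index on time in years (365.25 days),
#' skipping undefined days. Because the index is built on overlapping
#' windows, its day-to-day errors are serially correlated up to lag
#' `window - 1` (an MA(window-1) structure); the default standard error is
#' therefore heteroskedasticity-and-autocorrelation consistent, using a
#' truncated (flat) kernel at exactly that known lag, which is unbiased for
#' the long-run variance of a moving-average process. Set `se = "ols"` for
#' the classical iid standard error.
#'
#' @param index Output of [sentiment_index()] (needs `date` and `s`).
#' @param se `"hac"` (default) or `"ols"`.
#' @param lag HAC truncation lag in days: the maximal error autocorrelation
#'   lag, `window - 1` (default 6, matching the 7-day window).
#' @return A `trend_fit` list: `slope` and `stderr` (per year), `intercept`,
#'   `n` (days used).
#' @export
fit_linear_trend <- function(index, se = c("hac", "ols"), lag = 6) {
  se <- match.arg(se)
  ok <- !is.na(index$s)
  if (sum(ok) < 3) stop("need at least 3 defined index values", call. = FALSE)
  t_years <- as.numeric(index$date - index$date[1]) / 365.25
  fit <- stats::lm(s ~ t_years, data = data.frame(s = index$s, t_years)[ok, ])
  vc <- if (se == "hac") {
    # suppress the "essentially perfect fit" note: exact lines are legal input
    suppressWarnings(sandwich::kernHAC(fit, kernel = "Truncated", bw = lag,
                                       prewhite = FALSE, adjust = TRUE))
  } else {
    stats::vcov(fit)
  }
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    stderr = sqrt(max(vc[2, 2], 0)),
    intercept = unname(stats::coef(fit)[1]),
    n = sum(ok)
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("linear trend: slope %.4f per year (SE %.4f), intercept %.4f, n = %d days\n",
              x$slope, x$stderr, x$intercept, x$n))
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value. When both samples are constant the statistic
#' degenerates: equal means give `t = 0, p = 1`; unequal means give an
#' infinite statistic and `p = 0`.
#'
#' @param sample_a,sample_b Numeric vectors of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("both samples need at least 2 observations", call. = FALSE)
  }
  va <- stats::var(sample_a)
  vb <- stats::var(sample_b)
  if (va + vb <= 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(list(t = 0, df = length(sample_a) + length(sample_b) - 2, p = 1))
    }
    return(list(t = sign(mean(sample_a) - mean(sample_b)) * Inf,
                df = length(sample_a) + length(sample_b) - 2, p = 0))
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Yearly sentiment means and Welch comparisons
#'
#' Per calendar year, the mean and SD of the +1/-1 weights of polar
#' (positive/negative) posts — neutral posts are excluded — plus Welch tests
#' for every consecutive-year pair. Raw p values are reported alongside
#' Holm-adjusted ones.
#'
#' @param corpus Labeled corpus with `created_at` and `pred_sentiment`.
#' @param min_polar Minimum polar posts for a year to enter (default 2).
#' @return List of two tibbles: `yearly` (`year`, `n`, `mean`, `sd`) and
#'   `tests` (`year_a`, `year_b`, `t`, `df`, `p`, `p_holm`).
#' @export
yearly_sentiment_tests <- function(corpus, min_polar = 2) {
  polar <- corpus[corpus$pred_sentiment %in% c("positive", "negative"), , drop = FALSE]
  year <- as.integer(format(polar$created_at, "%Y", tz = "UTC"))
  w <- sentiment_weight(polar$pred_sentiment)
  yearly <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(year, w), .data$year),
    n = dplyr::n(), mean = mean(.data$w), sd = stats::sd(.data$w),
    .groups = "drop"
  )
  yearly <- yearly[yearly$n >= min_polar, , drop = FALSE]
  if (nrow(yearly) < 2) stop("need at least 2 years with enough polar posts", call. = FALSE)
  ys <- sort(yearly$year)
  tests <- do.call(rbind, lapply(seq_len(length(ys) - 1), function(i) {
    a <- w[year == ys[i]]
    b <- w[year == ys[i + 1]]
    wt <- welch_t(a, b)
    data.frame(year_a = ys[i], year_b = ys[i + 1], t = wt$t, df = wt$df, p = wt$p)
  }))
  tests$p_holm <- stats::p.adjust(tests$p, method = "holm")
  list(yearly = yearly, tests = tibble::as_tibble(tests))
}

#' Detect peaks by topographic prominence
#'
#' Local maxima (strictly greater than their immediate neighbors; for
#' plateaus the leftmost plateau index) are scored by topographic prominence:
#' walking away from the peak in each direction until a strictly higher
#' value (or the series end) is met, the prominence is the peak height above
#' the higher of the two minima encountered. Peaks with
#' `prominence / (max - min) >= rel_prominence_min` are kept.
#'
#' @param values Numeric series of length >= 3, not constant.
#' @param rel_prominence_min Relative prominence cut-off (default 0.2).
#' @return Tibble with `index`, `height`, `prominence`, `rel_prominence`,
#'   sorted by `index`.
#' @export
detect_peaks <- function(values, rel_prominence_min = 0.2) {
  stopifnot(length(values) >= 3, !anyNA(values))
  rng <- max(values) - min(values)
  if (rng <= 0) stop("constant series: relative prominence undefined", call. = FALSE)

  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  is_peak <- rep(FALSE, k)
  if (k >= 3) {
    mid <- 2:(k - 1)
    is_peak[mid] <- r$values[mid] > r$values[mid - 1] & r$values[mid] > r$values[mid + 1]
  }
  peak_idx <- starts[is_peak]

  prominence <- vapply(peak_idx, function(i) {
    h <- values[i]
    left_min <- h
    j <- i - 1L
    while (j >= 1 && values[j] <= h) {
      left_min <- min(left_min, values[j])
      j <- j - 1L
    }
    right_min <- h
    j <- i + 1L
    while (j <= length(values) && values[j] <= h) {
      right_min <- min(right_min, values[j])
      j <- j + 1L
    }
    h - max(left_min, right_min)
  }, numeric(1))

  out <- tibble::tibble(
    index = peak_idx,
    height = values[peak_idx],
    prominence = prominence,
    rel_prominence = prominence / rng
  )
  out[out$rel_prominence >= rel_prominence_min, , drop = FALSE]
}
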