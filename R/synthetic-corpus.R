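#' Configuration for a synthetic tweet stream
#'
#' Describes a corpus-generating process with known ground truth: a Poisson
#' daily activity baseline, a three-class sentiment mixture with a linear
#' drift of the expected sentiment index, discrete event bursts (activity
#' spikes with negative sentiment shifts), an organism-class mixture, a
#' weighted hashtag vocabulary, and retweet/duplicate structure. The defaults
#' emulate the surveilled 6.5-year CRISPR tweet stream: roughly 1.5M posts
#' between 2013-01-01 and 2019-05-31, a 52/40/7 positive/neutral/negative
#' mix, an index drift of -0.061 per year, and a duplicate share of about
#' two thirds.
#'
#' @param start_date,end_date UTC calendar dates (inclusive) bounding the
#'   stream; `start_date < end_date`.
#' @param base_rate Expected posts per day before event multipliers (> 0).
#' @param class_probs Probability vector over
#'   `positive`/`neutral`/`negative`; must sum to 1.
#' @param trend_slope Drift of the expected sentiment index per year. The
#'   drift is injected on the log-odds of the negative class (see Details).
#' @param events List of [event_spec()] bursts, or `NULL` (the default) for
#'   [default_events()] restricted to the corpus date range. Explicitly
#'   supplied events must lie inside the range.
#' @param organism_probs Probability vector over [organism_levels()].
#' @param hashtag_vocab Tibble with columns `tag`, `weight` (selection
#'   weight), `sentiment_shift` (log-weight added per unit of tweet sentiment
#'   weight, so negative shifts make a tag favor negative tweets).
#' @param duplicate_rate Fraction of records emitted as retweets/duplicates,
#'   in `[0, 1)`.
#' @param irrelevant_rate Fraction of off-topic records (ground-truth
#'   relevance `not_relevant`), in `[0, 1)`.
#' @param seed Integer RNG seed; generation is fully deterministic given it.
#'
#' @details
#' The expected sentiment index \eqn{s = (p_+ - p_-)/(p_+ + p_-)} follows the
#' line \eqn{s(t) = s_0 + \beta t} (clamped to \eqn{(-1, 1)}) by rescaling
#' the negative-class weight: the day-\eqn{t} class vector is
#' \eqn{(p_+, p_0, p_- e^{\delta(t)})} renormalized, with \eqn{\delta(t)}
#' chosen so the polar ratio matches the target line. Event
#' `sentiment_shift`s add to \eqn{\delta} during the event window. Acting on
#' log-odds keeps the class vector a valid probability vector for any slope.
#'
#' @return A `corpus_config` list.
#' @seealso [generate_corpus()]
#' @export
corpus_config <- function(start_date = "2013-01-01",
                          end_date = "2019-05-31",
                          base_rate = 644,
                          class_probs = c(positive = 0.5227, neutral = 0.4028,
                                          negative = 0.0745),
                          trend_slope = -0.061,
                          events = NULL,
                          organism_probs = c(humans = 0.30, embryos = 0.05,
                                             animals = 0.15, plants = 0.08,
                                             bacteria = 0.07, unspecified = 0.35),
                          hashtag_vocab = default_hashtag_vocab(),
                          duplicate_rate = 0.67,
                          irrelevant_rate = 0.017,
                          seed = 1L) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date)) abort_config("start_date", "not a date")
  if (is.na(end_date)) abort_config("end_date", "not a date")
  if (!start_date < end_date) abort_config("start_date", "must be before end_date")
  if (!is.numeric(base_rate) || length(base_rate) != 1 || base_rate < 0) {
    abort_config("base_rate", "must be a non-negative number")
  }
  class_probs <- check_prob_vector(class_probs, "class_probs", sentiment_levels())
  organism_probs <- check_prob_vector(organism_probs, "organism_probs", organism_levels())
  if (!is.numeric(duplicate_rate) || duplicate_rate < 0 || duplicate_rate >= 1) {
    abort_config("duplicate_rate", "must be in [0, 1)")
  }
  if (!is.numeric(irrelevant_rate) || irrelevant_rate < 0 || irrelevant_rate >= 1) {
    abort_config("irrelevant_rate", "must be in [0, 1)")
  }
  if (is.null(events)) {
    events <- Filter(function(ev) ev$date >= start_date & ev$date <= end_date,
                     default_events())
  } else {
    for (ev in events) {
      if (!inherits(ev, "event_spec")) abort_config("events", "entries must be event_spec objects")
      if (ev$date < start_date || ev$date > end_date) {
        abort_config("events", sprintf("event date %s outside corpus range", ev$date))
      }
    }
  }
  structure(list(
    start_date = start_date, end_date = end_date, base_rate = base_rate,
    class_probs = class_probs, trend_slope = trend_slope, events = events,
    organism_probs = organism_probs, hashtag_vocab = hashtag_vocab,
    duplicate_rate = duplicate_rate, irrelevant_rate = irrelevant_rate,
    seed = as.integer(seed)
  ), class = "corpus_config")
}

#' Specify a discrete event burst
#'
#' An event multiplies the expected daily activity and shifts the log-odds of
#' the negative sentiment class for `duration_days` consecutive days starting
#' at `date` — the generative analogue of a news event producing an activity
#' peak with a sentiment dip.
#'
#' @param date UTC day the burst starts.
#' @param activity_multiplier Multiplier (>= 1) on the Poisson rate.
#' @param sentiment_shift Real added to the negative-class log-odds.
#' @param duration_days Length of the burst in days (>= 1).
#' @return An `event_spec` list.
#' @export
event_spec <- function(date, activity_multiplier = 1, sentiment_shift = 0,
                       duration_days = 1L) {
  date <- as.Date(date)
  if (is.na(date)) abort_config("date", "not a date")
  if (activity_multiplier < 1) abort_config("activity_multiplier", "must be >= 1")
  if (duration_days < 1) abort_config("duration_days", "must be >= 1")
  structure(list(date = date, activity_multiplier = activity_multiplier,
                 sentiment_shift = sentiment_shift,
                 duration_days = as.integer(duration_days)),
            class = "event_spec")
}

#' Default event bursts for the 2013-2019 stream
#'
#' Six bursts at dates of major news moments in the genome-editing discourse
#' (international summits, patent rulings, embryo-editing reports, off-target
#' and cancer-risk studies, the germline-edited-babies announcement, and
#' moratorium calls), with activity multipliers and negative sentiment
#' shifts of plausible magnitude. These are synthetic stand-ins, not
#' measurements.
#'
#' @return List of [event_spec()] objects.
#' @export
default_events <- function() {
  list(
    event_spec("2015-11-30", 2.5, 1.0, 4),
    event_spec("2017-02-15", 3.0, 0.5, 3),
    event_spec("2017-08-02", 4.0, 1.5, 4),
    event_spec("2018-06-11", 3.5, 2.0, 4),
    event_spec("2018-11-26", 6.0, 2.5, 7),
    event_spec("2019-03-13", 3.0, 1.5, 3)
  )
}

#' Default hashtag vocabulary
#'
#' @return Tibble with columns `tag`, `weight`, `sentiment_shift`.
#' @export
default_hashtag_vocab <- function() {
  tibble::tribble(
    ~tag,            ~weight, ~sentiment_shift,
    "#crispr",        10.0,    0.0,
    "#science",        2.0,    0.3,
    "#geneediting",    2.0,    0.0,
    "#biotech",        1.5,    0.2,
    "#dna",            1.0,    0.0,
    "#research",       1.0,    0.1,
    "#genetherapy",    0.8,    0.5,
    "#gmo",            0.7,   -1.0,
    "#crisprbabies",   0.5,   -2.0,
    "#bioethics",      0.4,   -0.8
  )
}

.gen_vocab <- list(
  topic = c("crispr", "gene", "editing", "genome", "dna", "cells",
            "scientists", "research", "technology", "therapy", "enzyme",
            "sequence", "biology"),
  positive = c("breakthrough", "hope", "promising", "cure", "progress",
               "exciting", "revolutionary", "success", "benefit", "improved",
               "amazing", "great"),
  negative = c("fear", "risk", "dangerous", "ban", "unethical", "concern",
               "worried", "alarming", "scary", "controversy", "harm",
               "threat"),
  neutral = c("report", "study", "announced", "published", "paper",
              "explains", "review", "update", "describes", "results",
              "method", "data"),
  organism = list(
    humans = c("patients", "human", "people"),
    embryos = c("embryo", "embryos", "babies"),
    animals = c("mice", "animals", "pigs", "monkeys"),
    plants = c("crops", "plants", "rice", "tomato"),
    bacteria = c("bacteria", "microbes", "phage", "yeast"),
    unspecified = character(0)
  ),
  offtopic = c("coffee", "football", "music", "movie", "recipe", "holiday",
               "traffic", "weekend", "game", "pizza", "beach", "party",
               "birthday", "shopping", "weather", "dogs", "cats", "song"),
  filler = c("the", "a", "to", "of", "in", "new", "this", "that", "today",
             "will", "about", "for", "with", "now", "just", "more", "big",
             "first", "look", "think", "know", "world", "future", "year",
             "time", "work", "team", "story", "interesting"),
  interjection = c("wow", "omg", "whoa", "yay", "ugh", "hmm")
)

# paste word draws of variable per-record counts into one string per record
.paste_groups <- function(words, counts, n) {
  out <- character(n)
  nz <- counts > 0
  if (any(nz)) {
    f <- factor(rep.int(seq_len(n), counts), levels = seq_len(n)[nz])
    out[nz] <- vapply(split(words, f), paste, collapse = " ", character(1))
  }
  out
}

.sample_by_group <- function(group, pools) {
  out <- character(length(group))
  for (g in unique(group)) {
    idx <- which(group == g)
    pool <- pools[[g]]
    if (length(pool) == 0) next
    out[idx] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
  }
  out
}

#' Generate a synthetic tweet corpus with hidden ground truth
#'
#' Draws per-day record counts from a Poisson process (base rate times the
#' active event multipliers), assigns each record a true sentiment from the
#' drift- and event-adjusted class mixture, a true relevance and organism
#' class, template text over the packaged toy lexicon (with sentiment- and
#' organism-indicative cue words, hashtags from the weighted vocabulary, and
#' occasional handles/URLs), and emits a fraction of records as verbatim
#' same-day duplicates pointing at their original via `duplicate_of`. A
#' single RNG stream is seeded from `config$seed`, so equal configs produce
#' identical corpora.
#'
#' @param config A [corpus_config()].
#' @return Tibble with columns `id`, `created_at` (POSIXct UTC, sorted),
#'   `text`, `duplicate_of`, `hashtags` (list column), and hidden truth
#'   columns `true_relevance`, `true_sentiment`, `true_organism`.
#' @export
generate_corpus <- function(config) {
  if (!inherits(config, "corpus_config")) {
    abort_config("config", "must be created by corpus_config()")
  }
  withr::with_seed(config$seed, .generate_corpus_impl(config))
}

.generate_corpus_impl <- function(config) {
  days <- seq(config$start_date, config$end_date, by = "day")
  nd <- length(days)
  t_years <- as.numeric(days - days[1]) / 365.25

  mult <- rep(1, nd)
  shift <- rep(0, nd)
  for (ev in config$events) {
    active <- days >= ev$date & days <= ev$date + ev$duration_days - 1
    mult[active] <- mult[active] * ev$activity_multiplier
    shift[active] <- shift[active] + ev$sentiment_shift
  }

  n_day <- stats::rpois(nd, config$base_rate * mult)
  n <- sum(n_day)
  empty <- tibble::tibble(
    id = character(), created_at = as.POSIXct(character(), tz = "UTC"),
    text = character(), duplicate_of = character(), hashtags = list(),
    true_relevance = character(), true_sentiment = character(),
    true_organism = character()
  )
  if (n == 0) return(empty)

  # day-level class mixture: trend + events act on the negative log-odds
  p <- config$class_probs
  delta <- shift
  if (p[["positive"]] > 0 && p[["negative"]] > 0) {
    s0 <- (p[["positive"]] - p[["negative"]]) / (p[["positive"]] + p[["negative"]])
    s_target <- pmin(pmax(s0 + config$trend_slope * t_years, -0.999), 0.999)
    r0 <- p[["negative"]] / p[["positive"]]
    delta <- delta + log((1 - s_target) / (1 + s_target) / r0)
  } else if (config$trend_slope != 0) {
    warning("trend_slope ignored: class_probs has no polar mass on both sides")
  }
  w_neg <- p[["negative"]] * exp(delta)
  day_probs <- cbind(p[["positive"]], p[["neutral"]], w_neg)
  day_probs <- day_probs / rowSums(day_probs)

  day_idx <- rep.int(seq_len(nd), n_day)
  u <- stats::runif(n)
  cp_pos <- day_probs[day_idx, 1]
  cp_neu <- cp_pos + day_probs[day_idx, 2]
  sentiment <- ifelse(u < cp_pos, "positive", ifelse(u < cp_neu, "neutral", "negative"))
  relevance <- ifelse(stats::runif(n) < config$irrelevant_rate, "not_relevant", "relevant")
  organism <- sample(organism_levels(), n, replace = TRUE, prob = config$organism_probs)

  created_at <- as.POSIXct(days[day_idx], tz = "UTC") +
    floor(stats::runif(n, 0, 86400)) # whole seconds: ISO-8601 round-trips exactly
  ord <- order(day_idx, created_at)
  created_at <- created_at[ord]
  sentiment <- sentiment[ord]
  relevance <- relevance[ord]
  organism <- organism[ord]

  text <- .generate_text(sentiment, relevance, organism, config$hashtag_vocab)

  # duplicates reference a same-day original and copy it verbatim
  id <- sprintf("t%07d", seq_len(n))
  duplicate_of <- rep(NA_character_, n)
  day_start <- rep.int(cumsum(c(1L, n_day[-nd]))[n_day > 0] - 0L, n_day[n_day > 0])
  pos_in_day <- seq_len(n) - day_start + 1L
  is_dup <- stats::runif(n) < config$duplicate_rate & pos_in_day > 1L
  if (any(is_dup)) {
    orig_pos <- floor(stats::runif(n) * (pos_in_day - 1L)) + 1L
    root <- seq_len(n)
    for (i in which(is_dup)) {
      o <- day_start[i] + orig_pos[i] - 1L
      root[i] <- root[o]
    }
    dup <- which(root != seq_len(n))
    text[dup] <- text[root[dup]]
    sentiment[dup] <- sentiment[root[dup]]
    relevance[dup] <- relevance[root[dup]]
    organism[dup] <- organism[root[dup]]
    duplicate_of[dup] <- id[root[dup]]
  }

  tibble::tibble(
    id = id, created_at = created_at, text = text,
    duplicate_of = duplicate_of, hashtags = extract_hashtags(text),
    true_relevance = relevance, true_sentiment = sentiment,
    true_organism = organism
  )
}

.generate_text <- function(sentiment, relevance, organism, hashtag_vocab) {
  n <- length(sentiment)
  v <- .gen_vocab

  cue <- .sample_by_group(sentiment, v[c("positive", "negative", "neutral")])
  topic1 <- v$topic[sample.int(length(v$topic), n, replace = TRUE)]
  topic2 <- v$topic[sample.int(length(v$topic), n, replace = TRUE)]
  org_word <- .sample_by_group(organism, v$organism)

  n_fill <- sample.int(4L, n, replace = TRUE) + 1L
  fill <- .paste_groups(
    v$filler[sample.int(length(v$filler), sum(n_fill), replace = TRUE)], n_fill, n
  )

  body <- paste("crispr", cue, topic1, ifelse(nzchar(org_word), org_word, topic2), fill)
  off <- relevance == "not_relevant"
  if (any(off)) {
    k <- sum(off)
    body[off] <- paste(
      v$offtopic[sample.int(length(v$offtopic), k, replace = TRUE)], cue[off],
      v$offtopic[sample.int(length(v$offtopic), k, replace = TRUE)], fill[off]
    )
  }
  # a slice of low-content posts exercises the content-word filter downstream
  short <- stats::runif(n) < 0.05 & !off
  if (any(short)) {
    k <- sum(short)
    body[short] <- paste(
      "crispr", v$interjection[sample.int(length(v$interjection), k, replace = TRUE)]
    )
  }

  tags <- .generate_hashtags(sentiment, off, hashtag_vocab)
  handle <- ifelse(stats::runif(n) < 0.10, sprintf("@user%04d ", sample.int(9999L, n, replace = TRUE)), "")
  url <- ifelse(stats::runif(n) < 0.15, sprintf(" https://t.co/%06d", sample.int(999999L, n, replace = TRUE)), "")
  stringr::str_squish(paste0(handle, body, tags, url))
}

.generate_hashtags <- function(sentiment, off, vocab) {
  n <- length(sentiment)
  out <- rep("", n)
  if (is.null(vocab) || nrow(vocab) == 0) return(out)
  k <- sample(0:2, n, replace = TRUE, prob = c(0.45, 0.40, 0.15))
  k[off] <- 0L
  w <- sentiment_weight(sentiment)
  draw <- function(idx) {
    tag <- character(length(idx))
    for (wt in unique(w[idx])) {
      sub <- idx[w[idx] == wt]
      pr <- vocab$weight * exp(vocab$sentiment_shift * wt)
      tag[w[idx] == wt] <- sample(vocab$tag, length(sub), replace = TRUE, prob = pr)
    }
    tag
  }
  one <- which(k >= 1)
  if (length(one)) {
    t1 <- draw(one)
    out[one] <- paste0(" ", t1)
    two <- which(k == 2)
    if (length(two)) {
      t2 <- draw(two)
      keep <- t2 != t1[match(two, one)]
      out[two[keep]] <- paste0(out[two[keep]], " ", t2[keep])
    }
  }
  out
}
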