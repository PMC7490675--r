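# Small in-code fixtures shared across test files.

make_records <- function(texts,
                         created_at = seq(as.POSIXct("2018-01-01 12:00:00", tz = "UTC"),
                                          by = "1 day", length.out = length(texts)),
                         duplicate_of = rep(NA_character_, length(texts)),
                         ids = sprintf("t%03d", seq_along(texts))) {
  tibble::tibble(
    id = ids, created_at = created_at, text = texts,
    duplicate_of = duplicate_of, hashtags = extract_hashtags(texts)
  )
}

make_labeled <- function(sentiments,
                         organisms = rep("humans", length(sentiments)),
                         created_at = seq(as.POSIXct("2018-01-01 12:00:00", tz = "UTC"),
                                          by = "1 day", length.out = length(sentiments)),
                         texts = paste("crispr post", seq_along(sentiments))) {
  tibble::tibble(
    id = sprintf("t%03d", seq_along(sentiments)),
    created_at = created_at, text = texts,
    hashtags = extract_hashtags(texts),
    pred_relevance = "relevant",
    pred_sentiment = sentiments, pred_organism = organisms
  )
}

# one annotation row per (tweet, annotator); unasked fields filled neutrally
make_annotations <- function(tweet_id, annotator_id,
                             relevance = rep("relevant", length(tweet_id)),
                             sentiment = rep("neutral", length(tweet_id)),
                             organism = rep("humans", length(tweet_id))) {
  tibble::tibble(tweet_id, annotator_id, relevance, sentiment, organism)
}

small_corpus_config <- function(seed = 1, ...) {
  corpus_config(start_date = "2018-01-01", end_date = "2018-03-31",
                base_rate = 25, trend_slope = 0, events = list(),
                duplicate_rate = 0, irrelevant_rate = 0.05, seed = seed, ...)
}
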