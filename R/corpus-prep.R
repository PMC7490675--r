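#' Anonymize handles and URLs in post text
#'
#' Replaces every Twitter-style handle (`@` followed by word characters) with
#' the placeholder `@<user>` and every URL (`http`/`https` scheme, or a bare
#' `t.co/...` shortener) with `<url>`. All other characters are left
#' untouched. The operation is idempotent, so already-anonymized text passes
#' through unchanged.
#'
#' @param text Character vector of raw post texts.
#' @return Character vector of the same length with placeholders substituted.
#' @export
#' @examples
#' anonymize_text("@alice CRISPR rocks https://t.co/abc")
anonymize_text <- function(text) {
  text <- stringr::str_replace_all(text, stringr::regex("https?://\\S+", ignore_case = TRUE), "<url>")
  text <- stringr::str_replace_all(text, stringr::regex("\\bt\\.co/\\S+", ignore_case = TRUE), "<url>")
  stringr::str_replace_all(text, "@\\w+", "@<user>")
}

#' Tokenize post text
#'
#' Whitespace split, then strip leading/trailing non-alphanumeric characters
#' and case-fold. Placeholder tokens (`@<user>`, `<url>`), mentions, and —
#' unless `keep_hashtags` — hashtag tokens are dropped. This deliberately
#' simple contract keeps word counts deterministic and testable; it is not a
#' tweet-aware tokenizer.
#'
#' @param text Character vector.
#' @param keep_hashtags If `TRUE`, hashtag tokens are kept with their leading
#'   `#` stripped (used by the baseline classifier); if `FALSE` they are
#'   dropped (used for content-word counting).
#' @return A list of character vectors, one per input element.
#' @export
text_tokens <- function(text, keep_hashtags = FALSE) {
  toks <- strsplit(text, "\\s+")
  lapply(toks, function(x) {
    x <- x[!x %in% c("<url>", "@<user>")]
    x <- x[!startsWith(x, "@")]
    if (!keep_hashtags) x <- x[!startsWith(x, "#")]
    x <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", x)
    x <- tolower(x[nzchar(x)])
    x
  })
}

#' Count content words in a post
#'
#' Number of tokens (with multiplicity) that belong to an English `lexicon`
#' and are not stop words. Used as the inclusion criterion for annotation:
#' posts need a minimal amount of real content for a rater to judge relevance
#' and sentiment.
#'
#' @param text Character vector (anonymize first; placeholders never count).
#' @param lexicon Character vector of lowercase words considered "English".
#' @param stopwords Character vector of lowercase stop words.
#' @return Integer vector of content-word counts.
#' @export
#' @examples
#' count_content_words("the gene editing is gene",
#'   lexicon = c("gene", "editing", "is", "the"), stopwords = c("is", "the"))
count_content_words <- function(text, lexicon, stopwords = character()) {
  toks <- text_tokens(text, keep_hashtags = FALSE)
  vapply(toks, function(x) sum(x %in% lexicon & !x %in% stopwords), integer(1))
}

#' Keep posts with enough content words
#'
#' @param records A corpus tibble with a `text` column.
#' @param min_content_words Minimum number of lexicon words (default 3).
#' @param lexicon,stopwords Word lists; default to the packaged fixtures.
#' @return The surviving records, input order preserved.
#' @export
filter_min_words <- function(records, min_content_words = 3,
                             lexicon = default_lexicon(),
                             stopwords = default_stopwords()) {
  stopifnot(min_content_words >= 0)
  n <- count_content_words(records$text, lexicon, stopwords)
  records[n >= min_content_words, , drop = FALSE]
}

#' Remove retweets, quotes, and text duplicates
#'
#' Drops every record whose `duplicate_of` field is set (retweet/quote
#' linkage) and every record whose normalized text — anonymized and
#' whitespace-collapsed, case preserved — already occurred on an earlier
#' record. "Earlier" means smallest `created_at`, ties broken by `id`; the
#' first occurrence is kept. Output preserves input order.
#'
#' @param records A corpus tibble with `id`, `created_at`, `text`, and
#'   optionally `duplicate_of` columns.
#' @return Deduplicated records.
#' @export
deduplicate <- function(records) {
  if (nrow(records) == 0) return(records)
  norm <- stringr::str_squish(anonymize_text(records$text))
  ord <- order(records$created_at, records$id)
  dup_sorted <- duplicated(norm[ord])
  text_dup <- logical(nrow(records))
  text_dup[ord] <- dup_sorted
  linked <- if ("duplicate_of" %in% names(records)) !is.na(records$duplicate_of) else FALSE
  records[!text_dup & !linked, , drop = FALSE]
}

#' Stratified monthly sample of a corpus
#'
#' Bins records by UTC calendar month and draws up to `quota` records
#' uniformly without replacement from each bin (all of them when a bin is
#' smaller than the quota). This yields an annotation sample spread evenly
#' over the observation period instead of oversampling recent activity.
#'
#' @param records Non-empty corpus tibble with `created_at`.
#' @param quota Per-month sample size (>= 1).
#' @param seed Integer RNG seed; the draw is deterministic given the seed.
#' @return Sampled records sorted by `created_at` (ties by `id`).
#' @export
stratified_monthly_sample <- function(records, quota, seed) {
  stopifnot(nrow(records) > 0, quota >= 1)
  month <- format(records$created_at, "%Y-%m", tz = "UTC")
  idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(records)), month), function(i) {
      i[sample.int(length(i), min(quota, length(i)))]
    }), use.names = FALSE)
  })
  out <- records[idx, , drop = FALSE]
  out[order(out$created_at, out$id), , drop = FALSE]
}

#' Extract hashtags from post text
#'
#' Hashtags are the `#`-prefixed tokens of the text, case-folded, with the
#' leading `#` retained.
#'
#' @param text Character vector.
#' @return List of character vectors of lowercase hashtags.
#' @export
#' @examples
#' extract_hashtags("Big news! #CRISPR #GeneEditing")
extract_hashtags <- function(text) {
  stringr::str_extract_all(tolower(text), "#\\w+")
}

#' Packaged word lists
#'
#' A small English lexicon and stop-word list shipped as plain-text fixtures;
#' both are ordinary character vectors and can be swapped for larger corpora
#' via the `lexicon`/`stopwords` arguments of the prep functions.
#'
#' @return Character vector of lowercase words.
#' @export
default_lexicon <- function() {
  readLines(system.file("extdata", "lexicon.txt", package = "sentistream"))
}

#' @rdname default_lexicon
#' @export
default_stopwords <- function() {
  readLines(system.file("extdata", "stopwords.txt", package = "sentistream"))
}
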