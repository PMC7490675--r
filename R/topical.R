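#' Monthly sentiment by organism class
#'
#' Per calendar month and predicted organism class: the number of posts and
#' the mean weighted sentiment (weights +1/0/-1, neutral included). Cells
#' with fewer than `min_cell` posts are flagged `masked` (value retained,
#' rendered transparent in heatmaps) — sparse month/organism cells give
#' unstable means.
#'
#' @param corpus Labeled corpus with `created_at`, `pred_sentiment`,
#'   `pred_organism`.
#' @param min_cell Minimum posts for an unmasked cell (default 100).
#' @return Tibble with `month` (first day of month), `organism`, `n`,
#'   `mean_sentiment`, `masked`.
#' @export
organism_month_matrix <- function(corpus, min_cell = 100) {
  stopifnot(all(c("pred_sentiment", "pred_organism") %in% names(corpus)))
  df <- tibble::tibble(
    month = as.Date(format(corpus$created_at, "%Y-%m-01", tz = "UTC")),
    organism = corpus$pred_organism,
    w = sentiment_weight(corpus$pred_sentiment)
  )
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$month, .data$organism),
    n = dplyr::n(), mean_sentiment = mean(.data$w), .groups = "drop"
  )
  out$masked <- out$n < min_cell
  dplyr::arrange(out, .data$month, .data$organism)
}

#' Yearly top hashtags with sentiment statistics
#'
#' Counts case-folded hashtags per calendar year (a post with several
#' hashtags contributes to each; a tag is counted once per post), drops the
#' exclusion set (by default the overarching topic tag `#crispr`), keeps the
#' `top_k` most frequent tags per year (ties broken lexicographically), and
#' reports the mean and SD of the +1/0/-1 sentiment weights over the posts
#' carrying each selected tag that year.
#'
#' @param corpus Labeled corpus with `created_at`, `pred_sentiment`, and
#'   either a `hashtags` list column or `text` to extract from.
#' @param top_k Tags kept per year (default 15).
#' @param exclude Character vector of tags to drop (default `"#crispr"`).
#' @return Tibble with `year`, `hashtag`, `count`, `mean_sentiment`, `sd`.
#' @export
hashtag_year_stats <- function(corpus, top_k = 15, exclude = "#crispr") {
  tags <- if ("hashtags" %in% names(corpus)) corpus$hashtags else extract_hashtags(corpus$text)
  long <- tibble::tibble(
    year = rep(as.integer(format(corpus$created_at, "%Y", tz = "UTC")), lengths(tags)),
    w = rep(sentiment_weight(corpus$pred_sentiment), lengths(tags)),
    row = rep(seq_len(nrow(corpus)), lengths(tags)),
    hashtag = tolower(unlist(tags))
  )
  long <- dplyr::distinct(long, .data$year, .data$row, .data$hashtag, .keep_all = TRUE)
  long <- long[!long$hashtag %in% tolower(exclude), , drop = FALSE]
  if (nrow(long) == 0) {
    return(tibble::tibble(year = integer(), hashtag = character(),
                          count = integer(), mean_sentiment = numeric(),
                          sd = numeric()))
  }
  stats <- dplyr::summarise(
    dplyr::group_by(long, .data$year, .data$hashtag),
    count = dplyr::n(), mean_sentiment = mean(.data$w),
    sd = ifelse(dplyr::n() > 1, stats::sd(.data$w), 0), .groups = "drop"
  )
  stats <- dplyr::arrange(stats, .data$year, dplyr::desc(.data$count), .data$hashtag)
  top <- dplyr::slice_head(dplyr::group_by(stats, .data$year), n = top_k)
  dplyr::ungroup(top)
}

#' Read a theme table from CSV
#'
#' Themes are configuration, not code: a table of `name`, `pattern` pairs
#' where each pattern is a case-insensitive regular expression standing for a
#' theme of public discourse. Validates that names are unique and every
#' pattern compiles.
#'
#' @param path CSV file with columns `name`, `pattern`. Defaults to the
#'   packaged illustrative set (six stems: genome, baby, disease, embryo,
#'   treatment, mutation).
#' @return Tibble with `name`, `pattern`.
#' @export
read_themes <- function(path = system.file("extdata", "themes.csv",
                                           package = "sentistream")) {
  themes <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  validate_themes(themes)
}

#' @rdname read_themes
#' @param themes Tibble with `name` and `pattern` columns.
#' @export
validate_themes <- function(themes) {
  stopifnot(all(c("name", "pattern") %in% names(themes)))
  if (anyDuplicated(themes$name)) stop("theme names must be unique", call. = FALSE)
  for (i in seq_len(nrow(themes))) {
    ok <- tryCatch(
      { grepl(themes$pattern[i], "", ignore.case = TRUE, perl = TRUE); TRUE },
      condition = function(c) FALSE
    )
    if (!ok) {
      stop(sprintf("theme `%s`: pattern does not compile", themes$name[i]),
           call. = FALSE)
    }
  }
  tibble::as_tibble(themes[, c("name", "pattern")])
}

#' Match theme regexes against a corpus
#'
#' Case-insensitive search of every theme pattern against the anonymized
#' post text; a post may match any number of themes.
#'
#' @param corpus Corpus tibble with `id` and `text`.
#' @param themes Theme tibble (`name`, `pattern`), see [read_themes()].
#' @return Tidy tibble with one row per (post, theme): `tweet_id`, `theme`,
#'   `matched` (logical).
#' @export
match_themes <- function(corpus, themes) {
  themes <- validate_themes(themes)
  text <- anonymize_text(corpus$text)
  flags <- lapply(seq_len(nrow(themes)), function(i) {
    tibble::tibble(
      tweet_id = corpus$id,
      theme = themes$name[i],
      matched = stringr::str_detect(
        text, stringr::regex(themes$pattern[i], ignore_case = TRUE))
    )
  })
  dplyr::bind_rows(flags)
}

#' Yearly theme counts by sentiment, with partial-year extrapolation
#'
#' Counts theme matches per (year, theme, sentiment class). When the final
#' year of the corpus is only partially observed, its counts are scaled by
#' `12 / months_observed` and reported as reals, so partial years are
#' comparable to full ones.
#'
#' @param flags Output of [match_themes()].
#' @param corpus Labeled corpus with `id`, `created_at`, `pred_sentiment`.
#' @param months_observed_final_year Months observed in the final year, in
#'   `[1, 12]`; 12 means no extrapolation.
#' @return Tibble with `year`, `theme`, `sentiment`, `n_observed`, `n`
#'   (extrapolated count, real-valued).
#' @export
theme_year_counts <- function(flags, corpus, months_observed_final_year = 12) {
  m <- months_observed_final_year
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m > 12) {
    stop("months_observed_final_year must be in [1, 12]", call. = FALSE)
  }
  meta <- tibble::tibble(
    tweet_id = corpus$id,
    year = as.integer(format(corpus$created_at, "%Y", tz = "UTC")),
    sentiment = corpus$pred_sentiment
  )
  hits <- dplyr::inner_join(flags[flags$matched, , drop = FALSE], meta, by = "tweet_id")
  out <- dplyr::summarise(
    dplyr::group_by(hits, .data$year, .data$theme, .data$sentiment),
    n_observed = dplyr::n(), .groups = "drop"
  )
  final_year <- max(meta$year)
  out$n <- out$n_observed * ifelse(out$year == final_year, 12 / m, 1)
  dplyr::arrange(out, .data$year, .data$theme, .data$sentiment)
}
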