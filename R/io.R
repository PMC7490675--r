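#' Read and write tweet corpora as JSONL
#'
#' One JSON object per line with canonical field order: `id`, `created_at`
#' (ISO-8601 UTC, whole seconds), `text`, `duplicate_of`, then any truth
#' (`true_*`) and prediction (`pred_*`) columns present. The `hashtags` list
#' column is derived from `text` and therefore re-extracted on read rather
#' than stored. `write` then `read` then `write` is byte-stable.
#'
#' @param path File path.
#' @return `read_corpus` returns a corpus tibble.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(
      id = character(), created_at = as.POSIXct(character(), tz = "UTC"),
      text = character(), duplicate_of = character(), hashtags = list()
    ))
  }
  bad <- which(!vapply(lines, jsonlite::validate, logical(1), USE.NAMES = FALSE))
  if (length(bad)) {
    stop(sprintf("malformed JSON at line %d of %s", bad[1], path), call. = FALSE)
  }
  df <- jsonlite::stream_in(textConnection(lines), verbose = FALSE)
  if (is.null(df$created_at)) {
    stop(sprintf("missing timestamp at line 1 of %s", path), call. = FALSE)
  }
  ts <- as.POSIXct(df$created_at, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  if (anyNA(ts)) {
    stop(sprintf("missing or unparseable timestamp at line %d of %s",
                 which(is.na(ts))[1], path), call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  out$created_at <- ts
  if (is.null(out$duplicate_of)) out$duplicate_of <- NA_character_
  out$hashtags <- extract_hashtags(out$text)
  cols <- c("id", "created_at", "text", "duplicate_of", "hashtags")
  out[, c(cols, setdiff(names(out), cols))]
}

#' @rdname read_corpus
#' @param records Corpus tibble.
#' @export
write_corpus <- function(records, path) {
  df <- as.data.frame(records[, setdiff(names(records), "hashtags")])
  df$created_at <- format(df$created_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  lead <- intersect(c("id", "created_at", "text", "duplicate_of"), names(df))
  df <- df[, c(lead, setdiff(names(df), lead)), drop = FALSE]
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE, na = "null", digits = NA)
  invisible(path)
}

#' Read / write annotation sets as CSV
#'
#' Long format: `tweet_id`, `annotator_id`, `relevance`, `sentiment`,
#' `organism`.
#'
#' @param path File path.
#' @param annotations Annotation tibble.
#' @return `read_annotations` returns the annotation tibble.
#' @export
read_annotations <- function(path) {
  readr::read_csv(path, col_types = "ccccc", progress = FALSE)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  readr::write_csv(annotations, path)
  invisible(path)
}
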