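#' Per-annotator raw agreement
#'
#' For every annotator, the fraction of actual agreements over possible
#' agreements with co-annotators: each (item, other annotator) pair on a
#' shared item counts as one possible agreement, and it is actual when the
#' two answers coincide. With `question = "all"` the three questions are
#' pooled (each question on each shared item is one comparison).
#'
#' @param annotations Long annotation tibble (`tweet_id`, `annotator_id`,
#'   `relevance`, `sentiment`, `organism`).
#' @param question One of `"relevance"`, `"sentiment"`, `"organism"`,
#'   `"all"`.
#' @return Tibble with one row per annotator: `annotator_id`, `n_tasks`,
#'   `n_possible`, `n_actual`, `raw_agreement` (`NA` when an annotator has no
#'   co-annotated items).
#' @export
raw_agreement <- function(annotations, question = "relevance") {
  question <- match.arg(question, c("relevance", "sentiment", "organism", "all"))
  qs <- if (question == "all") c("relevance", "sentiment", "organism") else question
  long <- tidyr::pivot_longer(
    annotations[, c("tweet_id", "annotator_id", qs)],
    cols = dplyr::all_of(qs), names_to = "question", values_to = "answer"
  )
  pairs <- dplyr::inner_join(long, long, by = c("tweet_id", "question"),
                             relationship = "many-to-many")
  pairs <- dplyr::filter(pairs, .data$annotator_id.x != .data$annotator_id.y)
  agg <- dplyr::summarise(
    dplyr::group_by(pairs, annotator_id = .data$annotator_id.x),
    n_possible = dplyr::n(),
    n_actual = sum(.data$answer.x == .data$answer.y),
    .groups = "drop"
  )
  tasks <- dplyr::summarise(
    dplyr::group_by(annotations, .data$annotator_id),
    n_tasks = dplyr::n_distinct(.data$tweet_id), .groups = "drop"
  )
  out <- dplyr::left_join(tasks, agg, by = "annotator_id")
  out$n_possible[is.na(out$n_possible)] <- 0L
  out$n_actual[is.na(out$n_actual)] <- 0L
  out$raw_agreement <- ifelse(out$n_possible > 0, out$n_actual / out$n_possible, NA_real_)
  dplyr::arrange(out, .data$annotator_id)
}

#' Flag outlier annotators
#'
#' An annotator is an outlier when any of three rules fires: raw agreement
#' farther than `sd_mult` population standard deviations from the mean raw
#' agreement (computed over all annotators with a defined value), fewer than
#' `min_possible` possible agreements, or involvement in fewer than
#' `min_tasks` separate tasks. Screening is a single pass: statistics are not
#' recomputed after removal.
#'
#' @param stats Output of [raw_agreement()].
#' @param sd_mult SD multiplier for the agreement rule (default 3).
#' @param min_possible Minimum possible agreements (default 20).
#' @param min_tasks Minimum separate tasks (default 3).
#' @return Character vector of flagged `annotator_id`s.
#' @export
flag_outlier_annotators <- function(stats, sd_mult = 3, min_possible = 20,
                                    min_tasks = 3) {
  stopifnot(nrow(stats) > 0)
  ra <- stats$raw_agreement
  vals <- ra[!is.na(ra)]
  m <- mean(vals)
  s <- sqrt(mean((vals - m)^2)) # population SD
  dev <- !is.na(ra) & s > 0 & abs(ra - m) > sd_mult * s
  flagged <- dev | stats$n_possible < min_possible | stats$n_tasks < min_tasks
  sort(stats$annotator_id[flagged])
}

#' Fleiss' kappa for fixed-size rater panels
#'
#' Chance-corrected agreement for categorical ratings where each item is
#' rated by the same number of raters:
#' \eqn{\kappa = (\bar{P} - \bar{P_e})/(1 - \bar{P_e})}, with \eqn{\bar{P}}
#' the mean over items of the agreeing-pair fraction
#' \eqn{\sum_j n_{ij}(n_{ij}-1) / (n(n-1))} and
#' \eqn{\bar{P_e} = \sum_j p_j^2} from the overall category proportions.
#' Items whose rater count differs from the modal count are excluded with a
#' warning (the classical statistic assumes fixed \eqn{n}; removing outlier
#' annotators leaves ragged items).
#'
#' @param counts Items-by-categories matrix of rating counts.
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' m <- rbind(c(3, 0, 0), c(2, 1, 0), c(1, 1, 1), c(0, 0, 3))
#' fleiss_kappa(m)
fleiss_kappa <- function(counts) {
  counts <- as.matrix(counts)
  totals <- rowSums(counts)
  if (length(unique(totals)) > 1) {
    tab <- table(totals)
    n_mode <- max(as.numeric(names(tab)[tab == max(tab)])) # ties: larger panel
    warning(sprintf(
      "excluding %d of %d items whose rater count differs from the modal count (%d)",
      sum(totals != n_mode), length(totals), n_mode
    ))
    counts <- counts[totals == n_mode, , drop = FALSE]
    totals <- rowSums(counts)
  }
  n <- totals[1]
  if (nrow(counts) == 0 || is.na(n) || n < 2) {
    stop("fleiss_kappa needs items rated by at least 2 raters", call. = FALSE)
  }
  p_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / sum(counts)
  p_e <- sum(p_j^2)
  if (1 - p_e < 1e-12) {
    stop("degenerate input: all ratings fall in a single category", call. = FALSE)
  }
  (p_bar - p_e) / (1 - p_e)
}

#' Rating-count matrix for one annotation question
#'
#' Tabulates, per item, how many annotators chose each category — the input
#' format of [fleiss_kappa()].
#'
#' @param annotations Long annotation tibble.
#' @param question `"relevance"`, `"sentiment"`, or `"organism"`.
#' @param exclude Annotator ids to drop first (e.g. flagged outliers).
#' @return Integer matrix, items x categories.
#' @export
annotation_counts <- function(annotations, question = "relevance",
                              exclude = character()) {
  question <- match.arg(question, c("relevance", "sentiment", "organism"))
  ann <- annotations[!annotations$annotator_id %in% exclude, , drop = FALSE]
  levels <- switch(question,
    relevance = relevance_levels(),
    sentiment = sentiment_levels(),
    organism = organism_annotation_levels()
  )
  tab <- table(ann$tweet_id, factor(ann[[question]], levels = levels))
  matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
}

#' Unanimity consensus labels
#'
#' After dropping outlier annotators' rows, an item receives a relevance
#' consensus if and only if all its remaining annotations agree and there are
#' at least `min_unanimous` of them. Sentiment and organism consensuses are
#' computed the same way but stored only for items whose relevance consensus
#' is `relevant` (the relevance gate).
#'
#' @param annotations Long annotation tibble.
#' @param outliers Annotator ids to remove first.
#' @param min_unanimous Minimum number of agreeing annotators (default 3).
#' @return Tibble with `tweet_id`, `relevance`, `sentiment`, `organism`
#'   (`NA` where no consensus), and `n_annotators`.
#' @export
consensus_labels <- function(annotations, outliers = character(),
                             min_unanimous = 3) {
  ann <- annotations[!annotations$annotator_id %in% outliers, , drop = FALSE]
  unanimous <- function(x) {
    if (length(x) >= min_unanimous && length(unique(x)) == 1) x[1] else NA_character_
  }
  out <- dplyr::summarise(
    dplyr::group_by(ann, .data$tweet_id),
    n_annotators = dplyr::n(),
    relevance = unanimous(.data$relevance),
    sentiment = unanimous(.data$sentiment),
    organism = unanimous(.data$organism),
    .groups = "drop"
  )
  gate <- !is.na(out$relevance) & out$relevance == "relevant"
  out$sentiment[!gate] <- NA_character_
  out$organism[!gate] <- NA_character_
  out[, c("tweet_id", "relevance", "sentiment", "organism", "n_annotators")]
}
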