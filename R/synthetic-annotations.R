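#' Build a pool of annotator profiles
#'
#' Honest annotators answer each question correctly with probability
#' `accuracy` and otherwise pick a uniformly random wrong label; spammers
#' answer uniformly at random regardless of the truth. `n_tasks_target`
#' weights how often an annotator is drawn for a task.
#'
#' @param n_honest Number of honest annotators.
#' @param accuracy Per-question probability of reporting the true label,
#'   in `[0, 1]`; recycled over honest annotators.
#' @param n_spammers Number of uniform-random annotators.
#' @param n_tasks_target Relative workload weight (recycled).
#' @return Tibble with columns `annotator_id`, `accuracy`, `is_spammer`,
#'   `n_tasks_target`.
#' @export
annotator_pool <- function(n_honest = 15, accuracy = 0.9, n_spammers = 0,
                           n_tasks_target = 1) {
  stopifnot(n_honest >= 0, n_spammers >= 0, all(accuracy >= 0 & accuracy <= 1))
  n <- n_honest + n_spammers
  tibble::tibble(
    annotator_id = c(sprintf("ann%02d", seq_len(n_honest)),
                     if (n_spammers > 0) sprintf("spam%02d", seq_len(n_spammers))),
    accuracy = c(rep_len(accuracy, n_honest), rep(NA_real_, n_spammers)),
    is_spammer = rep(c(FALSE, TRUE), c(n_honest, n_spammers)),
    n_tasks_target = rep_len(n_tasks_target, n)
  )
}

# truth -> answer under the uniform-error model; `levels` is the question's
# full answer set (may exceed the truth set, e.g. "multiple" for organisms)
.answer_question <- function(truth, spam, accuracy, levels) {
  n <- length(truth)
  ans <- character(n)
  correct <- !spam & stats::runif(n) < accuracy
  ans[correct] <- truth[correct]
  wrong <- which(!spam & !correct)
  if (length(wrong)) {
    L <- length(levels)
    m <- match(truth[wrong], levels)
    r <- sample.int(L - 1L, length(wrong), replace = TRUE)
    ans[wrong] <- levels[((m + r - 1L) %% L) + 1L]
  }
  sp <- which(spam)
  if (length(sp)) ans[sp] <- sample(levels, length(sp), replace = TRUE)
  ans
}

#' Simulate crowdsourced annotations of a tweet sample
#'
#' Each record is annotated by exactly `redundancy` distinct annotators drawn
#' from `profiles` (weighted by `n_tasks_target`); every task answers all
#' three questions (relevance, sentiment, organism) under the profile's error
#' model.
#'
#' @param records Tibble with `id` and truth columns `true_relevance`,
#'   `true_sentiment`, `true_organism` (as produced by [generate_corpus()]).
#' @param profiles An [annotator_pool()] tibble.
#' @param redundancy Annotations per record (>= 1); must not exceed the
#'   number of profiles.
#' @param seed Integer RNG seed.
#' @return Long-format annotation tibble with columns `tweet_id`,
#'   `annotator_id`, `relevance`, `sentiment`, `organism`.
#' @export
generate_annotations <- function(records, profiles, redundancy = 3, seed = 1L) {
  stopifnot(redundancy >= 1)
  if (nrow(profiles) < redundancy) {
    stop("fewer annotator profiles than the requested redundancy", call. = FALSE)
  }
  n <- nrow(records)
  withr::with_seed(seed, {
    who <- vapply(
      seq_len(n),
      function(i) sample.int(nrow(profiles), redundancy, prob = profiles$n_tasks_target),
      integer(redundancy)
    )
    who <- as.integer(who) # column-major: redundancy rows per record
    tweet_id <- rep(records$id, each = redundancy)
    spam <- profiles$is_spammer[who]
    acc <- profiles$accuracy[who]
    acc[is.na(acc)] <- 0
    rep_truth <- function(x) rep(x, each = redundancy)
    tibble::tibble(
      tweet_id = tweet_id,
      annotator_id = profiles$annotator_id[who],
      relevance = .answer_question(rep_truth(records$true_relevance), spam, acc,
                                   relevance_levels()),
      sentiment = .answer_question(rep_truth(records$true_sentiment), spam, acc,
                                   sentiment_levels()),
      organism = .answer_question(rep_truth(records$true_organism), spam, acc,
                                  organism_annotation_levels())
    )
  })
}
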