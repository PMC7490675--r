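#' Configuration of an end-to-end pipeline run
#'
#' Aggregates every tunable of the pipeline: corpus source, preparation
#' thresholds, annotation-QC thresholds, analysis parameters, and the single
#' seed from which all stage-level randomness is derived.
#'
#' @param output_dir Directory for run artifacts (created if absent).
#' @param corpus Either a [corpus_config()] (the corpus is simulated) or a
#'   path to a JSONL corpus with truth columns.
#' @param min_content_words Content-word inclusion threshold (default 3).
#' @param monthly_quota Per-month annotation sample size (default 40).
#' @param annotators [annotator_pool()] used to simulate annotation.
#' @param redundancy Annotations per sampled post (default 3).
#' @param sd_mult,min_possible,min_tasks Outlier rules, see
#'   [flag_outlier_annotators()].
#' @param min_unanimous Consensus threshold, see [consensus_labels()].
#' @param window Rolling window in days (odd, default 7).
#' @param rel_prominence_min Peak cut-off (default 0.2).
#' @param min_cell Organism heatmap mask threshold (default 100).
#' @param top_k Hashtags per year (default 15).
#' @param months_observed_final_year Months observed in the final calendar
#'   year, or `NULL` to infer from the corpus end date.
#' @param themes Theme table (default [read_themes()]).
#' @param test_frac Test fraction of the classifier split (default 0.2).
#' @param seed Integer master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(output_dir,
                       corpus = corpus_config(),
                       min_content_words = 3,
                       monthly_quota = 40,
                       annotators = annotator_pool(n_honest = 20, accuracy = 0.9,
                                                   n_spammers = 1),
                       redundancy = 3,
                       sd_mult = 3, min_possible = 20, min_tasks = 3,
                       min_unanimous = 3,
                       window = 7, rel_prominence_min = 0.2,
                       min_cell = 100, top_k = 15,
                       months_observed_final_year = NULL,
                       themes = read_themes(),
                       test_frac = 0.2,
                       seed = 1L) {
  if (window %% 2 == 0 || window < 1) abort_config("window", "must be odd and >= 1")
  for (f in c("min_content_words", "monthly_quota", "redundancy", "sd_mult",
              "min_possible", "min_tasks", "min_unanimous", "min_cell", "top_k")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0) abort_config(f, "must be a non-negative number")
  }
  structure(list(
    output_dir = output_dir, corpus = corpus,
    min_content_words = min_content_words, monthly_quota = monthly_quota,
    annotators = annotators, redundancy = redundancy,
    sd_mult = sd_mult, min_possible = min_possible, min_tasks = min_tasks,
    min_unanimous = min_unanimous, window = window,
    rel_prominence_min = rel_prominence_min, min_cell = min_cell,
    top_k = top_k, months_observed_final_year = months_observed_final_year,
    themes = themes, test_frac = test_frac, seed = as.integer(seed)
  ), class = "run_config")
}

# named substreams derived from the master seed (kept below 2^31)
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

.train_eval <- function(texts, labels, label_set, test_frac, seed) {
  if (length(texts) < 5 || length(unique(labels)) < 1) {
    return(list(model = NULL, eval = NULL))
  }
  split <- train_test_split(length(texts), test_frac, seed)
  model <- train_baseline(texts[split$train], labels[split$train],
                          label_set = label_set)
  pred <- predict(model, texts[split$test])
  list(model = model, eval = macro_f1(labels[split$test], pred, label_set))
}

#' Run the full surveillance pipeline
#'
#' Executes simulation (or corpus loading), preparation (anonymize, filter,
#' deduplicate, monthly-stratified sampling), annotation simulation and QC
#' (raw agreement, outlier screening, Fleiss' kappa, unanimity consensus),
#' baseline classifier training/evaluation, the relevance-gated prediction
#' cascade over the full filtered corpus, the daily sentiment index with
#' trend fit, yearly Welch tests and peak detection, and the topical
#' breakdowns — then writes all artifacts under `config$output_dir` with
#' fixed names (`report.json`, `index.csv`, `peaks.csv`,
#' `organism_month.csv`, `hashtags_year.csv`, `themes_year.csv`,
#' `qc_report.csv`, `consensus.csv`). Identical config and seed reproduce
#' byte-identical outputs. On error the partially written artifacts are
#' removed and the failing stage is named.
#'
#' @param config A [run_config()].
#' @return The run report (also written as `report.json`), invisibly a list
#'   with stage counts, QC summaries, trend fit, peaks, evaluation reports,
#'   and a file manifest with MD5 hashes.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  d0 <- .stage("simulate", {
    if (is.character(config$corpus)) {
      read_corpus(config$corpus)
    } else {
      cc <- config$corpus
      cc$seed <- sub_seed(seed, 1)
      generate_corpus(cc)
    }
  })
  if (nrow(d0) == 0) stop("[stage simulate] empty corpus", call. = FALSE)

  prep <- .stage("prep", {
    d0$text <- anonymize_text(d0$text)
    d1 <- filter_min_words(d0, config$min_content_words)
    if (nrow(d1) == 0) stop("no records survive the content-word filter")
    d2 <- deduplicate(d1)
    s0 <- stratified_monthly_sample(d2, config$monthly_quota, sub_seed(seed, 2))
    list(d1 = d1, d2 = d2, s0 = s0)
  })

  qc <- .stage("qc", {
    a0 <- generate_annotations(prep$s0, config$annotators, config$redundancy,
                               sub_seed(seed, 3))
    stats <- raw_agreement(a0, "all")
    outliers <- flag_outlier_annotators(stats, config$sd_mult,
                                        config$min_possible, config$min_tasks)
    kap <- function(q) {
      tryCatch(
        suppressWarnings(fleiss_kappa(annotation_counts(a0, q, exclude = outliers))),
        error = function(e) NA_real_
      )
    }
    consensus <- consensus_labels(a0, outliers, config$min_unanimous)
    list(a0 = a0, stats = stats, outliers = outliers,
         kappa_relevance = kap("relevance"), kappa_sentiment = kap("sentiment"),
         consensus = consensus)
  })

  models <- .stage("train-eval", {
    labeled <- dplyr::inner_join(qc$consensus, prep$s0[, c("id", "text")],
                                 by = c(tweet_id = "id"))
    rel <- labeled[!is.na(labeled$relevance), ]
    sen <- labeled[!is.na(labeled$sentiment), ]
    org <- labeled[!is.na(labeled$organism), ]
    list(
      relevance = .train_eval(rel$text, rel$relevance, relevance_levels(),
                              config$test_frac, sub_seed(seed, 4)),
      sentiment = .train_eval(sen$text, sen$sentiment, sentiment_levels(),
                              config$test_frac, sub_seed(seed, 5)),
      organism = .train_eval(org$text, org$organism, organism_annotation_levels(),
                             config$test_frac, sub_seed(seed, 6)),
      n_labeled = c(relevance = nrow(rel), sentiment = nrow(sen),
                    organism = nrow(org))
    )
  })

  p2 <- .stage("predict", {
    cascade_predict(models$relevance$model, models$sentiment$model,
                    models$organism$model, prep$d1)
  })
  if (nrow(p2) == 0) stop("[stage predict] no records predicted relevant", call. = FALSE)

  ts <- .stage("analyze-timeseries", {
    daily <- daily_counts(p2)
    index <- sentiment_index(daily, config$window)
    trend <- fit_linear_trend(index, lag = config$window - 1)
    yearly <- tryCatch(yearly_sentiment_tests(p2), error = function(e) NULL)
    pk <- detect_peaks(index$a, config$rel_prominence_min)
    pk$date <- index$date[pk$index]
    list(index = index, trend = trend, yearly = yearly, peaks = pk)
  })

  top <- .stage("analyze-topical", {
    months_obs <- config$months_observed_final_year %||%
      max(as.integer(format(p2$created_at[
        format(p2$created_at, "%Y", tz = "UTC") ==
          max(format(p2$created_at, "%Y", tz = "UTC"))], "%m", tz = "UTC")))
    flags <- match_themes(p2, config$themes)
    list(
      organism = organism_month_matrix(p2, config$min_cell),
      hashtags = hashtag_year_stats(p2, config$top_k),
      themes = theme_year_counts(flags, p2, months_obs),
      months_observed = months_obs
    )
  })

  counts <- list(
    d0 = nrow(d0), d1 = nrow(prep$d1), d2 = nrow(prep$d2), s0 = nrow(prep$s0),
    a0 = nrow(qc$a0),
    a1 = sum(!is.na(qc$consensus$relevance)),
    a2_sentiment = sum(!is.na(qc$consensus$sentiment)),
    a2_organism = sum(!is.na(qc$consensus$organism)),
    p0 = nrow(prep$d1), p1 = nrow(p2)
  )
  stopifnot(counts$d0 >= counts$d1, counts$d1 >= counts$d2)

  .stage("write", {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$output_dir, f)
    csvs <- c("index.csv", "peaks.csv", "organism_month.csv",
              "hashtags_year.csv", "themes_year.csv", "qc_report.csv",
              "consensus.csv")
    on_fail <- function(e) {
      unlink(c(out(csvs), out("report.json")))
      stop(conditionMessage(e), call. = FALSE)
    }
    tryCatch({
      idx <- ts$index
      names(idx) <- c("date", "n_pos", "n_neu", "n_neg", "n_total", "s", "a")
      readr::write_csv(idx, out("index.csv"))
      readr::write_csv(ts$peaks[, c("date", "height", "prominence", "rel_prominence")],
                       out("peaks.csv"))
      readr::write_csv(top$organism, out("organism_month.csv"))
      readr::write_csv(top$hashtags, out("hashtags_year.csv"))
      readr::write_csv(top$themes, out("themes_year.csv"))
      qc_out <- qc$stats
      qc_out$flagged <- qc_out$annotator_id %in% qc$outliers
      readr::write_csv(qc_out, out("qc_report.csv"))
      readr::write_csv(qc$consensus, out("consensus.csv"))

      manifest <- tibble::tibble(
        file = csvs,
        md5 = unname(tools::md5sum(out(csvs)))
      )
      report <- list(
        counts = counts,
        kappa = list(relevance = qc$kappa_relevance, sentiment = qc$kappa_sentiment),
        n_outlier_annotators = length(qc$outliers),
        class_proportions = class_proportions(p2),
        trend = ts$trend[c("slope", "stderr", "intercept", "n")],
        yearly_tests = if (!is.null(ts$yearly)) ts$yearly$tests else NULL,
        peaks = ts$peaks[, c("date", "height", "prominence", "rel_prominence")],
        eval = list(
          relevance = if (!is.null(models$relevance$eval)) models$relevance$eval$macro_f1,
          sentiment = if (!is.null(models$sentiment$eval)) models$sentiment$eval$macro_f1,
          organism = if (!is.null(models$organism$eval)) models$organism$eval$macro_f1
        ),
        months_observed_final_year = top$months_observed,
        config = list(
          min_content_words = config$min_content_words,
          monthly_quota = config$monthly_quota, redundancy = config$redundancy,
          sd_mult = config$sd_mult, min_possible = config$min_possible,
          min_tasks = config$min_tasks, min_unanimous = config$min_unanimous,
          window = config$window,
          rel_prominence_min = config$rel_prominence_min,
          min_cell = config$min_cell, top_k = config$top_k,
          seed = config$seed
        ),
        manifest = manifest
      )
      jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, dataframe = "rows")
      report
    }, error = on_fail)
  })
}
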