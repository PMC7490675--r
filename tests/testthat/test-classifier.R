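test_that("the baseline separates token-disjoint classes on its training set", {
  texts <- c("alpha beta gamma", "alpha beta", "delta epsilon zeta", "delta zeta")
  labels <- c("up", "up", "down", "down")
  m <- train_baseline(texts, labels)
  expect_equal(predict(m, texts), labels)
  expect_equal(predict(m, "beta gamma alpha alpha"), "up")
})

test_that("prediction ties and missing evidence resolve by label_set order", {
  m <- train_baseline(c("aa bb", "cc dd"), c("x", "y"), label_set = c("y", "x"))
  # only unseen tokens, balanced priors: first label of label_set wins
  expect_equal(predict(m, "zz qq"), "y")
  # empty text falls back to the prior; majority class wins
  m2 <- train_baseline(c("aa", "aa bb", "cc"), c("x", "x", "y"))
  expect_equal(predict(m2, ""), "x")
})

test_that("training input is validated", {
  expect_error(train_baseline(character(), character()), "empty")
  expect_error(train_baseline("a b", "lab", label_set = c("other")))
})

test_that("macro F1 agrees with direct confusion-matrix arithmetic", {
  # perfect predictions
  r <- macro_f1(c("a", "b", "a"), c("a", "b", "a"), c("a", "b"))
  expect_equal(r$macro_f1, 1)
  # every binary prediction wrong
  r0 <- macro_f1(c("a", "b"), c("b", "a"), c("a", "b"))
  expect_equal(r0$macro_f1, 0)
  # confusion [[8,2],[3,7]]: P/R/F1 from the printed matrix
  true <- rep(c("a", "b"), c(10, 10))
  pred <- c(rep("a", 8), rep("b", 2), rep("a", 3), rep("b", 7))
  r2 <- macro_f1(true, pred, c("a", "b"))
  p1 <- 8 / 11; r1 <- 8 / 10
  p2 <- 7 / 9;  rr2 <- 7 / 10
  f1a <- 2 * p1 * r1 / (p1 + r1)
  f1b <- 2 * p2 * rr2 / (p2 + rr2)
  expect_equal(unname(r2$per_class$f1), c(f1a, f1b), tolerance = 1e-12)
  expect_equal(r2$macro_f1, mean(c(f1a, f1b)), tolerance = 1e-12)
  expect_equal(unname(rowSums(r2$confusion)), c(10, 10))
})

test_that("macro F1 is permutation-invariant and validates lengths", {
  withr::with_seed(8, {
    true <- sample(c("a", "b", "c"), 60, replace = TRUE)
    pred <- sample(c("a", "b", "c"), 60, replace = TRUE)
    perm <- sample.int(60)
    expect_equal(macro_f1(true, pred, c("a", "b", "c"))$macro_f1,
                 macro_f1(true[perm], pred[perm], c("a", "b", "c"))$macro_f1)
  })
  expect_error(macro_f1(c("a", "b"), "a", c("a", "b")), "length")
  # absent class contributes F1 = 0 to the macro average
  r <- macro_f1(c("a", "a"), c("a", "a"), c("a", "b"))
  expect_equal(r$macro_f1, 0.5)
})

test_that("the cascade gates sentiment and organism behind relevance", {
  rel_texts <- c(rep("crispr topic words", 7), rep("offtopic chatter stuff", 3))
  rel_model <- train_baseline(rel_texts, rep(c("relevant", "not_relevant"), c(7, 3)))
  sent_model <- train_baseline(c("good crispr", "bad crispr"), c("positive", "negative"))
  org_model <- train_baseline(c("crispr patients", "crispr crops"), c("humans", "plants"))
  rec <- make_records(rel_texts)
  out <- cascade_predict(rel_model, sent_model, org_model, rec)
  expect_equal(nrow(out), 7L)
  expect_true(all(out$pred_relevance == "relevant"))
  expect_true(all(c("pred_sentiment", "pred_organism") %in% names(out)))
  expect_false(any(rec$id[8:10] %in% out$id))

  # all-relevant and none-relevant extremes
  all_rel <- train_baseline(c("x y", "x z"), c("relevant", "relevant"),
                            label_set = relevance_levels())
  expect_equal(nrow(cascade_predict(all_rel, sent_model, org_model, rec)), 10L)
  none <- train_baseline(c("x y", "x z"), rep("not_relevant", 2),
                         label_set = relevance_levels())
  expect_equal(nrow(cascade_predict(none, sent_model, org_model, rec)), 0L)
  expect_error(cascade_predict(NULL, sent_model, org_model, rec), "untrained")
})

test_that("class proportions use half-up rounding to one decimal", {
  p <- class_proportions(c(positive = 1, neutral = 1, negative = 2))
  expect_equal(p$pct, c(25.0, 25.0, 50.0))
  single <- make_labeled(rep("positive", 5))
  expect_equal(class_proportions(single)$pct, c(100, 0, 0))
  expect_error(class_proportions(make_labeled(character())), "empty")
})

test_that("serialized baselines predict identically after a JSON round trip", {
  x <- generate_corpus(small_corpus_config(seed = 71))
  m <- train_baseline(head(x$text, 200), head(x$true_sentiment, 200),
                      label_set = sentiment_levels())
  path <- withr::local_tempfile(fileext = ".json")
  write_baseline(m, path)
  m2 <- read_baseline(path)
  probe <- x$text[201:300]
  expect_identical(predict(m2, probe), predict(m, probe))
})

test_that("the baseline clears a macro-F1 sanity floor on separable classes", {
  # separability setup: balanced classes, no sentiment-correlated hashtag
  # vocabulary (the default vocabulary deliberately leaks class signal into
  # shared tags, which is realistic but not separable)
  x <- generate_corpus(corpus_config(start_date = "2018-01-01",
                                     end_date = "2018-06-30", base_rate = 10,
                                     class_probs = c(positive = 1 / 3,
                                                     neutral = 1 / 3,
                                                     negative = 1 / 3),
                                     hashtag_vocab = default_hashtag_vocab()[0, ],
                                     trend_slope = 0, events = list(),
                                     duplicate_rate = 0, seed = 81))
  x <- x[x$true_relevance == "relevant", ]
  # the content-word filter runs before training in the pipeline; the
  # low-content posts it removes carry no class-indicative tokens
  x <- filter_min_words(x, 3)
  stopifnot(min(table(x$true_sentiment)) >= 50)
  split <- train_test_split(nrow(x), 0.2, seed = 3)
  m <- train_baseline(x$text[split$train], x$true_sentiment[split$train],
                      label_set = sentiment_levels())
  r <- macro_f1(x$true_sentiment[split$test], predict(m, x$text[split$test]),
                sentiment_levels())
  expect_gte(r$macro_f1, 0.95)
})
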