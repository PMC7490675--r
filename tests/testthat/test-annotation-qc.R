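test_that("raw agreement enumerates pairwise comparisons on shared items", {
  # one tweet, A=positive, B=positive, C=negative
  ann <- make_annotations(rep("tw1", 3), c("A", "B", "C"),
                          sentiment = c("positive", "positive", "negative"))
  st <- raw_agreement(ann, "sentiment")
  a <- st[st$annotator_id == "A", ]
  expect_equal(a$n_possible, 2L)
  expect_equal(a$n_actual, 1L)
  expect_equal(a$raw_agreement, 0.5)
  expect_equal(st$raw_agreement[st$annotator_id == "C"], 0)

  # annotator with no co-annotated tweets has undefined agreement
  ann2 <- rbind(ann, make_annotations("tw2", "D"))
  st2 <- raw_agreement(ann2, "sentiment")
  d <- st2[st2$annotator_id == "D", ]
  expect_equal(d$n_possible, 0L)
  expect_true(is.na(d$raw_agreement))

  # perfect agreement on every shared tweet
  ann3 <- make_annotations(rep(c("tw1", "tw2"), each = 3),
                           rep(c("A", "B", "C"), 2))
  expect_true(all(raw_agreement(ann3, "relevance")$raw_agreement == 1))
})

test_that("summed actual agreements count each agreeing pair exactly twice", {
  x <- generate_corpus(small_corpus_config(seed = 21))
  ann <- generate_annotations(head(x, 60), annotator_pool(6, 0.8), 3, seed = 2)
  for (q in c("relevance", "sentiment", "organism", "all")) {
    st <- raw_agreement(ann, q)
    expect_equal(sum(st$n_actual) %% 2, 0)
    expect_equal(sum(st$n_possible) %% 2, 0)
  }
})

test_that("outlier rules flag low-volume and deviant annotators", {
  ra <- c(0.89, 0.90, 0.91, 0.90, 0.89, 0.91, 0.90, 0.90, 0.89, 0.91, 0.20)
  st <- tibble::tibble(
    annotator_id = c(letters[1:10], "dev"),
    n_tasks = c(50L, 2L, rep(50L, 9)),
    n_possible = c(100L, 100L, 19L, rep(100L, 8)),
    n_actual = as.integer(round(ra * n_possible)),
    raw_agreement = ra
  )
  # the deviant sits > 3 population SDs below the mean
  stopifnot(abs(ra[11] - mean(ra)) > 3 * sqrt(mean((ra - mean(ra))^2)))
  fl <- flag_outlier_annotators(st)
  expect_true("b" %in% fl) # fewer than 3 tasks
  expect_true("c" %in% fl) # fewer than 20 possible agreements
  expect_true("dev" %in% fl) # agreement too far from the mean
  expect_false("a" %in% fl)
  expect_setequal(fl, c("b", "c", "dev"))

  # zero spread, enough volume: nobody is flagged
  st0 <- tibble::tibble(
    annotator_id = letters[1:4], n_tasks = 10L, n_possible = 30L,
    n_actual = 24L, raw_agreement = 0.8
  )
  expect_length(flag_outlier_annotators(st0), 0)

  # undefined agreement is caught by the min_possible rule
  st_na <- rbind(st0, tibble::tibble(annotator_id = "z", n_tasks = 5L,
                                     n_possible = 0L, n_actual = 0L,
                                     raw_agreement = NA_real_))
  expect_equal(flag_outlier_annotators(st_na), "z")
})

test_that("fleiss kappa matches hand arithmetic and handles degeneracies", {
  m <- rbind(c(3, 0, 0), c(2, 1, 0), c(1, 1, 1), c(0, 0, 3))
  expect_equal(fleiss_kappa(m), 7 / 22, tolerance = 1e-12)
  expect_equal(fleiss_kappa(m), fleiss_oracle(m), tolerance = 1e-12)

  # unanimity across several categories is perfect agreement
  uni <- rbind(c(3, 0), c(0, 3), c(3, 0))
  expect_equal(fleiss_kappa(uni), 1)

  # all ratings in one category: chance agreement is total, kappa undefined
  expect_error(fleiss_kappa(rbind(c(3, 0), c(3, 0))), "degenerate")

  # ragged rater counts: off-modal rows are excluded with a warning
  # (modal-count ties resolve to the larger panel: the 3-rater rows here)
  ragged <- rbind(c(3, 0), c(0, 3), c(1, 1), c(2, 0))
  expect_warning(k <- fleiss_kappa(ragged), "modal")
  expect_equal(k, fleiss_kappa(rbind(c(3, 0), c(0, 3))))
})

test_that("fleiss kappa equals the pair-enumeration oracle on random panels", {
  withr::with_seed(42, {
    for (rep in 1:50) {
      counts <- t(stats::rmultinom(5, size = 3, prob = stats::runif(3) + 0.1))
      if (sum(colSums(counts) > 0) < 2) next
      expect_equal(fleiss_kappa(counts), fleiss_oracle(counts), tolerance = 1e-12)
    }
  })
})

test_that("consensus requires unanimity of at least three remaining annotators", {
  ann <- make_annotations(
    rep(c("tw1", "tw2", "tw3"), times = c(3, 2, 4)),
    c("A", "B", "C", "A", "B", "A", "B", "C", "D"),
    relevance = c(rep("relevant", 3), rep("relevant", 2),
                  c("relevant", "relevant", "relevant", "not_relevant"))
  )
  out <- consensus_labels(ann)
  expect_equal(out$relevance[out$tweet_id == "tw1"], "relevant")
  expect_true(is.na(out$relevance[out$tweet_id == "tw2"])) # only 2 annotators
  expect_true(is.na(out$relevance[out$tweet_id == "tw3"])) # 3-1 is not unanimous

  # outlier removal can demote a tweet below the threshold
  out2 <- consensus_labels(ann, outliers = "C")
  expect_true(is.na(out2$relevance[out2$tweet_id == "tw1"]))
})

test_that("sentiment and organism are only stored behind the relevance gate", {
  ann <- make_annotations(
    rep(c("tw1", "tw2"), each = 3), rep(c("A", "B", "C"), 2),
    relevance = c(rep("relevant", 3), rep("not_relevant", 3)),
    sentiment = rep("positive", 6), organism = rep("plants", 6)
  )
  out <- consensus_labels(ann)
  expect_equal(out$sentiment[out$tweet_id == "tw1"], "positive")
  expect_equal(out$organism[out$tweet_id == "tw1"], "plants")
  expect_equal(out$relevance[out$tweet_id == "tw2"], "not_relevant")
  expect_true(is.na(out$sentiment[out$tweet_id == "tw2"]))
  expect_true(is.na(out$organism[out$tweet_id == "tw2"]))

  # property: never a gated label without a `relevant` consensus
  x <- generate_corpus(small_corpus_config(seed = 31))
  ann2 <- generate_annotations(head(x, 80), annotator_pool(6, 0.7), 3, seed = 5)
  out2 <- consensus_labels(ann2)
  gated <- !is.na(out2$sentiment) | !is.na(out2$organism)
  expect_true(all(out2$relevance[gated] == "relevant"))
})

test_that("removing a uniform spammer does not decrease kappa on average", {
  x <- generate_corpus(small_corpus_config(seed = 61))
  sample_x <- head(x, 80)
  pool <- annotator_pool(n_honest = 8, accuracy = 0.85, n_spammers = 1)
  deltas <- vapply(1:50, function(i) {
    ann <- generate_annotations(sample_x, pool, 3, seed = 700 + i)
    with_sp <- suppressWarnings(fleiss_kappa(annotation_counts(ann, "sentiment")))
    without <- suppressWarnings(
      fleiss_kappa(annotation_counts(ann, "sentiment", exclude = "spam01"))
    )
    without - with_sp
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})
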