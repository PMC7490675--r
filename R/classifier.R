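#' Train the multinomial bag-of-words baseline classifier
#'
#' A self-contained multinomial token-count scorer filling the classifier
#' slots of the prediction cascade: the score of class \eqn{c} for a document
#' is the log prior plus, for each token present in the training vocabulary,
#' \eqn{\log\{(\mathrm{count}(t, c) + \alpha) / (\mathrm{total}(c) + \alpha V)\}}
#' with smoothing \eqn{\alpha} and vocabulary size \eqn{V}. Prediction is the
#' arg-max score; ties break by `label_set` order. Tokens unseen in training
#' carry no evidence. The contract is pluggable: any object with a `predict`
#' method returning one label per text (e.g. an external neural model's
#' output wrapper) can stand in the cascade.
#'
#' @param texts Character vector of training documents.
#' @param labels Character vector of training labels (same length).
#' @param smoothing Additive smoothing constant (default 1).
#' @param label_set Ordered label vector; defaults to the sorted unique
#'   training labels. Every training label must be in it.
#' @return A `baseline_classifier` object.
#' @export
train_baseline <- function(texts, labels, smoothing = 1,
                           label_set = sort(unique(labels))) {
  if (length(texts) == 0) stop("empty training set", call. = FALSE)
  stopifnot(length(texts) == length(labels), all(labels %in% label_set))
  toks <- text_tokens(texts, keep_hashtags = TRUE)
  vocab <- sort(unique(unlist(toks)))
  doc_lab <- factor(rep(labels, lengths(toks)), levels = label_set)
  tok <- factor(unlist(toks), levels = vocab)
  counts <- if (length(vocab)) {
    m <- table(tok, doc_lab)
    matrix(as.numeric(m), nrow = length(vocab),
           dimnames = list(vocab, label_set))
  } else {
    matrix(0, 0, length(label_set), dimnames = list(NULL, label_set))
  }
  structure(list(
    label_set = label_set,
    vocab = vocab,
    token_counts = counts,
    class_counts = as.numeric(table(factor(labels, levels = label_set))),
    smoothing = smoothing
  ), class = "baseline_classifier")
}

#' @export
predict.baseline_classifier <- function(object, texts, ...) {
  n <- length(texts)
  K <- length(object$label_set)
  log_prior <- log(object$class_counts / sum(object$class_counts))
  totals <- colSums(object$token_counts)
  V <- length(object$vocab)
  logp <- log(sweep(object$token_counts + object$smoothing, 2,
                    totals + object$smoothing * V, "/"))
  scores <- matrix(log_prior, n, K, byrow = TRUE)
  toks <- text_tokens(texts, keep_hashtags = TRUE)
  doc <- rep.int(seq_len(n), lengths(toks))
  m <- match(unlist(toks), object$vocab)
  keep <- !is.na(m)
  if (any(keep)) {
    contrib <- rowsum(logp[m[keep], , drop = FALSE], group = doc[keep])
    rows <- as.integer(rownames(contrib))
    scores[rows, ] <- scores[rows, , drop = FALSE] + contrib
  }
  object$label_set[max.col(scores, ties.method = "first")]
}

#' Serialize / restore a baseline classifier as JSON
#'
#' @param model A `baseline_classifier`.
#' @param path File path.
#' @return `read_baseline` returns the restored model.
#' @export
write_baseline <- function(model, path) {
  counts_by_class <- lapply(seq_along(model$label_set),
                            function(j) unname(model$token_counts[, j]))
  jsonlite::write_json(list(
    label_set = model$label_set, vocab = model$vocab,
    token_counts = counts_by_class,
    class_counts = model$class_counts, smoothing = model$smoothing
  ), path, digits = NA)
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  label_set <- unlist(x$label_set)
  vocab <- as.character(unlist(x$vocab))
  counts <- matrix(0, length(vocab), length(label_set),
                   dimnames = list(vocab, label_set))
  for (j in seq_along(label_set)) counts[, j] <- unlist(x$token_counts[[j]])
  structure(list(
    label_set = label_set, vocab = vocab, token_counts = counts,
    class_counts = unlist(x$class_counts), smoothing = unlist(x$smoothing)
  ), class = "baseline_classifier")
}

#' Macro-averaged F1 evaluation
#'
#' Per-class precision, recall, and F1 from the confusion matrix, plus the
#' unweighted macro average over `label_set`. A class with no predicted and
#' no true instances (or zero precision and recall) contributes F1 = 0, which
#' keeps the macro average defined on small test splits.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param label_set Ordered label vector covering both.
#' @return An `eval_report` list: `confusion` (true x predicted), `per_class`
#'   tibble, `macro_f1`.
#' @export
macro_f1 <- function(true_labels, predicted_labels, label_set) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("true and predicted label vectors differ in length", call. = FALSE)
  }
  stopifnot(all(true_labels %in% label_set), all(predicted_labels %in% label_set))
  confusion <- table(
    true = factor(true_labels, levels = label_set),
    predicted = factor(predicted_labels, levels = label_set)
  )
  tp <- diag(confusion)
  prec <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), 0)
  rec <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(
    confusion = confusion,
    per_class = tibble::tibble(label = label_set, precision = unname(prec),
                               recall = unname(rec), f1 = unname(f1)),
    macro_f1 = mean(f1)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("macro-F1: %.3f\n", x$macro_f1))
  print(x$per_class)
  invisible(x)
}

#' Relevance-gated prediction cascade
#'
#' Predicts relevance on every record, removes records predicted
#' `not_relevant`, and predicts sentiment and organism only on the
#' survivors — so topic-specific labels are never attached to off-topic
#' posts.
#'
#' @param relevance_model,sentiment_model,organism_model Trained classifiers
#'   (any object with a `predict(object, texts)` method).
#' @param records Corpus tibble with a `text` column.
#' @return The surviving records with `pred_relevance`, `pred_sentiment`,
#'   `pred_organism` columns appended.
#' @export
cascade_predict <- function(relevance_model, sentiment_model, organism_model,
                            records) {
  for (m in list(relevance_model, sentiment_model, organism_model)) {
    if (is.null(m) || !is.object(m)) stop("untrained or missing model", call. = FALSE)
  }
  rel <- predict(relevance_model, records$text)
  out <- records[rel == "relevant", , drop = FALSE]
  out$pred_relevance <- "relevant"
  out$pred_sentiment <- if (nrow(out)) predict(sentiment_model, out$text) else character()
  out$pred_organism <- if (nrow(out)) predict(organism_model, out$text) else character()
  out
}

#' Sentiment class proportions of a labeled corpus
#'
#' Percentage of each sentiment class, rounded half-up to one decimal.
#' Accepts either a labeled corpus (counts its `pred_sentiment` column) or a
#' named vector of class counts.
#'
#' @param x Labeled corpus tibble or named numeric count vector.
#' @return Tibble with `label`, `n`, `pct`.
#' @export
#' @examples
#' class_proportions(c(positive = 685578, neutral = 528196, negative = 97770))
class_proportions <- function(x) {
  counts <- if (is.numeric(x)) {
    x
  } else {
    if (nrow(x) == 0) stop("empty corpus", call. = FALSE)
    c(table(factor(x$pred_sentiment, levels = sentiment_levels())))
  }
  total <- sum(counts)
  if (total == 0) stop("empty corpus", call. = FALSE)
  tibble::tibble(
    label = names(counts),
    n = as.numeric(counts),
    pct = round_half_up(100 * as.numeric(counts) / total, 1)
  )
}

#' Shuffled train/test split
#'
#' 80/20 split after shuffling with a fixed seed, mirroring the evaluation
#' protocol used for the classifier slots.
#'
#' @param n Number of examples.
#' @param test_frac Test fraction (default 0.2).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(n, test_frac = 0.2, seed = 1L) {
  stopifnot(n >= 2, test_frac > 0, test_frac < 1)
  withr::with_seed(seed, {
    perm <- sample.int(n)
    n_test <- max(1L, round(n * test_frac))
    list(test = sort(perm[seq_len(n_test)]), train = sort(perm[-seq_len(n_test)]))
  })
}
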