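# Independent brute-force oracles. These re-derive each statistic from first
# principles (pair enumeration, exhaustive window sums, textbook formulas)
# and deliberately share no code with the implementations they check.

# Fleiss' kappa by explicit pair enumeration: expand each item's counts to a
# vector of rater labels, count agreeing unordered pairs among raters.
fleiss_oracle <- function(counts) {
  n <- rowSums(counts)[1]
  agree_frac <- apply(counts, 1, function(row) {
    labels <- rep(seq_along(row), row)
    pairs <- utils::combn(length(labels), 2)
    mean(labels[pairs[1, ]] == labels[pairs[2, ]])
  })
  p_j <- colSums(counts) / sum(counts)
  p_e <- sum(p_j^2)
  (mean(agree_frac) - p_e) / (1 - p_e)
}

# Sentiment index by explicit window loops.
index_oracle <- function(n_pos, n_neg, n_total, window = 7) {
  half <- (window - 1) / 2
  n <- length(n_pos)
  s <- rep(NA_real_, n)
  a <- numeric(n)
  for (d in seq_len(n)) {
    w <- max(1, d - half):min(n, d + half)
    P <- sum(n_pos[w]); N <- sum(n_neg[w])
    if (P + N > 0) s[d] <- (P - N) / (P + N)
    a[d] <- mean(n_total[w])
  }
  list(s = s, a = a)
}

# Topographic prominence by scanning all lower bounds between each peak and
# its nearest strictly higher ground (or the series ends).
peak_oracle <- function(v, rel_min = 0.2) {
  n <- length(v)
  is_peak <- function(i) {
    if (i == 1 || i == n) return(FALSE)
    if (v[i] <= v[i - 1]) return(FALSE) # leftmost plateau index rises into i
    j <- i + 1
    while (j <= n && v[j] == v[i]) j <- j + 1
    j <= n && v[j] < v[i]
  }
  idx <- Filter(is_peak, seq_len(n))
  prom <- vapply(idx, function(i) {
    h <- v[i]
    left <- v[seq_len(i - 1)]
    hi <- which(left > h)
    lmin <- if (length(hi)) min(left[(max(hi) + 1):(i - 1)]) else min(left)
    right <- v[(i + 1):n]
    hi <- which(right > h)
    rmin <- if (length(hi)) min(right[seq_len(min(hi) - 1)]) else min(right)
    h - max(lmin, rmin)
  }, numeric(1))
  rel <- prom / (max(v) - min(v))
  data.frame(index = unlist(idx), prominence = prom,
             rel_prominence = rel)[rel >= rel_min, , drop = FALSE]
}

# Welch's t from the textbook formulas (statistic, Welch-Satterthwaite df,
# two-sided p from the t survival function).
welch_oracle <- function(a, b) {
  va <- stats::var(a); vb <- stats::var(b)
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
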