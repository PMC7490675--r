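---
title: "Methods: sentiment surveillance of a social-media stream"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sentiment surveillance of a social-media stream}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Public perception of a fast-moving biomedical topic — here, genome editing —
can be monitored at scale by classifying the sentiment of every post in a
long-running social-media stream ("infoveillance"). The analytic chain is
long: raw posts must be anonymized, filtered for minimal content, and
deduplicated; a stratified sample must be labelled by crowdworkers whose
reliability varies; classifiers trained on the cleaned labels must be applied
behind a relevance gate; and the resulting labelled stream must be condensed
into a temporal sentiment index, trend and event statistics, and topical
breakdowns. `sentistream` implements that chain as composable, seeded,
individually tested functions, together with a synthetic stream generator
whose ground truth makes every stage's target recoverable.

```{r setup}
library(sentistream)
```

# The synthetic stream and what it does (not) emulate

`generate_corpus()` draws per-day post counts from a Poisson process with a
base rate multiplied by any active event bursts. Each post carries a hidden
true sentiment from a positive/neutral/negative mixture, a true relevance,
and a true organism class. The defaults describe the surveilled 6.5-year
stream: 2013-01-01 to 2019-05-31, about 644 posts/day, a 52/40/7 class mix
(the proportions observed in the predicted corpus), an index drift of
-0.061 per year, six event bursts at dates of major genome-editing news, a
duplicate share of two thirds (the observed retweet attrition), and 1.7%
off-topic posts (the observed relevance attrition).

Two generative choices matter for interpretation:

* **Drift and events act on the log-odds of the negative class.** The
  expected index $s = (p_+ - p_-)/(p_+ + p_-)$ follows the target line
  exactly (clamped to $(-1, 1)$) by rescaling the negative-class weight and
  renormalizing; this keeps the class vector a valid probability vector for
  any slope or shift magnitude, unlike additive adjustment.
* **Duplicates are same-day verbatim copies.** A retweet burst is
  short-lived; sampling originals uniformly over all history would smear
  early-period labels across the whole series and corrupt an injected trend.
  Duplicates copy text and truth from a same-day original and point at it
  via `duplicate_of`, which makes deduplication exactly testable.

Post text is template prose over a packaged toy lexicon: a topic word,
a sentiment cue word, an organism cue word, fillers, hashtags drawn from a
weighted vocabulary whose tags can lean positive or negative, and occasional
handles and URLs. About 5% of on-topic posts are low-content interjections
that the content-word filter is meant to remove. The generator does **not**
emulate real language (negation, sarcasm, code-switching), user networks,
media, or platform payload schemas. Passing tests therefore demonstrate that
the *pipeline machinery* is correct — filters filter, estimators recover
injected parameters, QC catches planted spammers — not that any particular
classifier will perform well on real text.

Annotators are simulated by `generate_annotations()` under a uniform-error
model: an honest annotator answers each of the three questions (relevance,
sentiment, organism) correctly with probability `accuracy` and otherwise
picks a uniformly random wrong label; a spammer answers uniformly at random.
Real crowdworker error is not uniform (it correlates with item difficulty);
the uniform model is a stated assumption chosen because the QC rules under
test only consume agreement statistics, not error structure.

# Preparation

`anonymize_text()` replaces handles with `@<user>` and URLs with `<url>`,
idempotently. Anonymization runs **before** word counting and deduplication,
so placeholders never count as content words and handle/URL variation never
defeats text dedup.

The tokenizer contract is deliberately simple: whitespace split, strip
leading/trailing non-alphanumerics, case-fold, drop mentions, placeholders
and (for counting) hashtags. A tweet-aware tokenizer would segment emoji and
contractions differently; the simple contract is deterministic and
swappable, and the lexicon and stop-word list are plain-text configuration.

`filter_min_words()` keeps posts with at least 3 lexicon words after
stop-word removal — enough context for a rater to judge relevance and
sentiment. `deduplicate()` drops linked retweets/quotes and any post whose
normalized text already occurred earlier (earliest timestamp wins, ties by
id). `stratified_monthly_sample()` bins by UTC calendar month and draws a
fixed quota per bin; when a bin is smaller than the quota it contributes all
its records, which maximizes the sample without replacement.

# Annotation quality control

Raw agreement is, per annotator, the fraction of (item, co-annotator)
comparisons that agree. An annotator is an outlier if their agreement is more
than 3 **population** standard deviations from the mean (two-sided — the
conservative reading of a one-sided phrasing), if they have fewer than 20
possible agreements, or fewer than 3 tasks. Screening is a single pass;
statistics are not recomputed after removal. By default agreement is
computed on the relevance question; `question = "all"` pools the three
questions, which roughly triples the comparisons per annotator and separates
a uniform spammer (pooled expected agreement about 0.31 against honest
annotators near 0.8) much more sharply than the binary relevance question
alone (0.5). The pooled variant is what the packaged pipeline uses.

Fleiss' kappa assumes a fixed panel size; after outlier removal items are
ragged, so items whose rater count differs from the modal count are excluded
(with a warning; ties resolve to the larger panel). Consensus follows the
strict reading of "unanimous consensus of at least 3": **all remaining**
annotations on an item must agree and there must be at least 3 of them — not
"some 3 agree". Sentiment and organism consensus are stored only behind a
`relevant` relevance consensus.

# Classifiers

The packaged baseline is a multinomial token-count scorer (log prior plus
smoothed log likelihood per token, arg-max with ties broken by label-set
order, unseen tokens carrying no evidence). It exists to fill the three
classifier slots of the cascade with something self-contained and exactly
testable; the cascade accepts any object with a `predict(object, texts)`
method, so externally trained models (e.g. fine-tuned transformers) plug in
without code changes. Evaluation is macro-averaged F1 on an unstratified
80/20 split with a fixed seed; a class with no predicted and no true
instances contributes F1 = 0, which keeps the macro average defined on small
splits. The cascade removes posts predicted `not_relevant` before sentiment
and organism prediction, so topic-specific labels never exist for off-topic
posts. Prediction runs on the filtered corpus *with* duplicates (each
retweet is a signal of engagement, and the upstream study predicted on the
pre-deduplication set); deduplication serves the annotation sample only.

# The sentiment index, trend, and peaks

The daily index is the count-weighted mean of +1/-1 weights over a centered
7-day window: $s(d) = (P - N)/(P + N)$ with $P, N$ the windowed
positive/negative counts — not a mean of daily ratios. Neutral posts are
excluded from the index (deviations stay visible) but counted in activity.
Windows truncate at the series edges rather than dropping edge days. The
index is undefined where a window has no polar posts.

**Trend.** `fit_linear_trend()` regresses $s$ on time in years. Overlapping
windows make consecutive index errors correlated up to lag `window - 1`
(an MA(6) structure for the 7-day window), so the classical iid OLS
standard error understates the slope uncertainty by roughly $\sqrt{7}$. The
default standard error is therefore HAC with a **truncated (flat) kernel at
exactly that known lag** — unbiased for the long-run variance of a
moving-average process, where the tapered Newey–West kernel still
underestimates. In repeated synthetic streams with a -0.061/year drift, the
2-SE interval covers the injected slope in about 94% of replicates, against
56% for the iid OLS error. `se = "ols"` restores the classical error.

**Yearly comparisons.** Welch's unequal-variance $t$ (via `stats::t.test`,
with explicit handling of zero-variance degeneracies) compares consecutive
years of per-post +1/-1 weights; Holm-adjusted p values are reported
alongside raw ones because the pairing is a multiple-testing family.

**Peaks.** `detect_peaks()` finds local maxima (plateaus count once, at
their leftmost index) and scores them by topographic prominence: height
above the higher of the two lowest descent points toward the nearest higher
ground or the series ends. "Relative" prominence normalizes by the range of
the analyzed series, making the 0.2 cut-off dimensionless; the
normalization base (range, rather than peak height) is a stated choice.
Peaks are detected on the 7-day-smoothed activity series, as the sentiment
dips of interest coincide with activity bursts. Note a localization caveat:
a burst of duration $d$ days smears into a plateau of roughly $d + 6$ days
under 7-day smoothing, so a detected peak is guaranteed within
$\pm d$ days of the burst start only for $d \ge 3$; tests use bursts of 3-7
days, which is the realistic scale of news cycles.

# Topical breakdowns

The organism-month matrix reports per-cell counts and mean weighted
sentiment with weights +1/0/-1 — here neutral posts **are** included, unlike
in the rolling index, because monthly class means are level estimates rather
than deviation signals. Cells under 100 posts are flagged masked (the value
is kept but marked unstable). Hashtags are case-folded (they are
case-insensitive identifiers on the platform) but never stemmed or grouped;
the overarching topic tag `#crispr` is excluded since it would trivially top
every year; ranking ties break lexicographically for determinism. Themes are
configuration, not code: a CSV of name/regex pairs matched
case-insensitively against anonymized text; the packaged six stems (genome,
baby, disease, embryo, treatment, mutation) are illustrative placeholders
for a curated table. Partial final years are extrapolated linearly by
$12/m$ for $m$ observed months.

# Reproducibility and problem sizes

Every stochastic function takes an explicit seed; `run_pipeline()` derives
named substream seeds from one master seed, and identical configs reproduce
byte-identical artifacts. The packaged test-and-acceptance workloads use
deliberately modest sizes chosen to exercise every code path with
comfortable statistical margins: 50 replicate 6.5-year streams at 12
posts/day for trend recovery, 20 replicate half-year streams at 50 posts/day
with multiplier-4+ bursts for peak recovery, 50 replicate annotation pools
(15 honest annotators at accuracy 0.9, one spammer, 250 tasks, redundancy
3) for QC behavior, and a roughly 50,000-post end-to-end run for
determinism. These are the package's own study conditions; larger corpora
change runtimes, not code paths.

# Known limitations

* The tokenizer is not tweet-aware; emoji, contractions, and
  non-whitespace-delimited scripts are out of contract.
* The uniform annotator error model cannot express difficulty-correlated or
  adversarial-but-consistent error; the QC rules would need item-response
  modelling to catch the latter.
* The baseline classifier is a bag-of-words scorer: adequate for the
  separable synthetic vocabulary, far below transformer performance on real
  text. It is a slot-filler, not a recommendation.
* Fleiss' kappa on a heavily imbalanced question (e.g. relevance when ~98%
  of posts are relevant) is small even for accurate annotators, because
  chance agreement is near 1; compare values only across equally balanced
  questions.
* Peak detection reports *when* activity burst, not *why*; attribution to
  named events is outside the package.
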