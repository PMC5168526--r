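---
title: "Methods: dual-source HPV-vaccine tweet surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-source HPV-vaccine tweet surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxtweets)
```

## The problem

Public conversation about the HPV vaccine happens largely on social
media, and surveillance of that conversation ("infoveillance") needs
three things done carefully: collecting tweets from imperfect sources,
classifying their content at scale from a modest hand-coded sample, and
summarizing content and reach by sentiment. vaxtweets implements that
workflow as a tested pipeline. Because real tweet corpora cannot be
redistributed, the package carries its own corpus generator whose
defaults encode the study conditions of a year-long, ten-keyword
HPV-vaccine tweet sample, plus a fixture of that sample's published
summary counts so the arithmetic of the reporting stage is checkable
exactly.

## The synthetic corpus generator

`simulate_corpus()` draws, per tweet:

* a **sentiment** code in {1 positive, 2 negative, 3 neutral, 4 no
  mention of the vaccine}, with default shares (0.3899, 0.2531, 0.1298,
  0.2272) matching the published sample;
* binary **side-effect** and **prevention/protection** codes
  (1 absent / 2 present) as Bernoulli draws whose per-sentiment rates
  default to the published conditional percentages (e.g. 46.44%
  side-effect content among negative tweets);
* one of the ten **keywords**, with "HPV" dominant (weight 0.45) and
  every hashtag variant rarer than any term it contains as a substring,
  so that substring-matched keyword subsets nest;
* a **user** by a Zipf(1) law over `n_users`, so the average number of
  tweets per user exceeds one; each user carries a single log-normal
  follower count (defaults mu = 6.1, sigma = 1.5, chosen to reproduce a
  follower median near 443 and a mean far above the median — the
  published mean is higher still, but only the median and the
  mean >> median skew are targeted);
* a **retweet count** `floor(0.75 * U^(-1/alpha))` with Pareto tail
  index `alpha = 1.065`: median 1, finite heavy-tailed mean of order
  10;
* a **timestamp** uniform over the collection year (the timestamp
  distribution of the real stream is not characterized anywhere, so
  uniform is assumed), with snowflake-style tweet IDs strictly
  increasing in time.

Text is a bag of tokens: the keyword itself, an optional
keyword-specific marker hashtag, tokens drawn from label-conditional
pools (two per variable, plus background), hashtags, mentions and URLs
at per-sentiment rates. `marker_strength` interpolates between
label-independent text (0) and fully class-specific vocabulary (1);
classifiers can learn the labels exactly insofar as this is above 0.

Two design points deserve emphasis:

* **Marker naming.** Association scores (below) tie exactly for every
  token that occurs only inside a keyword's subset, and ties break
  lexicographically. Keyword markers are therefore named `#0NNxx` with
  `NN` ordered general-before-specific along substring containment, so
  they sort before any natural token and the planted marker is
  deterministically the top associated term of its keyword. This is a
  property of the generator, not of the association statistic.
* **What the generator does not emulate.** No follower graph, no
  retweet cascades, no burstiness in time, no topic drift, no
  near-duplicate spam, and hand-coders are emulated as error-free
  readers of the latent labels. Tests passing on this corpus therefore
  validate the pipeline's arithmetic and statistical machinery, not
  classifier performance on real tweets; in particular the published
  AUCs of the original classifiers depend on unavailable hand-coded
  data and feature lists and are deliberately not reproduction targets.

`simulate_dual_sources()` degrades a corpus into the two collection
views the merge stage must reconcile: the retrospective (firehose-type)
view loses deleted tweets; the prospective (search-API-type) view loses
tweets inside configured gap windows and mislabels the language on a
small fraction. A ground-truth match map records each tweet's exclusion
cause with precedence deleted > coverage gap > language flip.

## Merging and accounting

`merge_sources()` inner-joins deduplicated streams on tweet ID; a
matched ID with disagreeing language codes counts as an exclusion
(cause `language_flip`) on both sides. Merged records take their fields
from the retrospective view, which complete-feed collection makes the
gold standard; whether the original study used prospective or
retrospective metadata for merged records is unstated, and this is the
package's choice. The `merge_report` enforces the conservation
identities `n_matched = n_prospective - n_excluded_prospective =
n_retrospective - n_excluded_retrospective` on every run, and when the
ground-truth map is supplied the attributed causes must (and in tests
do) reproduce it exactly.

Keyword matching is case-insensitive fixed substring search on the raw
text with `#` literal. This is the simplest rule that reproduces the
containment property that anything matching "HPV vaccine" also matches
"HPV"; the original tokenization for query matching is not documented.

## Annotation and reliability

The codebook codes every variable with consecutive positive integers —
zero is never valid, which is the premise of the rounded-zero discard
rule. Interrater reliability is Krippendorff's alpha (nominal), chosen
because it handles five coders and missing assignments and because the
original reliability statistic is unnamed; raw percent agreement is
reported alongside for transparency. Alpha is computed from the
coincidence matrix with the usual \(1 - D_o/D_e\) form; a variable with
a single observed category yields `NA` with a warning rather than an
error.

## Classifiers

Features are lowercase unigram counts over the top-`V` tokens of the
labelled set (default 500, fitted on labelled data only), four
structural indicators (URL, hashtag, mention, token count) and an
intercept. The original feature list is unavailable; this is the
simplest family compatible with a pseudoinverse classifier on ~1,500
samples.

**Binary variables** are fit by regressing the codes {1, 2} on the
design matrix through the Moore-Penrose pseudoinverse,
\(w = X^{+} y\), the minimum-norm least-squares solution (SVD with
relative singular-value cutoff 1e-10). Scores are thresholded by
rounding half away from zero, consistent with the discard rule.

**Multiclass sentiment** uses a CART-style tree: greedy binary splits
minimizing weighted Gini impurity, midpoint thresholds, both children
at least `min_leaf = 5` rows, depth at most `max_depth = 8` (defaults;
the original hyperparameters are unreported). Split ties break to the
lowest feature index then lowest threshold, and leaf argmax ties to the
lowest code, so fits and predictions are deterministic.

**Leave-one-out evaluation** pools the n held-out predictions and
scores them once — AUC (rank-sum form, half credit for ties) for binary
targets, error fraction for multiclass — because a single held-out
point has no AUC of its own. For the linear model the package uses the
closed-form identity \(\hat y_{(i)} = (\hat y_i - h_{ii} y_i)/(1 -
h_{ii})\) with \(h_{ii}\) the leverage of the full fit; aliased columns
are first dropped by pivoted QR (the same treatment `lm()` gives
collinear designs), and any row with leverage within 1e-8 of one falls
back to explicit retraining, as does `method = "retrain"` wholesale.
The identity is asserted against explicit retraining to 1e-8 in the
test suite. Two caveats are documented rather than hidden: for designs
with more columns than rows the closed form degenerates and the
package retrains explicitly; and under label-independent text the LOO
AUC is a slightly pessimistic estimate of 0.5 (the held-out class is
under-represented in its training set), a known property of
leave-one-out, so null checks use a 3-standard-error band at a fixed
seed.

**Discard rules.** Applied to the full corpus, linear scores round to
codes (codes above the variable's maximum clamp to the maximum; the
original rule only specifies the zero case). A tweet is discarded when
on *any* of the three variables the rounded code is zero or below, or
the certainty does not exceed the threshold (default 0.70 — tweets are
kept only when classified with certainty strictly above 70%). Linear
certainty is \(1 - 2\,|s - \mathrm{round}(s)|\); tree certainty is the
leaf majority fraction. Every discard carries its cause, and the
discard report counts them per variable.

## Word association

For a keyword's subset of tweets, each token's probability is its count
over the total token count of the set; the association score is the
ratio of subset to corpus probability (a log-ratio is reported
alongside; the comparison statistic of the original procedure is
unnamed, and a ratio is the most direct reading of "compared with").
The token stream is unigrams plus adjacent bigrams, because multi-word
associations ("to prevent") are part of the intended output; a
`bigrams = FALSE` switch recovers pure unigrams. Tokens below
`min_count = 5` within the subset are suppressed as hapax noise (no
threshold is stated in the original procedure; 5 is the package
default, and the worked examples in the tests use 1). No stop-word list
is applied — published association tables retain words like "I" and
"my", so none was evidently used. Scores are computed as
`(c_sub * W_corpus) / (c_tot * W_subset)` with exact integer products,
so tokens tied in exact arithmetic are tied in floating point too, and
ordering (score descending, token ascending in C collation) is
deterministic.

## Summary analytics and tests

`summarize_by_sentiment()` stores only counts and aggregates; every
percentage is derived at output time by `summary_table()` from its
stored numerator and denominator, which is what makes the bundled
published-count fixture a complete arithmetic check — all of the
published table's percentages, including 38.99% positive sentiment and
46.44% side-effect content among negative tweets, reproduce to two
decimals. Follower aggregates deduplicate users within a class at the
user's maximum observed count (the original user-level aggregation rule
is unstated). Group comparisons use a Pearson chi-square
(no continuity correction by default — the intended tables have counts
in the tens of thousands — with a flag for small tables), classic
one-way ANOVA, and Mood's median test implemented as the chi-square on
the groups-by-{above, at-or-below} grand-median table with ties
assigned to at-or-below. Whether the original comparisons excluded the
"no mention" class for vaccine-specific variables is unstated; the
package tests whatever groups it is given and leaves that choice to the
caller.

## Problem sizes and reproducibility

Every random stage takes an explicit integer seed, and identical
parameters plus seed give byte-identical JSONL. The test suite runs the
generator at n = 10,000 for distributional shares, n = 50,000 for
conditional-rate recovery, n = 100,000 for the log-normal mean check,
n = 5,000 for marker recovery, and n = 1,470 (the hand-coded sample
size) for classifier recovery; these sizes make binomial 3-standard-
error bands tight enough to be meaningful while keeping a full run in
tens of seconds. The end-to-end pipeline demonstration uses a few
hundred tweets, which exercises every stage without large artifacts.

## Known limitations

* Classifier quality numbers on synthetic text say nothing quantitative
  about real tweets; only the machinery (LOO identity, AUC definition,
  discard accounting) is validated.
* The tree is exact greedy CART without pruning; with the default depth
  8 it is a deliberately simple reference implementation, not a tuned
  learner.
* The pseudoinverse classifier regresses codes directly; no
  regularized or logistic alternative is offered on the primary path.
* The merge stage resolves record-level field conflicts wholesale in
  favour of the retrospective view rather than field by field.
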