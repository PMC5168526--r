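# Independent oracles and small fixture builders used across the suite.

# AUC by exhaustive enumeration of positive-negative pairs.
brute_auc <- function(scores, labels, positive = max(labels)) {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# Best Gini split by brute force over every feature and every midpoint,
# with the same deterministic tie rules (lowest feature, then lowest
# threshold) stated for the tree learner.
brute_gini_split <- function(X, y, min_leaf = 1) {
  gini <- function(v) {
    p <- table(v) / length(v)
    length(v) * (1 - sum(p^2))
  }
  best <- list(score = Inf, feature = NA, threshold = NA)
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    for (t in (xs[-length(xs)] + xs[-1]) / 2) {
      left <- X[, j] <= t
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      sc <- gini(y[left]) + gini(y[!left])
      if (sc < best$score - 1e-12) best <- list(score = sc, feature = j,
                                                threshold = t)
    }
  }
  best
}

# Krippendorff alpha (nominal) by literal enumeration of ordered value
# pairs within units, independent of the package's coincidence-matrix
# vectorization.
brute_kripp <- function(ratings) {
  pairs_disagree <- 0
  n_pairable <- 0
  pooled <- c()
  for (u in seq_len(nrow(ratings))) {
    r <- ratings[u, !is.na(ratings[u, ])]
    if (length(r) < 2) next
    n_pairable <- n_pairable + length(r)
    pooled <- c(pooled, r)
    for (a in seq_along(r)) for (b in seq_along(r)) {
      if (a != b && r[a] != r[b])
        pairs_disagree <- pairs_disagree + 1 / (length(r) - 1)
    }
  }
  d_obs <- pairs_disagree / n_pairable
  exp_dis <- 0
  for (a in seq_along(pooled)) for (b in seq_along(pooled)) {
    if (a != b && pooled[a] != pooled[b]) exp_dis <- exp_dis + 1
  }
  d_exp <- exp_dis / (n_pairable * (n_pairable - 1))
  1 - d_obs / d_exp
}

# Hand-enumerable 6-tweet classified corpus: 2 positive, 2 negative,
# 1 neutral, 1 no-mention, with known links/hashtags/mentions.
tiny_classified <- function() {
  tibble::tibble(
    tweet_id = 1:6,
    user_id = c(1L, 1L, 2L, 3L, 4L, 5L),
    follower_count = c(100, 100, 50, 10, 70, 20),
    retweet_count = c(0L, 2L, 1L, 5L, 0L, 3L),
    urls = list("http://t.co/a", character(0), "http://t.co/b",
                character(0), character(0), "http://t.co/c"),
    hashtags = list("#x", character(0), character(0), "#y",
                    character(0), character(0)),
    mentions = list(character(0), "@a", "@b", character(0),
                    character(0), character(0)),
    sentiment = c(1L, 1L, 2L, 2L, 3L, 4L),
    side_effects = c(1L, 2L, 2L, 2L, 1L, 1L),
    prevention = c(2L, 1L, 1L, 2L, 2L, 1L)
  )
}

# Labelled design matrix + binary/multiclass labels from a synthetic
# corpus, for classifier tests. `vocabulary` overrides the fitted
# vocabulary (e.g. restricting to one variable's marker pools, under
# which full marker strength makes the binary labels exactly linearly
# recoverable).
labeled_design <- function(n, marker_strength, seed, vocab = 300,
                           vocabulary = NULL, ...) {
  tw <- simulate_corpus(corpus_params(
    n_tweets = n, n_users = max(2, n %/% 2),
    marker_strength = marker_strength, seed = seed, ...))
  if (is.null(vocabulary))
    vocabulary <- build_vocabulary(tw$text, max_size = vocab)
  spec <- feature_spec(vocabulary)
  list(tweets = tw, spec = spec, X = featurize(tw, spec))
}

side_effect_vocab <- function() c(paste0("e1w", 1:6), paste0("e2w", 1:6))

strip_X <- function(X) {
  attr(X, "spec") <- NULL
  dimnames(X) <- NULL
  X
}
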