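# Controlled-score harness: one token "aa" with weight 0.05 and one
# "bb" with weight -0.05, no structural features, so a text with k
# copies of aa scores 0.05 k exactly; binary models use the intercept
# route (score exactly 2 or 1, certainty 1) unless stated otherwise.
score_spec <- function() feature_spec(c("aa", "bb", "one"),
                                      include_structural = FALSE,
                                      include_intercept = FALSE)

score_model <- function(w) {
  structure(list(w = stats::setNames(w, c("aa", "bb", "one")),
                 target = NULL, feature_spec = score_spec()),
            class = "linear_model")
}

score_text <- function(k) {
  # k > 0: k copies of aa; k < 0: |k| copies of bb; always one "one"
  tok <- if (k >= 0) rep("aa", k) else rep("bb", -k)
  paste(c(tok, "one"), collapse = " ")
}

controlled_corpus <- function(ks) {
  tibble::tibble(tweet_id = seq_along(ks),
                 text = vapply(ks, score_text, ""))
}

test_that("rounding is half-away-from-zero", {
  expect_equal(round_half_away(c(0.4, 0.5, 1.2, 1.5, 2.5, -0.5, -1.2)),
               c(0, 1, 1, 2, 3, -1, -1))
})

test_that("rounded-zero scores are discarded and codes clamp to the maximum", {
  models <- list(
    sentiment = score_model(c(0.05, -0.05, 0)),
    side_effects = score_model(c(0, 0, 1)),   # always exactly 1, cert 1
    prevention = score_model(c(0, 0, 2))      # always exactly 2, cert 1
  )
  # sentiment scores: 0.49, 1.51, 3.70, 0.40, 1.20
  models$sentiment <- score_model(c(0.01, -0.01, 0))
  corp <- controlled_corpus(c(49, 151, 370, 40, 120))
  out <- classify_corpus(models, corp, score_spec())
  tw <- out$tweets
  expect_equal(tw$sentiment_score, c(0.49, 1.51, 3.70, 0.40, 1.20))
  expect_identical(tw$sentiment, c(NA, 2L, 4L, NA, 1L))  # clamp 4 at max
  expect_true(all(tw$discarded[c(1, 4)]))
  expect_match(tw$discard_causes[1], "sentiment:rounded_zero")
  # certainty = 1 - 2|score - round(score)|
  expect_equal(tw$sentiment_certainty, c(0.02, 0.02, 0.4, 0.2, 0.6))
})

test_that("negative rounded scores are treated as invalid codes", {
  models <- list(sentiment = score_model(c(0.01, -0.01, 0)),
                 side_effects = score_model(c(0, 0, 1)),
                 prevention = score_model(c(0, 0, 2)))
  out <- classify_corpus(models, controlled_corpus(c(-80, 100)),
                         score_spec())
  expect_true(out$tweets$discarded[1])
  expect_match(out$tweets$discard_causes[1], "rounded_zero")
  expect_true(is.na(out$tweets$sentiment[1]))
})

test_that("exactly the rounded-zero and low-certainty tweets are discarded", {
  models <- list(sentiment = score_model(c(0.01, -0.01, 0)),
                 side_effects = score_model(c(0, 0, 1)),
                 prevention = score_model(c(0, 0, 2)))
  # scores: 0.40 (zero), 1.90 (keep), 1.20 (cert 0.6), 2.05 (keep),
  #         4.90 (rounds 5, clamps to 4, cert 0.8), 1.15 (cert 0.70, drop)
  ks <- c(40, 190, 120, 205, 490, 115)
  out <- classify_corpus(models, controlled_corpus(ks), score_spec())
  tw <- out$tweets
  expect_identical(tw$discarded, c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_identical(tw$discard_causes,
                   c("sentiment:rounded_zero", "", "sentiment:low_certainty",
                     "", "", "sentiment:low_certainty"))
  expect_identical(tw$sentiment[5], 4L)
  expect_identical(out$report$n_discarded, 3L)
  expect_identical(out$report$cause_counts,
                   c(`sentiment:low_certainty` = 2L,
                     `sentiment:rounded_zero` = 1L))
})

test_that("tree certainty feeds the same discard rule", {
  set.seed(70)
  X <- matrix(c(rep(0, 12), rep(1, 6)), ncol = 1)
  y <- c(rep(1L, 8), rep(2L, 4), rep(3L, 6))  # left leaf 8/12 majority
  tree <- fit_tree(X, y, max_depth = 1, min_leaf = 3)
  spec <- feature_spec("aa", include_structural = FALSE,
                       include_intercept = FALSE)
  tree$feature_spec <- spec
  binary_one <- structure(list(w = c(aa = 1), target = NULL,
                               feature_spec = spec),
                          class = "linear_model")
  models <- list(sentiment = tree, side_effects = binary_one,
                 prevention = binary_one)
  corp <- tibble::tibble(tweet_id = 1:2, text = c("", "aa"))
  out <- classify_corpus(models, corp, spec)
  # row 1: tree leaf majority 8/12 = 0.667 <= 0.7 -> discarded
  expect_true(out$tweets$discarded[1])
  expect_match(out$tweets$discard_causes[1], "sentiment:low_certainty")
  # row 2: right leaf is pure class 3, binary scores exactly 1
  expect_false(out$tweets$discarded[2])
  expect_identical(out$tweets$sentiment[2], 3L)
})

test_that("kept_tweets joins surviving classifications onto metadata", {
  models <- list(sentiment = score_model(c(0.01, -0.01, 0)),
                 side_effects = score_model(c(0, 0, 1)),
                 prevention = score_model(c(0, 0, 2)))
  corp <- controlled_corpus(c(40, 190, 205))
  corp$user_id <- 1:3
  out <- classify_corpus(models, corp, score_spec())
  kept <- kept_tweets(out, corp)
  expect_identical(kept$tweet_id, c(2L, 3L))
  expect_identical(kept$sentiment, c(2L, 2L))
})
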