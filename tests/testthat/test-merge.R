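test_that("JSONL write-then-read round trips a corpus", {
  tw <- simulate_corpus(corpus_params(n_tweets = 100, seed = 20))
  f <- tempfile()
  write_tweet_jsonl(tw, f)
  back <- read_tweet_stream(f)
  expect_identical(nrow(back), 100L)
  expect_equal(back$tweet_id, tw$tweet_id)
  expect_identical(back$text, tw$text)
  expect_equal(back$timestamp, as.POSIXct(format(tw$timestamp,
    "%Y-%m-%d %H:%M:%S", tz = "UTC"), tz = "UTC"))
  expect_identical(back$latent_sentiment, tw$latent_sentiment)
  expect_identical(back$hashtags, tw$hashtags)
  unlink(f)
})

test_that("empty and malformed streams are handled per contract", {
  f <- tempfile()
  writeLines(character(0), f)
  expect_identical(nrow(read_tweet_stream(f)), 0L)

  tw <- simulate_corpus(corpus_params(n_tweets = 10, seed = 21))
  write_tweet_jsonl(tw, f)
  lines <- readLines(f)
  lines[4] <- "{not valid json"
  writeLines(lines, f)
  expect_warning(back <- read_tweet_stream(f), "1 malformed")
  expect_identical(nrow(back), 9L)
  expect_identical(attr(back, "n_malformed"), 1L)

  writeLines(c("{bad", "{worse", lines[1]), f)
  expect_error(read_tweet_stream(f), "format error")
  expect_error(read_tweet_stream(tempfile()), "cannot read")
  unlink(f)
})

test_that("dedupe keeps the first record per tweet id", {
  tw <- simulate_corpus(corpus_params(n_tweets = 20, seed = 22))
  expect_identical(dedupe_by_id(tw), tw)
  trip <- tw[c(1, 1, 1, 2:20), ]
  expect_identical(nrow(dedupe_by_id(trip)), 20L)

  ten <- tw[c(1, 2, 1, 3, 2, 4, 1, 3, 4, 2), ]
  ten$text[3] <- "later duplicate"
  dd <- dedupe_by_id(ten)
  expect_identical(nrow(dd), 4L)
  expect_identical(dd$text[dd$tweet_id == ten$tweet_id[1]], tw$text[1])
})

test_that("merge keeps exactly the ids present in both streams", {
  mk <- function(ids) tibble::tibble(tweet_id = ids, language = "en",
                                     text = paste("HPV", ids))
  out <- merge_sources(mk(1:3), mk(2:4))
  expect_setequal(out$merged$tweet_id, 2:3)
  expect_identical(out$report$n_excluded_prospective, 1L)
  expect_identical(out$report$n_excluded_retrospective, 1L)
  expect_identical(out$report$n_matched, 2L)

  same <- merge_sources(mk(1:5), mk(1:5))
  expect_identical(same$report$n_matched, 5L)
  expect_identical(same$report$n_excluded_prospective, 0L)
})

test_that("merge membership is symmetric and conserves counts", {
  set.seed(23)
  mk <- function(ids) tibble::tibble(tweet_id = ids, language = "en",
                                     text = paste("HPV", ids))
  for (r in 1:5) {
    a <- mk(sample(1:50, 30))
    b <- mk(sample(1:50, 35))
    ab <- merge_sources(a, b)$merged$tweet_id
    ba <- merge_sources(b, a)$merged$tweet_id
    expect_setequal(ab, ba)
    rep <- merge_sources(a, b)$report
    expect_identical(rep$n_prospective,
                     rep$n_matched + rep$n_excluded_prospective)
    expect_identical(rep$n_retrospective,
                     rep$n_matched + rep$n_excluded_retrospective)
  }
})

test_that("merged records take their fields from the retrospective view", {
  p <- tibble::tibble(tweet_id = 1:2, language = "en",
                      text = c("HPV a", "HPV b"), retweet_count = c(1L, 1L))
  r <- tibble::tibble(tweet_id = 1:2, language = "en",
                      text = c("HPV a", "HPV b"), retweet_count = c(9L, 7L))
  out <- merge_sources(p, r)
  expect_identical(out$merged$retweet_count, c(9L, 7L))
})

test_that("attributed exclusion reasons match the ground-truth map", {
  tw <- simulate_corpus(corpus_params(n_tweets = 2000, seed = 24))
  st <- simulate_dual_sources(tw, source_view_params(
    p_delete = 0.15, p_language_flip = 0.05,
    gap_windows = list(c("2015-01-01", "2015-02-01")), seed = 25))
  out <- merge_sources(dedupe_by_id(st$prospective),
                       dedupe_by_id(st$retrospective),
                       match_map = st$match_map, query = keyword_query())
  mm <- st$match_map
  in_p <- mm$tweet_id %in% st$prospective$tweet_id
  in_r <- mm$tweet_id %in% st$retrospective$tweet_id
  excluded <- (in_p | in_r) &
    !(mm$tweet_id %in% out$merged$tweet_id)
  truth <- table(factor(mm$reason[excluded],
                        levels = names(out$report$exclusion_reason_counts)))
  expect_identical(out$report$exclusion_reason_counts,
                   stats::setNames(as.integer(truth), names(truth)))
  expect_identical(sum(out$report$exclusion_reason_counts == 0)
                   >= 2, TRUE)  # no_keyword / unexplained unused here
})

test_that("merging undeduplicated streams is refused", {
  d <- tibble::tibble(tweet_id = c(1, 1), language = "en", text = "HPV")
  expect_error(merge_sources(d, d), "deduplicated")
})

test_that("language filtering keeps only the requested language", {
  tw <- simulate_corpus(corpus_params(n_tweets = 10, seed = 26))
  expect_identical(nrow(filter_language(tw, "en")), 10L)
  tw$language[1:3] <- "es"
  kept <- filter_language(tw, "en")
  expect_identical(nrow(kept), 7L)
  expect_identical(attr(kept, "n_removed"), 3L)
  expect_identical(nrow(filter_language(tw[0, ], "en")), 0L)
})
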