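test_that("a hand-built 6-tweet corpus summarizes to its manual counts", {
  s <- summarize_by_sentiment(tiny_classified())
  tab <- summary_table(s)
  expect_identical(tab$n_tweets, c(2L, 2L, 1L, 1L, 6L))
  expect_identical(tab$n_users, c(1L, 2L, 1L, 1L, 5L))
  expect_identical(tab$n_link, c(1L, 1L, 0L, 1L, 3L))
  expect_identical(tab$n_hashtag, c(1L, 1L, 0L, 0L, 2L))
  expect_identical(tab$n_mention, c(1L, 1L, 0L, 0L, 2L))
  expect_identical(tab$n_prevention, c(1L, 1L, 1L, 0L, 3L))
  expect_identical(tab$n_side_effects, c(1L, 2L, 0L, 0L, 3L))
  expect_equal(tab$pct_of_sample, round(100 * c(2, 2, 1, 1, 6) / 6, 2))
  expect_equal(tab$median_followers[1], 100)  # user 1 deduplicated
  expect_equal(tab$mean_retweets[5], mean(c(0, 2, 1, 5, 0, 3)))
})

test_that("single-tweet corpora and empty corpora behave per contract", {
  one <- tiny_classified()[3, ]
  tab <- summary_table(summarize_by_sentiment(one))
  expect_equal(tab$pct_of_sample[tab$class == "negative"], 100)
  expect_equal(tab$n_tweets[tab$class %in% c("positive", "neutral")],
               c(0L, 0L))
  expect_error(summarize_by_sentiment(tiny_classified()[0, ]),
               class = "vaxtweets_undefined")
})

test_that("stored counts are internally consistent and validated", {
  s <- published_summary_counts()
  cls <- s$counts[s$counts$class != "total", ]
  tot <- s$counts[s$counts$class == "total", ]
  expect_identical(sum(cls$n_tweets), tot$n_tweets)
  expect_lte(tot$n_users, sum(cls$n_users))
  bad <- s$counts
  bad$n_tweets[1] <- bad$n_tweets[1] + 1L
  expect_error(sentiment_summary(bad), "sum to the total")
})

test_that("follower skew survives the pipeline into every sentiment class", {
  tw <- simulate_corpus(corpus_params(n_tweets = 8000, n_users = 3000,
                                      seed = 90))
  cl <- tw
  cl$sentiment <- cl$latent_sentiment
  cl$side_effects <- cl$latent_side_effects
  cl$prevention <- cl$latent_prevention
  tab <- summary_table(summarize_by_sentiment(cl))
  expect_true(all(tab$mean_followers > tab$median_followers))
})

test_that("keyword shares count non-exclusive matches", {
  corp <- tibble::tibble(
    tweet_id = 1:4,
    text = c("the HPV vaccine works", "gardasil news", "#HPV facts",
             "HPV and gardasil"))
  ks <- keyword_share(corp)
  expect_equal(ks$n[ks$keyword == "HPV"], 3L)
  expect_equal(ks$n[ks$keyword == "HPV vaccine"], 1L)
  expect_equal(ks$n[ks$keyword == "Gardasil"], 2L)
  expect_equal(ks$pct[ks$keyword == "Gardasil"], 50)
  all_hpv <- tibble::tibble(tweet_id = 1:3, text = rep("hpv now", 3))
  expect_equal(keyword_share(all_hpv)$pct[1], 100)
})

test_that("chi-square matches the direct formula and closed 2x2 form", {
  # a table equal to its own independence expectation
  tab0 <- outer(c(10, 20), c(3, 7)) / 10
  r0 <- chi_square(tab0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  r1 <- chi_square(rbind(c(10, 0), c(0, 10)))
  expect_equal(r1$statistic, 20)
  expect_identical(r1$df, 1L)

  set.seed(91)
  for (rep in 1:5) {
    t2 <- matrix(sample(5:40, 4), 2, 2)
    a <- t2[1, 1]; b <- t2[1, 2]; c <- t2[2, 1]; d <- t2[2, 2]
    n <- sum(t2)
    closed <- (a * d - b * c)^2 * n /
      (sum(t2[1, ]) * sum(t2[2, ]) * sum(t2[, 1]) * sum(t2[, 2]))
    expect_equal(chi_square(t2)$statistic, closed, tolerance = 1e-12)
  }
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "zero marginal")
})

test_that("one-way ANOVA equals the sum-of-squares oracle", {
  g <- list(c(6, 8, 4, 5, 3, 4), c(8, 12, 9, 11, 6, 8), c(13, 9, 11, 8, 7, 12))
  res <- anova_oneway(g)
  all_v <- unlist(g)
  gm <- mean(all_v)
  ss_b <- sum(lengths(g) * (vapply(g, mean, 1) - gm)^2)
  ss_w <- sum(unlist(lapply(g, function(x) (x - mean(x))^2)))
  f_oracle <- (ss_b / (length(g) - 1)) / (ss_w / (length(all_v) - length(g)))
  expect_equal(res$statistic, f_oracle, tolerance = 1e-12)
  expect_identical(res$df, c(2, 15))
  expect_equal(res$p_value,
               stats::pf(f_oracle, 2, 15, lower.tail = FALSE))

  expect_equal(anova_oneway(list(1:5, 1:5))$statistic, 0)
  expect_error(anova_oneway(list(1:3)), "2 groups")
  expect_error(anova_oneway(list(c(1, 1), c(1, 1))),
               class = "vaxtweets_undefined")
})

test_that("ANOVA p tends to 1 for large equal-mean groups", {
  set.seed(92)
  g <- list(rnorm(2000), rnorm(2000))
  expect_gt(anova_oneway(g)$p_value, 0.01)
})

test_that("Mood's median test reduces to chi-square on the above/below table", {
  g <- list(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 30),
            c(2, 2, 3, 3, 15, 16, 17, 18, 19, 20, 21, 22))
  res <- median_test(g)
  med <- stats::median(unlist(g))
  tab <- rbind(vapply(g, function(x) sum(x > med), 1),
               vapply(g, function(x) sum(x <= med), 1))
  ref <- chi_square(tab)
  expect_equal(res$statistic, ref$statistic, tolerance = 1e-12)
  expect_equal(res$p_value, ref$p_value)
  expect_identical(res$test_name, "median_test")

  expect_equal(median_test(list(1:9, 1:9))$statistic, 0)
  expect_error(median_test(list(rep(2, 5), rep(2, 5))),
               class = "vaxtweets_undefined")
})

test_that("groups fully split around the median give the maximal statistic", {
  g <- list(c(1, 2, 3, 4), c(10, 11, 12, 13))
  res <- median_test(g)
  expect_equal(res$statistic, 8)  # all mass on the diagonal of a 2x2
  expect_lt(res$p_value, 0.01)
})
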