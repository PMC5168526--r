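sentiment_levels <- function() c("positive", "negative", "neutral",
                                 "no_mention")

#' Construct a sentiment summary from stored counts
#'
#' The summary stores only counts and per-class aggregates; every
#' percentage is derived from the stored numerator and denominator at
#' output time ([summary_table()]), never stored independently.
#'
#' @param counts Tibble/data frame with one row per sentiment class plus
#'   a \code{total} row (column \code{class}), and columns
#'   \code{n_tweets}, \code{n_users}, \code{mean_followers},
#'   \code{median_followers}, \code{n_link}, \code{n_hashtag},
#'   \code{n_mention}, \code{n_prevention}, \code{n_side_effects},
#'   \code{mean_retweets}, \code{median_retweets}.
#' @return An object of class \code{sentiment_summary}.
#' @export
sentiment_summary <- function(counts) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c(sentiment_levels(), "total") %in% counts$class))
  cls <- counts[counts$class != "total", ]
  tot <- counts[counts$class == "total", ]
  if (sum(cls$n_tweets) != tot$n_tweets)
    stop("class tweet counts must sum to the total")
  if (tot$n_users > sum(cls$n_users))
    stop("total users cannot exceed the sum of per-class users")
  structure(list(counts = counts), class = "sentiment_summary")
}

#' Cross-tabulate a classified corpus by sentiment
#'
#' Builds the per-sentiment and total counts: tweets, distinct users,
#' follower aggregates (one entry per user within a class, at the user's
#' maximum observed count), link/hashtag/mention counts, prevention and
#' side-effect content counts, and retweet aggregates.
#'
#' @param classified Tibble of classified tweets with discards removed
#'   (e.g. from [kept_tweets()]): columns \code{sentiment},
#'   \code{side_effects}, \code{prevention}, \code{user_id},
#'   \code{follower_count}, \code{retweet_count} and the
#'   \code{hashtags}/\code{mentions}/\code{urls} list-columns.
#' @return A [sentiment_summary()].
#' @export
summarize_by_sentiment <- function(classified) {
  if (nrow(classified) == 0L) stop_undefined("empty corpus: no summary")
  lv <- sentiment_levels()
  grp <- factor(lv[classified$sentiment], levels = lv)
  one_group <- function(idx) {
    d <- classified[idx, ]
    fol <- tapply(d$follower_count, d$user_id, max)
    tibble::tibble(
      n_tweets = nrow(d),
      n_users = length(unique(d$user_id)),
      mean_followers = mean(fol),
      median_followers = stats::median(fol),
      n_link = sum(lengths(d$urls) > 0),
      n_hashtag = sum(lengths(d$hashtags) > 0),
      n_mention = sum(lengths(d$mentions) > 0),
      n_prevention = sum(d$prevention == 2),
      n_side_effects = sum(d$side_effects == 2),
      mean_retweets = mean(d$retweet_count),
      median_retweets = stats::median(d$retweet_count)
    )
  }
  rows <- lapply(lv, function(s) one_group(which(grp == s)))
  counts <- dplyr::bind_rows(c(rows, list(one_group(seq_len(nrow(classified))))))
  counts <- dplyr::bind_cols(tibble::tibble(class = c(lv, "total")), counts)
  sentiment_summary(counts)
}

#' Percentage table of a sentiment summary
#'
#' Derives every reported percentage from the stored counts:
#' \code{pct_of_sample} uses the total tweet count as denominator;
#' content percentages (link, hashtag, mention, prevention, side
#' effects) use the class tweet count; \code{mean_tweets_per_user} is
#' the class tweet count over the class user count.
#'
#' @param x A [sentiment_summary()].
#' @param digits Rounding for percentages (default 2) and tweets-per-user
#'   (1 decimal).
#' @return Tibble, one row per class plus the total.
#' @export
summary_table <- function(x, digits = 2) {
  stopifnot(inherits(x, "sentiment_summary"))
  c0 <- x$counts
  n_total <- c0$n_tweets[c0$class == "total"]
  pct <- function(num, den) round(100 * num / den, digits)
  tibble::tibble(
    class = c0$class,
    n_tweets = c0$n_tweets,
    pct_of_sample = pct(c0$n_tweets, n_total),
    n_users = c0$n_users,
    mean_tweets_per_user = round(c0$n_tweets / c0$n_users, 1),
    mean_followers = c0$mean_followers,
    median_followers = c0$median_followers,
    n_link = c0$n_link, pct_link = pct(c0$n_link, c0$n_tweets),
    n_hashtag = c0$n_hashtag, pct_hashtag = pct(c0$n_hashtag, c0$n_tweets),
    n_mention = c0$n_mention, pct_mention = pct(c0$n_mention, c0$n_tweets),
    n_prevention = c0$n_prevention,
    pct_prevention = pct(c0$n_prevention, c0$n_tweets),
    n_side_effects = c0$n_side_effects,
    pct_side_effects = pct(c0$n_side_effects, c0$n_tweets),
    mean_retweets = c0$mean_retweets,
    median_retweets = c0$median_retweets
  )
}

#' @export
print.sentiment_summary <- function(x, ...) {
  cat("<sentiment_summary>\n")
  print(as.data.frame(summary_table(x)), row.names = FALSE)
  invisible(x)
}

#' Per-keyword share of the corpus
#'
#' Counts, for every query term, the tweets whose text matches it
#' (categories are not mutually exclusive: a tweet counts once for every
#' keyword it matches) and the percentage of the corpus.
#'
#' @param corpus Corpus tibble.
#' @param query A [keyword_query()].
#' @return Tibble: keyword, n, pct.
#' @export
keyword_share <- function(corpus, query = keyword_query()) {
  if (nrow(corpus) == 0L) stop("corpus must be nonempty")
  hits <- keyword_hits(corpus$text, query)
  tibble::tibble(keyword = query$keywords,
                 n = unname(as.integer(colSums(hits))),
                 pct = unname(100 * colSums(hits) / nrow(corpus)))
}

new_test_result <- function(statistic, df, p_value, test_name) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), test_name = test_name),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, df = %s, p = %.3g\n",
              x$test_name, x$statistic,
              paste(x$df, collapse = ", "), x$p_value))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' @param tab r x c count matrix; all margins must be positive.
#' @param correct Apply continuity correction on 2 x 2 tables? Off by
#'   default (the target use has large counts).
#' @return A \code{test_result} (statistic, df = (r-1)(c-1), upper-tail
#'   p-value).
#' @export
chi_square <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in contingency table")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  if (any(ht$expected <= 0)) stop("all expected counts must be > 0")
  new_test_result(ht$statistic, ht$parameter, ht$p.value, "chi_square")
}

#' One-way analysis of variance
#'
#' Classic fixed-effects F test: between-group over within-group mean
#' square.
#'
#' @param groups List of numeric vectors (>= 2 groups, total n greater
#'   than the number of groups).
#' @return A \code{test_result} with df = (k-1, n-k).
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  n <- sum(lengths(groups))
  if (any(lengths(groups) < 1L) || n <= length(groups))
    stop("each group needs n >= 1 and total n > number of groups")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  if (!is.finite(ht$statistic))
    stop_undefined("ANOVA undefined: no within-group variance")
  new_test_result(ht$statistic,
                  c(ht$parameter[["num df"]], ht$parameter[["denom df"]]),
                  ht$p.value, "anova_F")
}

#' Mood's median test
#'
#' Nonparametric equality of medians: a chi-square test on the groups by
#' \{above, at-or-below\} grand-median contingency table, with ties
#' assigned to the at-or-below cell.
#'
#' @param groups List of numeric vectors (>= 2 groups).
#' @return A \code{test_result} with \code{test_name = "median_test"}.
#' @export
median_test <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  values <- unlist(groups, use.names = FALSE)
  med <- stats::median(values)
  above <- vapply(groups, function(x) sum(x > med), 1)
  at_below <- lengths(groups) - above
  tab <- rbind(above = above, at_or_below = at_below)
  if (any(rowSums(tab) == 0))
    stop_undefined("median test undefined: all values on one side of the grand median")
  res <- chi_square(tab)
  new_test_result(res$statistic, res$df, res$p_value, "median_test")
}
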