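# Planted vocabulary. Keyword markers are hashtag-style tokens named so
# they sort (C collation) before every natural token, ordered
# general-before-specific along keyword substring containment; this makes
# the planted marker the deterministic rank-1 association token for its
# keyword subset (contained tokens tie exactly on the score, and ties
# break lexicographically). None of the marker strings contains any of
# the ten search terms as a substring except the keyword's own family.
keyword_marker_tokens <- function() {
  stats::setNames(
    c("#001hv", "#002ht", "#003vx", "#004vt", "#005sh",
      "#006st", "#007gd", "#008gt", "#009cx", "#010ct"),
    hpv_keywords()
  )
}

sentiment_pool <- function(k) paste0("s", k, "w", 1:6)
side_pool <- function(code) paste0("e", code, "w", 1:6)
prevention_pool <- function(code) paste0("p", code, "w", 1:6)
background_pool <- function() sprintf("bgw%02d", 1:40)
hashtag_choices <- function() c("#cancer", "#health", "#teens", "#screening")
mention_choices <- function() c("@cdcgov", "@whonews", "@healthchat", "@newsdesk")

# One token per tweet: label-conditional with probability `strength`,
# otherwise background. pools is a list indexed by the label code.
draw_marked <- function(labels, pools, strength) {
  n <- length(labels)
  use_marker <- stats::runif(n) < strength
  bg <- background_pool()
  out <- bg[sample.int(length(bg), n, replace = TRUE)]
  for (k in unique(labels[use_marker])) {
    idx <- which(use_marker & labels == k)
    out[idx] <- pools[[k]][sample.int(length(pools[[k]]), length(idx),
                                      replace = TRUE)]
  }
  out
}

#' Simulate a labelled HPV-vaccine tweet corpus
#'
#' Generates \code{n_tweets} synthetic tweets with the structure the
#' downstream analysis assumes: every text contains exactly one sampled
#' keyword; text vocabulary is drawn from label-conditional marker pools
#' (so classifiers can learn the latent labels when
#' \code{marker_strength > 0}) plus shared background tokens; follower
#' counts are log-normal per user, retweet counts Pareto-tailed,
#' timestamps uniform over the study window, and tweet IDs monotone
#' snowflake-style integers in timestamp order.
#'
#' @param params A [corpus_params()] object.
#' @return A tibble with one row per tweet: \code{tweet_id},
#'   \code{user_id}, \code{timestamp}, \code{language}, \code{text},
#'   list-columns \code{hashtags}/\code{mentions}/\code{urls},
#'   \code{retweet_count}, \code{follower_count}, and latent ground-truth
#'   labels \code{latent_sentiment} (1-4), \code{latent_side_effects} and
#'   \code{latent_prevention} (1 absent / 2 present).
#' @examples
#' tw <- simulate_corpus(corpus_params(n_tweets = 50, seed = 1))
#' @export
simulate_corpus <- function(params) {
  stopifnot(inherits(params, "corpus_params"))
  n <- params$n_tweets
  if (n == 0L) return(empty_corpus())
  set.seed(params$seed)

  sentiment <- sample.int(4L, n, replace = TRUE, prob = params$sentiment_probs)
  side <- 1L + stats::rbinom(n, 1L,
                             params$p_side_effects_given_sentiment[sentiment])
  prev <- 1L + stats::rbinom(n, 1L,
                             params$p_prevention_given_sentiment[sentiment])

  kws <- hpv_keywords()
  kw_idx <- sample.int(10L, n, replace = TRUE, prob = params$keyword_weights)

  # Zipf user assignment; follower count is a per-user draw so the same
  # user always shows the same count.
  user_id <- sample.int(params$n_users, n, replace = TRUE,
                        prob = 1 / seq_len(params$n_users))
  followers_by_user <- round(stats::rlnorm(params$n_users,
                                           params$follower_lognormal_mu,
                                           params$follower_lognormal_sigma))
  follower_count <- followers_by_user[user_id]

  # Pareto tail, floor'd to counts: median 1, configurable tail index.
  retweet_count <- floor(0.75 * stats::runif(n)^(-1 / params$retweet_tail_param))

  win <- study_window()
  timestamp <- win[1] + stats::runif(n, 0, as.numeric(win[2] - win[1],
                                                      units = "secs"))
  # Snowflake-style IDs: strictly increasing with timestamp.
  ord <- order(timestamp)
  tweet_id <- numeric(n)
  tweet_id[ord] <- 1e12 + seq_len(n) * 4096 +
    sample.int(4095L, n, replace = TRUE)

  has_link <- stats::runif(n) < params$p_link_given_sentiment[sentiment]
  has_tag <- stats::runif(n) < params$p_hashtag_given_sentiment[sentiment]
  has_mention <- stats::runif(n) < params$p_mention_given_sentiment[sentiment]

  ms <- params$marker_strength
  kw_marker <- ifelse(stats::runif(n) < ms,
                      keyword_marker_tokens()[kw_idx], NA_character_)
  s_tok1 <- draw_marked(sentiment, lapply(1:4, sentiment_pool), ms)
  s_tok2 <- draw_marked(sentiment, lapply(1:4, sentiment_pool), ms)
  e_tok1 <- draw_marked(side, lapply(1:2, side_pool), ms)
  e_tok2 <- draw_marked(side, lapply(1:2, side_pool), ms)
  p_tok1 <- draw_marked(prev, lapply(1:2, prevention_pool), ms)
  p_tok2 <- draw_marked(prev, lapply(1:2, prevention_pool), ms)
  bg <- background_pool()
  b_tok <- bg[sample.int(length(bg), n, replace = TRUE)]

  tag <- ifelse(has_tag,
                hashtag_choices()[sample.int(4L, n, replace = TRUE)],
                NA_character_)
  men <- ifelse(has_mention,
                mention_choices()[sample.int(4L, n, replace = TRUE)],
                NA_character_)
  url <- ifelse(has_link,
                sprintf("http://t.co/%07x",
                        sample.int(.Machine$integer.max, n) %% 0xfffffff),
                NA_character_)

  parts <- cbind(kws[kw_idx], kw_marker, s_tok1, s_tok2, e_tok1, e_tok2,
                 p_tok1, p_tok2, b_tok, tag, men, url)
  text <- apply(parts, 1L, function(p) paste(p[!is.na(p)], collapse = " "))

  tibble::tibble(
    tweet_id = tweet_id,
    user_id = as.integer(user_id),
    timestamp = timestamp,
    language = "en",
    text = unname(text),
    hashtags = extract_prefixed(text, "#"),
    mentions = extract_prefixed(text, "@"),
    urls = extract_urls(text),
    retweet_count = as.integer(retweet_count),
    follower_count = as.numeric(follower_count),
    latent_sentiment = as.integer(sentiment),
    latent_side_effects = as.integer(side),
    latent_prevention = as.integer(prev)
  )
}

empty_corpus <- function() {
  tibble::tibble(
    tweet_id = numeric(), user_id = integer(),
    timestamp = as.POSIXct(character(), tz = "UTC"), language = character(),
    text = character(), hashtags = list(), mentions = list(), urls = list(),
    retweet_count = integer(), follower_count = numeric(),
    latent_sentiment = integer(), latent_side_effects = integer(),
    latent_prevention = integer()
  )
}

extract_prefixed <- function(text, prefix) {
  lapply(strsplit(text, "[[:space:]]+"), function(tk)
    tk[startsWith(tk, prefix)])
}

extract_urls <- function(text) {
  lapply(strsplit(text, "[[:space:]]+"), function(tk)
    tk[grepl("^https?://", tk)])
}

#' Degrade a corpus into prospective and retrospective collection streams
#'
#' The retrospective (firehose-style) stream drops deleted tweets; the
#' prospective (search-API-style) stream drops tweets inside the
#' configured gap windows and mislabels the language on a random
#' fraction. A ground-truth match map records, per tweet, which exclusion
#' cause (if any) applies, with precedence deleted > coverage gap >
#' language flip.
#'
#' @param corpus A nonempty corpus tibble from [simulate_corpus()].
#' @param params A [source_view_params()] object.
#' @return List with elements \code{prospective}, \code{retrospective}
#'   (corpus tibbles) and \code{match_map} (tibble: \code{tweet_id},
#'   logical cause flags, and \code{reason}).
#' @export
simulate_dual_sources <- function(corpus, params) {
  stopifnot(inherits(params, "source_view_params"))
  if (nrow(corpus) == 0L) stop("corpus must be nonempty")
  set.seed(params$seed)
  n <- nrow(corpus)

  deleted <- stats::runif(n) < params$p_delete
  in_gap <- rep(FALSE, n)
  for (w in params$gap_windows)
    in_gap <- in_gap | (corpus$timestamp >= w[1] & corpus$timestamp <= w[2])
  flipped <- stats::runif(n) < params$p_language_flip

  retrospective <- corpus[!deleted, , drop = FALSE]
  prospective <- corpus[!in_gap, , drop = FALSE]
  flip_kept <- flipped[!in_gap]
  prospective$language[flip_kept] <- params$flip_language

  reason <- rep("none", n)
  reason[flipped & !deleted & !in_gap] <- "language_flip"
  reason[in_gap] <- "coverage_gap"
  reason[deleted] <- "deleted"
  match_map <- tibble::tibble(
    tweet_id = corpus$tweet_id,
    deleted = deleted, coverage_gap = in_gap, language_flip = flipped,
    reason = reason
  )
  list(prospective = prospective, retrospective = retrospective,
       match_map = match_map)
}
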