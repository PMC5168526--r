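`%||%` <- function(a, b) if (is.null(a)) b else a

stop_undefined <- function(msg) {
  stop(structure(list(message = msg, call = sys.call(-1)),
                 class = c("vaxtweets_undefined", "error", "condition")))
}

check_prob4 <- function(x, name, simplex = FALSE) {
  if (length(x) != 4 || !is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must be a 4-vector of probabilities in [0,1]", name))
  if (simplex && abs(sum(x) - 1) > 1e-8)
    stop(sprintf("'%s' must sum to 1", name))
  as.numeric(x)
}

#' Parameters of the synthetic tweet corpus generator
#'
#' Defines the study conditions the generator emulates: the four-class
#' sentiment mix (positive, negative, neutral, no mention of the vaccine),
#' the conditional rates of side-effect and prevention/protection content
#' given sentiment, per-sentiment link/hashtag/mention rates, right-skewed
#' follower counts (log-normal), heavy-tailed retweet counts (Pareto tail),
#' and the keyword mix over the ten HPV search terms. Defaults follow the
#' published shares of a year-long HPV-vaccine tweet sample (e.g. 38.99\%
#' positive, 46.44\% side-effect content among negative tweets).
#'
#' @param n_tweets Number of tweets to generate.
#' @param n_users Number of distinct users; tweets are assigned by a Zipf
#'   law so the average number of tweets per user exceeds 1.
#' @param sentiment_probs Probability 4-vector over sentiment codes 1-4
#'   (positive, negative, neutral, no mention); must sum to 1.
#' @param p_side_effects_given_sentiment,p_prevention_given_sentiment
#'   Per-sentiment Bernoulli probabilities that the binary variable is
#'   "present" (code 2).
#' @param p_link_given_sentiment,p_hashtag_given_sentiment,p_mention_given_sentiment
#'   Per-sentiment probabilities that a tweet carries a URL, an extra
#'   hashtag, or a mention.
#' @param follower_lognormal_mu,follower_lognormal_sigma Log-normal
#'   parameters of per-user follower counts. The defaults reproduce a
#'   median near 443 with mean >> median.
#' @param retweet_tail_param Pareto tail index (> 1 gives a finite mean).
#' @param keyword_weights Probability vector over [hpv_keywords()]; the
#'   default makes "HPV" dominant and every hashtag variant rarer than the
#'   plain term it contains.
#' @param marker_strength In [0,1]: how strongly planted vocabulary signals
#'   the latent labels and the keyword. 0 makes text independent of labels;
#'   1 makes label vocabulary fully class-specific.
#' @param seed Integer RNG seed; mandatory. Same parameters and seed give a
#'   bit-identical corpus.
#' @return An object of class \code{corpus_params}.
#' @export
corpus_params <- function(n_tweets = 10000,
                          n_users = 4000,
                          sentiment_probs = c(0.3899, 0.2531, 0.1298, 0.2272),
                          p_side_effects_given_sentiment =
                            c(0.1714, 0.4644, 0.1508, 0.0596),
                          p_prevention_given_sentiment =
                            c(0.2709, 0.1154, 0.2579, 0.0730),
                          p_link_given_sentiment =
                            c(0.7666, 0.7048, 0.7526, 0.6116),
                          p_hashtag_given_sentiment =
                            c(0.4860, 0.4398, 0.4337, 0.4078),
                          p_mention_given_sentiment =
                            c(0.5910, 0.6352, 0.5041, 0.5405),
                          follower_lognormal_mu = 6.1,
                          follower_lognormal_sigma = 1.5,
                          retweet_tail_param = 1.065,
                          keyword_weights = default_keyword_weights(),
                          marker_strength = 0.8,
                          seed) {
  if (missing(seed)) stop("'seed' is mandatory in corpus_params()")
  if (length(n_tweets) != 1 || is.na(n_tweets) || n_tweets < 0 ||
      n_tweets != floor(n_tweets))
    stop("'n_tweets' must be a nonnegative integer")
  if (length(n_users) != 1 || is.na(n_users) || n_users < 1 ||
      n_users != floor(n_users))
    stop("'n_users' must be a positive integer")
  if (length(keyword_weights) != 10 || any(keyword_weights < 0) ||
      abs(sum(keyword_weights) - 1) > 1e-8)
    stop("'keyword_weights' must be a probability 10-vector summing to 1")
  if (length(marker_strength) != 1 || marker_strength < 0 || marker_strength > 1)
    stop("'marker_strength' must lie in [0,1]")
  if (retweet_tail_param <= 0) stop("'retweet_tail_param' must be > 0")
  structure(list(
    n_tweets = as.integer(n_tweets),
    n_users = as.integer(n_users),
    sentiment_probs = check_prob4(sentiment_probs, "sentiment_probs", TRUE),
    p_side_effects_given_sentiment =
      check_prob4(p_side_effects_given_sentiment,
                  "p_side_effects_given_sentiment"),
    p_prevention_given_sentiment =
      check_prob4(p_prevention_given_sentiment,
                  "p_prevention_given_sentiment"),
    p_link_given_sentiment =
      check_prob4(p_link_given_sentiment, "p_link_given_sentiment"),
    p_hashtag_given_sentiment =
      check_prob4(p_hashtag_given_sentiment, "p_hashtag_given_sentiment"),
    p_mention_given_sentiment =
      check_prob4(p_mention_given_sentiment, "p_mention_given_sentiment"),
    follower_lognormal_mu = as.numeric(follower_lognormal_mu),
    follower_lognormal_sigma = as.numeric(follower_lognormal_sigma),
    retweet_tail_param = as.numeric(retweet_tail_param),
    keyword_weights = as.numeric(keyword_weights),
    marker_strength = as.numeric(marker_strength),
    seed = as.integer(seed)
  ), class = "corpus_params")
}

#' Default keyword mix
#'
#' Weights over [hpv_keywords()] with "HPV" dominant (most tweets contain
#' the bare term) and each hashtag variant rarer than any term it contains
#' as a substring, so keyword subsets nest the way substring matching
#' implies.
#'
#' @return Named numeric 10-vector summing to 1.
#' @export
default_keyword_weights <- function() {
  stats::setNames(
    c(0.45, 0.08, 0.20, 0.04, 0.03, 0.01, 0.10, 0.03, 0.04, 0.02),
    hpv_keywords()
  )
}

#' Parameters of the two degraded collection-stream views
#'
#' The retrospective (firehose-style) view loses tweets deleted by users;
#' the prospective (search-API-style) view loses tweets falling in
#' collection gap windows and records a wrong language code on a small
#' fraction of tweets, so that the two views disagree in the ways the
#' merge stage must account for.
#'
#' @param p_delete Probability a tweet was deleted before retrospective
#'   collection.
#' @param p_language_flip Probability the prospective view records a
#'   different language code.
#' @param gap_windows List of length-2 vectors (start, end), coercible to
#'   UTC times within the study window, missed by prospective collection.
#' @param flip_language Language code recorded when a flip occurs.
#' @param seed Integer RNG seed; mandatory.
#' @return An object of class \code{source_view_params}.
#' @export
source_view_params <- function(p_delete = 0.10,
                               p_language_flip = 0.02,
                               gap_windows = list(),
                               flip_language = "es",
                               seed) {
  if (missing(seed)) stop("'seed' is mandatory in source_view_params()")
  for (p in c(p_delete, p_language_flip))
    if (length(p) != 1 || is.na(p) || p < 0 || p > 1)
      stop("probabilities must lie in [0,1]")
  gap_windows <- lapply(gap_windows, function(w) {
    w <- as.POSIXct(w, tz = "UTC")
    if (length(w) != 2 || any(is.na(w)) || w[1] > w[2])
      stop("each gap window must be an ordered (start, end) pair")
    if (w[1] < study_window()[1] || w[2] > study_window()[2])
      stop("gap windows must lie within the study window")
    w
  })
  structure(list(p_delete = p_delete,
                 p_language_flip = p_language_flip,
                 gap_windows = gap_windows,
                 flip_language = flip_language,
                 seed = as.integer(seed)),
            class = "source_view_params")
}

#' Study collection window (UTC)
#'
#' @return POSIXct vector (start, end): 1 August 2014 to 31 July 2015.
#' @export
study_window <- function() {
  as.POSIXct(c("2014-08-01 00:00:00", "2015-07-31 23:59:59"), tz = "UTC")
}
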