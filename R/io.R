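#' Write a tweet corpus as JSONL
#'
#' One UTF-8 JSON object per line with the canonical field names;
#' latent ground-truth labels (when present) go in a nested
#' \code{"latent"} object. Timestamps are written as ISO-8601 UTC.
#' Output is deterministic: the same corpus always produces identical
#' bytes.
#'
#' @param corpus Corpus tibble (see [simulate_corpus()]).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_tweet_jsonl <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    rec <- list(
      tweet_id = corpus$tweet_id[i],
      user_id = corpus$user_id[i],
      timestamp = format(corpus$timestamp[i], "%Y-%m-%dT%H:%M:%SZ",
                         tz = "UTC"),
      language = corpus$language[i],
      text = corpus$text[i],
      hashtags = corpus$hashtags[[i]],
      mentions = corpus$mentions[[i]],
      urls = corpus$urls[[i]],
      retweet_count = corpus$retweet_count[i],
      follower_count = corpus$follower_count[i]
    )
    if ("latent_sentiment" %in% names(corpus) &&
        !is.na(corpus$latent_sentiment[i])) {
      rec$latent <- list(sentiment = corpus$latent_sentiment[i],
                         side_effects = corpus$latent_side_effects[i],
                         prevention = corpus$latent_prevention[i])
    }
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a JSONL tweet stream
#'
#' Loads all well-formed records; malformed lines are counted (attribute
#' \code{"n_malformed"}, with a warning) rather than fatal, unless more
#' than half of the lines fail to parse, which aborts with a format
#' error.
#'
#' @param path Path to a JSONL file as written by [write_tweet_jsonl()].
#' @return Corpus tibble; latent labels are unnested into
#'   \code{latent_*} columns when present.
#' @export
read_tweet_stream <- function(path) {
  if (!file.exists(path)) stop("cannot read tweet stream: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_corpus())
  recs <- lapply(lines, function(l)
    tryCatch(jsonlite::fromJSON(l), error = function(e) NULL))
  bad <- vapply(recs, is.null, logical(1))
  if (mean(bad) > 0.5)
    stop("format error: more than 50% of lines are malformed JSONL")
  if (any(bad))
    warning(sum(bad), " malformed line(s) skipped in ", path)
  recs <- recs[!bad]
  chr0 <- function(x) if (length(x)) as.character(x) else character(0)
  out <- tibble::tibble(
    tweet_id = vapply(recs, function(r) as.numeric(r$tweet_id), 1),
    user_id = vapply(recs, function(r) as.integer(r$user_id), 1L),
    timestamp = as.POSIXct(
      vapply(recs, function(r) r$timestamp, ""),
      format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    language = vapply(recs, function(r) r$language, ""),
    text = vapply(recs, function(r) r$text, ""),
    hashtags = lapply(recs, function(r) chr0(r$hashtags)),
    mentions = lapply(recs, function(r) chr0(r$mentions)),
    urls = lapply(recs, function(r) chr0(r$urls)),
    retweet_count = vapply(recs, function(r) as.integer(r$retweet_count), 1L),
    follower_count = vapply(recs, function(r) as.numeric(r$follower_count), 1)
  )
  if (any(vapply(recs, function(r) !is.null(r$latent), logical(1)))) {
    lat <- function(field) vapply(recs, function(r)
      if (is.null(r$latent)) NA_integer_ else as.integer(r$latent[[field]]),
      1L)
    out$latent_sentiment <- lat("sentiment")
    out$latent_side_effects <- lat("side_effects")
    out$latent_prevention <- lat("prevention")
  }
  attr(out, "n_malformed") <- sum(bad)
  out
}

#' Export latent labels as a hand-coding style CSV
#'
#' Writes \code{tweet_id, coder_id, sentiment, side_effects, prevention}
#' rows from a corpus carrying latent labels, emulating a file of
#' manually coded tweets.
#'
#' @param corpus Corpus tibble with \code{latent_*} columns.
#' @param path Output CSV path.
#' @param coder_id Coder identifier stored on every row.
#' @return \code{path}, invisibly.
#' @export
write_labels_csv <- function(corpus, path, coder_id = "truth") {
  stopifnot("latent_sentiment" %in% names(corpus))
  df <- data.frame(tweet_id = format(corpus$tweet_id, scientific = FALSE,
                                     trim = TRUE),
                   coder_id = coder_id,
                   sentiment = corpus$latent_sentiment,
                   side_effects = corpus$latent_side_effects,
                   prevention = corpus$latent_prevention)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
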