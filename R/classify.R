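#' Round half away from zero
#'
#' Classifier scores are mapped to integer codes by rounding halves away
#' from zero (so 1.5 becomes 2, -0.5 becomes -1), matching the coding
#' convention under which a rounded value of 0 is invalid for every
#' variable.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

linear_certainty <- function(score) {
  pmin(1, pmax(0, 1 - 2 * abs(score - round_half_away(score))))
}

#' Classify a corpus and apply the discard rules
#'
#' Scores every tweet with the per-variable models (tree for the
#' multiclass sentiment, pseudoinverse linear for the binary variables),
#' converts linear scores to codes by [round_half_away()], clamps codes
#' above the variable's maximum to the maximum, and discards a tweet
#' when, on any of the three variables, either the rounded code is zero
#' or below (an invalid code under the codebook) or the classification
#' certainty does not exceed \code{certainty_threshold}. Linear
#' certainty is \code{1 - 2 |score - round(score)|}; tree certainty is
#' the leaf majority fraction.
#'
#' @param models Named list with elements \code{sentiment} (a
#'   \code{tree_model} or \code{linear_model}), \code{side_effects} and
#'   \code{prevention} (usually \code{linear_model}s).
#' @param corpus Corpus tibble to classify.
#' @param spec The [feature_spec()] the models were trained with.
#' @param certainty_threshold Tweets are kept only when every variable's
#'   certainty is strictly above this value (default 0.70).
#' @param schema A [codebook()] giving the valid code range per variable.
#' @return List of class \code{classified_corpus}: \code{tweets} (tibble
#'   with per-variable codes, certainties, \code{discarded} flag and
#'   comma-separated \code{discard_causes}) and \code{report} (counts of
#'   discards per variable and cause).
#' @export
classify_corpus <- function(models, corpus, spec,
                            certainty_threshold = 0.70,
                            schema = codebook()) {
  stopifnot(all(c("sentiment", "side_effects", "prevention") %in%
                  names(models)))
  X <- featurize(corpus, spec)
  n <- nrow(X)
  out <- tibble::tibble(tweet_id = corpus$tweet_id)
  causes <- vector("list", n)

  for (v in c("sentiment", "side_effects", "prevention")) {
    max_code <- max(schema$variables[[v]]$codes)
    m <- models[[v]]
    if (inherits(m, "linear_model")) {
      score <- predict_linear(m, X)
      code <- round_half_away(score)
      cert <- linear_certainty(score)
      rounded_zero <- code <= 0
      code <- pmin(code, max_code)
    } else {
      pr <- predict_tree(m, X)
      score <- pr$class
      code <- pmin(pr$class, max_code)
      cert <- pr$certainty
      rounded_zero <- rep(FALSE, n)
    }
    low_cert <- !rounded_zero & cert <= certainty_threshold
    for (i in which(rounded_zero))
      causes[[i]] <- c(causes[[i]], paste0(v, ":rounded_zero"))
    for (i in which(low_cert))
      causes[[i]] <- c(causes[[i]], paste0(v, ":low_certainty"))
    out[[v]] <- as.integer(ifelse(rounded_zero, NA, code))
    out[[paste0(v, "_score")]] <- as.numeric(score)
    out[[paste0(v, "_certainty")]] <- cert
  }

  out$discarded <- lengths(causes) > 0L
  out$discard_causes <- vapply(causes, function(x)
    if (is.null(x)) "" else paste(x, collapse = ","), "")

  cause_counts <- table(unlist(causes))
  report <- list(
    n_total = n,
    n_discarded = sum(out$discarded),
    n_kept = sum(!out$discarded),
    cause_counts = stats::setNames(as.integer(cause_counts),
                                   names(cause_counts)),
    certainty_threshold = certainty_threshold
  )
  structure(list(tweets = out, report = report),
            class = "classified_corpus")
}

#' @export
print.classified_corpus <- function(x, ...) {
  r <- x$report
  cat("<classified_corpus>", r$n_total, "tweets:", r$n_kept, "kept,",
      r$n_discarded, "discarded\n")
  if (length(r$cause_counts))
    cat("  causes:", paste(sprintf("%s=%d", names(r$cause_counts),
                                   r$cause_counts), collapse = ", "), "\n")
  invisible(x)
}

#' Keep only classified tweets that survived the discard rules
#'
#' Joins the kept classifications back onto the corpus metadata, giving
#' the analysis-ready sample.
#'
#' @param classified A [classify_corpus()] result.
#' @param corpus The corpus that was classified.
#' @return Tibble of kept tweets with metadata and assigned codes.
#' @export
kept_tweets <- function(classified, corpus) {
  stopifnot(inherits(classified, "classified_corpus"))
  keep <- classified$tweets[!classified$tweets$discarded,
                            c("tweet_id", "sentiment", "side_effects",
                              "prevention")]
  dplyr::inner_join(corpus, keep, by = "tweet_id")
}
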