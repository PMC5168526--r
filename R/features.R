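#' Feature specification for tweet classification
#'
#' A fixed, ordered token vocabulary plus optional structural features
#' (\code{has_url}, \code{has_hashtag}, \code{has_mention},
#' \code{token_count}) and an intercept column. The vocabulary must be
#' fitted on the labelled set only, never on the unlabelled corpus.
#'
#' @param vocabulary Ordered character vector of distinct tokens.
#' @param include_structural Add the four structural features?
#' @param lowercase Lowercase text before tokenizing?
#' @param include_intercept Add a constant column of ones?
#' @return An object of class \code{feature_spec}.
#' @export
feature_spec <- function(vocabulary, include_structural = TRUE,
                         lowercase = TRUE, include_intercept = TRUE) {
  if (length(vocabulary) < 1L) stop("vocabulary must have at least 1 token")
  if (anyDuplicated(vocabulary)) stop("vocabulary tokens must be distinct")
  structure(list(vocabulary = as.character(vocabulary),
                 include_structural = isTRUE(include_structural),
                 lowercase = isTRUE(lowercase),
                 include_intercept = isTRUE(include_intercept)),
            class = "feature_spec")
}

#' Build a token vocabulary from labelled texts
#'
#' The most frequent tokens of the labelled texts (default top 500),
#' frequency descending with lexicographic tie-break, optionally dropping
#' tokens seen fewer than \code{min_count} times.
#'
#' @param texts Character vector of labelled tweet texts.
#' @param max_size Vocabulary size cap.
#' @param min_count Minimum token frequency.
#' @return Character vector of tokens.
#' @export
build_vocabulary <- function(texts, max_size = 500, min_count = 1) {
  toks <- unlist(tokenize(texts), use.names = FALSE)
  if (length(toks) == 0L) stop("no tokens in labelled texts")
  tab <- table(toks)
  tab <- tab[tab >= min_count]
  ord <- order(-as.integer(tab), names(tab))
  utils::head(names(tab)[ord], max_size)
}

#' Featurize tweet texts into a design matrix
#'
#' Deterministic text-to-row mapping: token counts over the spec's
#' vocabulary (out-of-vocabulary tokens ignored), then structural
#' features derived from the tokens, then the intercept.
#'
#' @param x Corpus tibble (with a \code{text} column) or character vector
#'   of texts.
#' @param spec A [feature_spec()].
#' @return Numeric matrix with one row per tweet; row names are tweet IDs
#'   when available, and the spec is attached as attribute \code{"spec"}.
#' @export
featurize <- function(x, spec) {
  stopifnot(inherits(spec, "feature_spec"))
  texts <- if (is.character(x)) x else x$text
  ids <- if (!is.character(x) && "tweet_id" %in% names(x))
    format(x$tweet_id, scientific = FALSE, trim = TRUE) else NULL
  toks <- tokenize(texts, lowercase = spec$lowercase)
  if (length(texts) == 1L) toks <- list(toks)
  n <- length(texts)
  V <- length(spec$vocabulary)
  X <- matrix(0, n, V, dimnames = list(NULL, spec$vocabulary))
  row_idx <- rep.int(seq_len(n), lengths(toks))
  col_idx <- match(unlist(toks, use.names = FALSE), spec$vocabulary)
  keep <- !is.na(col_idx)
  if (any(keep)) {
    inc <- table(factor(row_idx[keep], levels = seq_len(n)),
                 factor(col_idx[keep], levels = seq_len(V)))
    X <- X + as.matrix(inc)
    dimnames(X) <- list(NULL, spec$vocabulary)
  }
  if (spec$include_structural) {
    X <- cbind(X,
      has_url = as.numeric(vapply(toks, function(t) any(t == "<url>"),
                                  logical(1))),
      has_hashtag = as.numeric(vapply(toks, function(t)
        any(startsWith(t, "#")), logical(1))),
      has_mention = as.numeric(vapply(toks, function(t)
        any(startsWith(t, "@")), logical(1))),
      token_count = lengths(toks))
  }
  if (spec$include_intercept) X <- cbind(X, `(intercept)` = 1)
  rownames(X) <- ids
  attr(X, "spec") <- spec
  X
}
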