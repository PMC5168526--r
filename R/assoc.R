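#' Tokenize tweet text
#'
#' Whitespace split, then per raw token: URLs collapse to the single
#' token \code{"<url>"}; everything else is (optionally) lowercased and
#' stripped of punctuation, keeping \code{#} and \code{@} so hashtags
#' and mentions survive as tokens; empty remainders are dropped.
#'
#' @param text Character vector.
#' @param lowercase Lowercase non-URL tokens? Default \code{TRUE}.
#' @return For one text, a character vector of tokens; for several, a
#'   list of such vectors.
#' @examples
#' tokenize("RT @cdc: #HPV http://t.co/x")
#' @export
tokenize <- function(text, lowercase = TRUE) {
  out <- lapply(strsplit(text, "[[:space:]]+"), function(raw) {
    raw <- raw[nzchar(raw)]
    if (length(raw) == 0L) return(character(0))
    is_url <- grepl("^(https?://|www\\.)", raw, ignore.case = TRUE)
    tok <- raw
    tok[is_url] <- "<url>"
    rest <- tok[!is_url]
    if (lowercase) rest <- tolower(rest)
    rest <- gsub("[^[:alnum:]#@]", "", rest)
    tok[!is_url] <- rest
    tok[nzchar(tok)]
  })
  if (length(text) == 1L) out[[1L]] else out
}

token_stream <- function(tokens, bigrams = TRUE) {
  if (!bigrams || length(tokens) < 2L) return(tokens)
  c(tokens, paste(tokens[-length(tokens)], tokens[-1L]))
}

#' Keyword-word association scores
#'
#' For each token occurring at least \code{min_count} times among tweets
#' matching the keyword, compares the token's probability inside that
#' subset with its probability in the whole corpus: probabilities are
#' the token's count divided by the total number of tokens in the
#' respective set, and the score is their ratio. Entries are sorted by
#' score descending with lexicographic tie-break. The token stream
#' contains unigrams and, by default, adjacent bigrams, so multi-word
#' associations are visible.
#'
#' @param corpus Corpus tibble.
#' @param keyword One of the query's search terms.
#' @param query A [keyword_query()] (default the ten HPV terms).
#' @param min_count Minimum within-subset token count (default 5).
#' @param bigrams Include adjacent bigrams in the token stream?
#' @return An \code{association_table}: \code{keyword}, \code{entries}
#'   (tibble: token, n_subset, n_corpus, p_subset, p_corpus, score,
#'   log_score), and \code{totals}.
#' @export
association_scores <- function(corpus, keyword, query = keyword_query(),
                               min_count = 5, bigrams = TRUE) {
  if (nrow(corpus) == 0L) stop("corpus must be nonempty")
  if (!keyword %in% query$keywords)
    stop("'", keyword, "' is not among the configured query terms")
  hits <- keyword_hits(corpus$text, query)[, keyword]
  if (!any(hits)) {
    warning("no tweet matches keyword '", keyword, "': empty table")
    return(empty_association_table(keyword))
  }
  toks <- lapply(tokenize(corpus$text), token_stream, bigrams = bigrams)
  all_tok <- unlist(toks, use.names = FALSE)
  sub_tok <- unlist(toks[hits], use.names = FALSE)
  w_corpus <- length(all_tok)
  w_subset <- length(sub_tok)
  n_corpus <- table(all_tok)
  n_subset <- table(sub_tok)
  keep <- names(n_subset)[as.integer(n_subset) >= min_count]
  cs <- as.numeric(n_subset[keep])
  ct <- as.numeric(n_corpus[keep])
  # score written as an integer-product ratio so exactly-tied rationals
  # (tokens wholly inside the subset) compare as exactly equal doubles
  score <- (cs * w_corpus) / (ct * w_subset)
  entries <- tibble::tibble(
    token = keep,
    n_subset = cs, n_corpus = ct,
    p_subset = cs / w_subset, p_corpus = ct / w_corpus,
    score = score, log_score = log(score)
  )
  entries <- entries[order(-entries$score,
                           factor(entries$token,
                                  levels = stringi_sort(entries$token))), ]
  structure(list(keyword = keyword, entries = entries,
                 totals = c(subset_word_count = w_subset,
                            corpus_word_count = w_corpus)),
            class = "association_table")
}

# deterministic C-locale ordering regardless of the session collation
stringi_sort <- function(x) sort(x, method = "radix")

empty_association_table <- function(keyword) {
  structure(list(keyword = keyword,
                 entries = tibble::tibble(
                   token = character(), n_subset = numeric(),
                   n_corpus = numeric(), p_subset = numeric(),
                   p_corpus = numeric(), score = numeric(),
                   log_score = numeric()),
                 totals = c(subset_word_count = 0, corpus_word_count = 0)),
            class = "association_table")
}

#' @export
print.association_table <- function(x, n = 10, ...) {
  cat("<association_table> keyword:", x$keyword, "—",
      nrow(x$entries), "tokens;",
      x$totals["subset_word_count"], "/", x$totals["corpus_word_count"],
      "words (subset/corpus)\n")
  print(utils::head(x$entries, n))
  invisible(x)
}

#' Top associated terms for a keyword
#'
#' @param table An [association_scores()] table.
#' @param k Number of terms (the whole table if smaller).
#' @return Character vector of at most \code{k} tokens in table order.
#' @export
top_terms <- function(table, k) {
  stopifnot(inherits(table, "association_table"), k >= 1)
  utils::head(table$entries$token, k)
}
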