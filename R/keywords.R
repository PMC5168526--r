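#' The ten HPV-vaccine keyword search terms
#'
#' The keyword and hashtag queries used to collect the tweet stream:
#' general HPV terms, vaccine-specific terms, and the two brand-name
#' vaccines (Gardasil, Cervarix), each with a hashtag variant.
#'
#' @return Character vector of length 10.
#' @export
hpv_keywords <- function() {
  c("HPV", "#HPV", "HPV vaccine", "#HPVvaccine", "HPV shot",
    "#hpvshot", "Gardasil", "#Gardasil", "Cervarix", "#Cervarix")
}

#' Construct a keyword query
#'
#' A keyword query is an ordered set of search terms matched against raw
#' tweet text. Matching is plain substring search: a hashtag term such as
#' \code{"#HPV"} requires the literal \code{#} character, so any text
#' matching \code{"HPV vaccine"} also matches \code{"HPV"} (the containment
#' property the collection design relies on).
#'
#' @param keywords Character vector of search terms (no duplicates).
#' @param case_sensitive Match case-sensitively? Default \code{FALSE}.
#' @return An object of class \code{keyword_query}.
#' @export
keyword_query <- function(keywords = hpv_keywords(), case_sensitive = FALSE) {
  if (length(keywords) == 0) stop("keyword list must be nonempty")
  if (anyDuplicated(keywords)) stop("duplicate keywords are forbidden")
  structure(
    list(keywords = as.character(keywords),
         case_sensitive = isTRUE(case_sensitive)),
    class = "keyword_query"
  )
}

#' @export
print.keyword_query <- function(x, ...) {
  cat("<keyword_query> ", length(x$keywords), " terms (",
      if (x$case_sensitive) "case-sensitive" else "case-insensitive", ")\n",
      sep = "")
  cat("  ", paste(x$keywords, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Match keywords against tweet text
#'
#' Returns, for each text, the set of query terms found by (by default
#' case-insensitive) fixed substring search. \code{#} is treated literally.
#'
#' @param text Character vector of tweet texts.
#' @param query A [keyword_query()].
#' @return For a single text, a character vector of matched keywords; for
#'   several texts, a list of such vectors.
#' @examples
#' match_keywords("Offered the HPV vaccine today", keyword_query())
#' @export
match_keywords <- function(text, query = keyword_query()) {
  stopifnot(inherits(query, "keyword_query"))
  hits <- keyword_hits(text, query)
  out <- lapply(seq_along(text), function(i) query$keywords[hits[i, ]])
  if (length(text) == 1L) out[[1L]] else out
}

# Logical matrix length(text) x length(keywords); workhorse shared with
# keyword_share() so per-keyword counting never loops in R over tweets.
keyword_hits <- function(text, query) {
  txt <- if (query$case_sensitive) text else tolower(text)
  kw <- if (query$case_sensitive) query$keywords else tolower(query$keywords)
  m <- vapply(kw, function(k) grepl(k, txt, fixed = TRUE),
              logical(length(text)))
  matrix(m, nrow = length(text),
         dimnames = list(NULL, query$keywords))
}
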