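#' Deduplicate a tweet collection by ID
#'
#' Tweets captured under several keyword queries appear once per query;
#' the first occurrence of each \code{tweet_id} is kept.
#'
#' @param collection Corpus tibble.
#' @return Tibble with one row per \code{tweet_id}.
#' @export
dedupe_by_id <- function(collection) {
  collection[!duplicated(collection$tweet_id), , drop = FALSE]
}

#' Merge the prospective and retrospective streams by tweet ID
#'
#' Inner-joins the two deduplicated collection views on \code{tweet_id}.
#' A tweet matches when its ID is present in both streams and (when both
#' streams carry a \code{language} column) the recorded language agrees;
#' a language disagreement is an exclusion with cause
#' \code{language_flip}. Merged records take their fields from the
#' retrospective view, which is treated as the gold standard.
#'
#' @param prospective,retrospective Deduplicated corpus tibbles.
#' @param match_map Optional ground-truth map from
#'   [simulate_dual_sources()], used to attribute exclusion causes.
#' @param query Optional [keyword_query()]; excluded records whose text
#'   matches no keyword are attributed to \code{no_keyword} when the
#'   ground truth offers no cause.
#' @return List with \code{merged} (tibble) and \code{report}
#'   (a \code{merge_report}).
#' @export
merge_sources <- function(prospective, retrospective, match_map = NULL,
                          query = NULL) {
  if (anyDuplicated(prospective$tweet_id) ||
      anyDuplicated(retrospective$tweet_id))
    stop("streams must be deduplicated before merging (see dedupe_by_id)")

  p_ids <- prospective$tweet_id
  r_ids <- retrospective$tweet_id
  in_both <- intersect(p_ids, r_ids)

  both_lang <- "language" %in% names(prospective) &&
    "language" %in% names(retrospective)
  if (both_lang && length(in_both)) {
    p_lang <- prospective$language[match(in_both, p_ids)]
    r_lang <- retrospective$language[match(in_both, r_ids)]
    lang_mismatch <- in_both[p_lang != r_lang]
    matched_ids <- setdiff(in_both, lang_mismatch)
  } else {
    lang_mismatch <- numeric(0)
    matched_ids <- in_both
  }

  merged <- retrospective[match(matched_ids, r_ids), , drop = FALSE]

  excl_p <- setdiff(p_ids, matched_ids)
  excl_r <- setdiff(r_ids, matched_ids)
  reasons <- attribute_reasons(
    excl_p, excl_r, lang_mismatch, match_map, query,
    prospective, retrospective
  )

  report <- new_merge_report(
    n_prospective = length(p_ids),
    n_retrospective = length(r_ids),
    n_matched = length(matched_ids),
    exclusion_reason_counts = reasons
  )
  list(merged = merged, report = report)
}

# Cause per excluded record: ground truth first, then a keyword check,
# else unexplained. Counted over the union of both sides' exclusions so
# a language flip (excluded from each side) is one underlying cause.
attribute_reasons <- function(excl_p, excl_r, lang_mismatch, match_map,
                              query, prospective, retrospective) {
  ids <- union(excl_p, excl_r)
  if (length(ids) == 0L)
    return(c(deleted = 0L, language_flip = 0L, coverage_gap = 0L,
             no_keyword = 0L, unexplained = 0L))
  reason <- rep("unexplained", length(ids))
  reason[ids %in% lang_mismatch] <- "language_flip"
  if (!is.null(match_map)) {
    m <- match(ids, match_map$tweet_id)
    known <- !is.na(m) & match_map$reason[m] != "none"
    reason[known] <- match_map$reason[m][known]
  }
  if (!is.null(query)) {
    unex <- which(reason == "unexplained")
    if (length(unex)) {
      txt <- character(length(unex))
      src_p <- match(ids[unex], prospective$tweet_id)
      src_r <- match(ids[unex], retrospective$tweet_id)
      txt[!is.na(src_p)] <- prospective$text[src_p[!is.na(src_p)]]
      txt[is.na(src_p)] <- retrospective$text[src_r[is.na(src_p)]]
      nk <- rowSums(keyword_hits(txt, query)) == 0L
      reason[unex[nk]] <- "no_keyword"
    }
  }
  counts <- table(factor(reason, levels = c("deleted", "language_flip",
                                            "coverage_gap", "no_keyword",
                                            "unexplained")))
  stats::setNames(as.integer(counts), names(counts))
}

new_merge_report <- function(n_prospective, n_retrospective, n_matched,
                             exclusion_reason_counts) {
  rep <- structure(list(
    n_prospective = n_prospective,
    n_retrospective = n_retrospective,
    n_matched = n_matched,
    n_excluded_prospective = n_prospective - n_matched,
    n_excluded_retrospective = n_retrospective - n_matched,
    exclusion_reason_counts = exclusion_reason_counts,
    pct_retained_prospective =
      if (n_prospective > 0) 100 * n_matched / n_prospective else NA_real_,
    pct_retained_retrospective =
      if (n_retrospective > 0) 100 * n_matched / n_retrospective else NA_real_
  ), class = "merge_report")
  stopifnot(rep$n_matched ==
              rep$n_prospective - rep$n_excluded_prospective,
            rep$n_matched ==
              rep$n_retrospective - rep$n_excluded_retrospective)
  rep
}

#' @export
print.merge_report <- function(x, ...) {
  cat("<merge_report>\n")
  cat(sprintf("  prospective   %8d  (retained %.2f%%, excluded %.2f%%)\n",
              x$n_prospective, x$pct_retained_prospective,
              100 - x$pct_retained_prospective))
  cat(sprintf("  retrospective %8d  (retained %.2f%%, excluded %.2f%%)\n",
              x$n_retrospective, x$pct_retained_retrospective,
              100 - x$pct_retained_retrospective))
  cat(sprintf("  matched       %8d\n", x$n_matched))
  rc <- x$exclusion_reason_counts
  cat("  exclusion causes:",
      paste(sprintf("%s=%d", names(rc), rc), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a merge report to JSON
#'
#' @param report A \code{merge_report}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_merge_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Filter a collection to one language
#'
#' @param collection Corpus tibble.
#' @param language ISO language code to keep (default \code{"en"}).
#' @return Filtered tibble; the number of removed records is stored in
#'   attribute \code{"n_removed"}.
#' @export
filter_language <- function(collection, language = "en") {
  keep <- collection$language == language
  out <- collection[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}
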