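#' Published summary counts of the HPV-vaccine tweet sample
#'
#' The bundled cross-tabulation counts of a year-long, 193,379-tweet
#' English-language HPV-vaccine Twitter sample: tweets, users, follower
#' and retweet aggregates and content counts per sentiment class. Every
#' percentage of the published table is recomputable from these counts
#' via [summary_table()].
#'
#' @return A [sentiment_summary()].
#' @export
published_summary_counts <- function() {
  path <- system.file("extdata", "hpv_summary_counts.csv",
                      package = "vaxtweets", mustWork = TRUE)
  sentiment_summary(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Published per-keyword counts of the merged tweet sample
#'
#' Bundled counts of merged tweets (n = 216,060) matching the dominant
#' search terms, with the share of the corpus each represents (keyword
#' categories are not mutually exclusive).
#'
#' @return Tibble: keyword, n, denominator, pct.
#' @export
published_keyword_counts <- function() {
  path <- system.file("extdata", "hpv_keyword_counts.csv",
                      package = "vaxtweets", mustWork = TRUE)
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                          check.names = FALSE))
  df$pct <- 100 * df$n / df$denominator
  df
}
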