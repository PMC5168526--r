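#' The content-classification codebook
#'
#' Three study variables: four-class vaccine \code{sentiment}
#' (1 positive, 2 negative, 3 neutral, 4 no mention of the vaccine though
#' HPV is mentioned) and two binary variables, \code{side_effects} and
#' \code{prevention} (1 absent, 2 present). Codes within a variable are
#' consecutive integers starting at 1: zero is never a valid code for any
#' variable, which is the premise of the rounded-zero discard rule.
#'
#' @return An object of class \code{codebook}.
#' @export
codebook <- function() {
  structure(list(variables = list(
    sentiment = list(
      kind = "multiclass",
      codes = c(positive = 1L, negative = 2L, neutral = 3L, no_mention = 4L)),
    side_effects = list(
      kind = "binary", codes = c(absent = 1L, present = 2L)),
    prevention = list(
      kind = "binary", codes = c(absent = 1L, present = 2L))
  )), class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat("<codebook>\n")
  for (v in names(x$variables)) {
    var <- x$variables[[v]]
    cat(sprintf("  %-12s (%s): %s\n", v, var$kind,
                paste(sprintf("%s=%d", names(var$codes), var$codes),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Serialize the codebook schema to JSON
#'
#' @param schema A [codebook()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_codebook_json <- function(schema, path) {
  jsonlite::write_json(
    lapply(schema$variables, function(v)
      list(kind = v$kind, codes = as.list(v$codes))),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Load hand-coded labels from CSV
#'
#' Expects columns \code{tweet_id, coder_id, sentiment, side_effects,
#' prevention} and validates every code against the codebook; an invalid
#' code aborts with an error naming the row and variable.
#'
#' @param path CSV file path.
#' @param schema A [codebook()].
#' @return Tibble of validated labelled tweets.
#' @export
load_labels <- function(path, schema = codebook()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("tweet_id", "coder_id", "sentiment", "side_effects",
              "prevention")
  if (!all(needed %in% names(df)))
    stop("label CSV must have columns: ", paste(needed, collapse = ", "))
  for (v in names(schema$variables)) {
    codes <- schema$variables[[v]]$codes
    bad <- which(!(df[[v]] %in% codes))
    if (length(bad))
      stop(sprintf("invalid code %s for variable '%s' at row %d",
                   df[[v]][bad[1]], v, bad[1]))
  }
  tibble::tibble(tweet_id = as.numeric(df$tweet_id),
                 coder_id = as.character(df$coder_id),
                 sentiment = as.integer(df$sentiment),
                 side_effects = as.integer(df$side_effects),
                 prevention = as.integer(df$prevention))
}

#' Krippendorff's alpha for nominal data
#'
#' Chance-corrected agreement over a units-by-coders matrix of nominal
#' codes (\code{NA} = not coded). Units rated by fewer than two coders
#' are ignored. Returns \code{NA} with a warning when agreement is
#' undefined (a single observed category, or fewer than two pairable
#' values).
#'
#' @param ratings Matrix, units in rows, coders in columns.
#' @return Alpha in [-1, 1], or \code{NA}.
#' @export
krippendorff_alpha <- function(ratings) {
  ratings <- as.matrix(ratings)
  vals <- sort(unique(stats::na.omit(as.vector(ratings))))
  if (length(vals) < 2L) {
    warning("agreement undefined: a single observed category")
    return(NA_real_)
  }
  k <- length(vals)
  o <- matrix(0, k, k, dimnames = list(vals, vals))
  for (u in seq_len(nrow(ratings))) {
    r <- ratings[u, !is.na(ratings[u, ])]
    m_u <- length(r)
    if (m_u < 2L) next
    idx <- match(r, vals)
    tab <- tabulate(idx, k)
    # ordered pairs within the unit, weighted 1/(m_u - 1)
    o <- o + (outer(tab, tab) - diag(tab, k)) / (m_u - 1)
  }
  n_c <- rowSums(o)
  n_tot <- sum(n_c)
  if (n_tot <= 1) {
    warning("agreement undefined: fewer than two pairable values")
    return(NA_real_)
  }
  d_obs <- sum(o) - sum(diag(o))
  d_exp <- (sum(outer(n_c, n_c)) - sum(n_c^2)) / (n_tot - 1)
  if (d_exp == 0) {
    warning("agreement undefined: no expected disagreement")
    return(NA_real_)
  }
  1 - d_obs / d_exp
}

#' Interrater reliability per codebook variable
#'
#' Computes Krippendorff's alpha (nominal) and raw percent agreement for
#' each study variable over a multi-coder labelled set. Requires at
#' least two coders sharing at least one tweet.
#'
#' @param labels Labelled tibble as from [load_labels()], with several
#'   \code{coder_id} values.
#' @param schema A [codebook()].
#' @return Tibble: variable, alpha, percent_agreement, n_items,
#'   n_coders.
#' @export
interrater_reliability <- function(labels, schema = codebook()) {
  coders <- sort(unique(labels$coder_id))
  if (length(coders) < 2L) stop("need at least two coders")
  ids <- sort(unique(labels$tweet_id))
  per_var <- lapply(names(schema$variables), function(v) {
    m <- matrix(NA_integer_, length(ids), length(coders),
                dimnames = list(NULL, coders))
    m[cbind(match(labels$tweet_id, ids), match(labels$coder_id, coders))] <-
      labels[[v]]
    if (!any(rowSums(!is.na(m)) >= 2L))
      stop("coders share no common tweet")
    alpha <- krippendorff_alpha(m)
    # percent agreement over all coder pairs on jointly coded units
    agree <- 0; tot <- 0
    for (a in seq_along(coders)) for (b in seq_len(a - 1L)) {
      both <- !is.na(m[, a]) & !is.na(m[, b])
      agree <- agree + sum(m[both, a] == m[both, b])
      tot <- tot + sum(both)
    }
    tibble::tibble(variable = v, alpha = alpha,
                   percent_agreement = if (tot > 0) 100 * agree / tot
                                       else NA_real_,
                   n_items = sum(rowSums(!is.na(m)) >= 2L),
                   n_coders = length(coders))
  })
  dplyr::bind_rows(per_var)
}
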