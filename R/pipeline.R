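#' Pipeline configuration
#'
#' Collects every stage's parameters: the corpus generator, the two
#' source views, the labelled subsample size, featurization and
#' thresholds. Can be built from arguments or loaded from a YAML file
#' whose top-level keys mirror the argument names (\code{seed} is
#' mandatory either way).
#'
#' @param seed Integer master seed for the run.
#' @param n_tweets,n_users Corpus size parameters.
#' @param corpus Optional named list of further [corpus_params()]
#'   arguments.
#' @param views Optional named list of [source_view_params()] arguments
#'   (\code{p_delete}, \code{p_language_flip}, \code{gap_windows},
#'   \code{flip_language}).
#' @param n_labeled Number of tweets in the hand-coded emulation file
#'   (capped at the merged sample size).
#' @param vocab_size Vocabulary cap for [build_vocabulary()].
#' @param certainty_threshold Discard threshold of [classify_corpus()].
#' @param min_count Token threshold of [association_scores()].
#' @param keywords Keyword list for the [keyword_query()].
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed, n_tweets = 2000, n_users = 800,
                            corpus = list(), views = list(),
                            n_labeled = 300, vocab_size = 300,
                            certainty_threshold = 0.70, min_count = 5,
                            keywords = hpv_keywords()) {
  if (missing(seed)) stop("'seed' is mandatory in pipeline_config()")
  structure(list(seed = as.integer(seed), n_tweets = n_tweets,
                 n_users = n_users, corpus = corpus, views = views,
                 n_labeled = n_labeled, vocab_size = vocab_size,
                 certainty_threshold = certainty_threshold,
                 min_count = min_count, keywords = keywords),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with keys matching [pipeline_config()]
#'   arguments.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config error: 'seed' is mandatory")
  do.call(pipeline_config, cfg)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full surveillance pipeline
#'
#' Chains every stage on a synthetic corpus: simulate, degrade into two
#' collection streams, write and re-read JSONL, dedupe, merge by tweet
#' ID, filter to English, emulate the hand-coded label file, train the
#' per-variable classifiers (tree for sentiment, pseudoinverse linear
#' for the binary variables), classify the remaining corpus with the
#' discard rules, compute keyword associations and the sentiment
#' summary, and write all artifacts plus a manifest with the seed and
#' the record count at every box of the flow.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  query <- keyword_query(config$keywords)

  corpus <- pipeline_stage("simulate", {
    cp <- do.call(corpus_params, c(
      list(n_tweets = config$n_tweets, n_users = config$n_users,
           seed = config$seed), config$corpus))
    simulate_corpus(cp)
  })
  streams <- pipeline_stage("dual_sources", {
    vp <- do.call(source_view_params,
                  c(list(seed = config$seed + 1L), config$views))
    simulate_dual_sources(corpus, vp)
  })

  pipeline_stage("write_streams", {
    write_tweet_jsonl(corpus, file.path(out_dir, "corpus.jsonl"))
    write_tweet_jsonl(streams$prospective,
                      file.path(out_dir, "prospective.jsonl"))
    write_tweet_jsonl(streams$retrospective,
                      file.path(out_dir, "retrospective.jsonl"))
  })

  merged <- pipeline_stage("merge", {
    pros <- dedupe_by_id(read_tweet_stream(
      file.path(out_dir, "prospective.jsonl")))
    retro <- dedupe_by_id(read_tweet_stream(
      file.path(out_dir, "retrospective.jsonl")))
    m <- merge_sources(pros, retro, match_map = streams$match_map,
                       query = query)
    write_merge_report(m$report, file.path(out_dir, "merge_report.json"))
    m
  })
  english <- pipeline_stage("filter_language",
                            filter_language(merged$merged, "en"))
  pipeline_stage("write_merged",
                 write_tweet_jsonl(english,
                                   file.path(out_dir, "merged.jsonl")))

  labels_path <- file.path(out_dir, "labels.csv")
  labeled <- pipeline_stage("labels", {
    set.seed(config$seed + 2L)
    n_lab <- min(config$n_labeled, nrow(english))
    lab <- english[sample.int(nrow(english), n_lab), ]
    write_labels_csv(lab, labels_path)
    list(tweets = lab, labels = load_labels(labels_path))
  })

  models <- pipeline_stage("train", {
    spec <- feature_spec(build_vocabulary(labeled$tweets$text,
                                          max_size = config$vocab_size))
    X <- featurize(labeled$tweets, spec)
    list(
      spec = spec,
      sentiment = fit_tree(X, labeled$labels$sentiment),
      side_effects = fit_linear_pinv(X, labeled$labels$side_effects,
                                     target = "side_effects"),
      prevention = fit_linear_pinv(X, labeled$labels$prevention,
                                   target = "prevention")
    )
  })
  pipeline_stage("write_models", {
    ser <- list(
      vocabulary = models$spec$vocabulary,
      side_effects_weights = as.list(models$side_effects$w),
      prevention_weights = as.list(models$prevention$w),
      sentiment_tree = models$sentiment$root
    )
    jsonlite::write_json(ser, file.path(out_dir, "models.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  classified <- pipeline_stage("classify", {
    rest <- english[!english$tweet_id %in% labeled$tweets$tweet_id, ]
    cl <- classify_corpus(models[c("sentiment", "side_effects",
                                   "prevention")],
                          rest, models$spec,
                          certainty_threshold = config$certainty_threshold)
    utils::write.csv(cl$tweets, file.path(out_dir, "classified.csv"),
                     row.names = FALSE)
    list(result = cl, corpus = rest)
  })

  assoc <- pipeline_stage("associate", {
    dir.create(file.path(out_dir, "associations"), showWarnings = FALSE)
    lapply(stats::setNames(nm = query$keywords), function(kw) {
      tab <- tryCatch(
        association_scores(english, kw, query,
                           min_count = config$min_count),
        warning = function(w) empty_association_table(kw))
      fn <- file.path(out_dir, "associations",
                      paste0(gsub("[^[:alnum:]]", "_", kw), ".csv"))
      utils::write.csv(tab$entries, fn, row.names = FALSE)
      tab
    })
  })

  summary <- pipeline_stage("summarize", {
    kept <- kept_tweets(classified$result, classified$corpus)
    s <- summarize_by_sentiment(kept)
    utils::write.csv(summary_table(s), file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary_table(s), file.path(out_dir,
                                                     "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(summary = s, kept = kept,
         keyword_share = keyword_share(english, query))
  })

  manifest <- list(
    package = "vaxtweets",
    version = as.character(utils::packageVersion("vaxtweets")),
    seed = config$seed,
    boxes = list(
      simulated = nrow(corpus),
      prospective = nrow(streams$prospective),
      retrospective = nrow(streams$retrospective),
      matched = merged$report$n_matched,
      english = nrow(english),
      labeled = nrow(labeled$tweets),
      classified = classified$result$report$n_total,
      kept = classified$result$report$n_kept
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(corpus = corpus, streams = streams, merged = merged,
                 english = english, labeled = labeled, models = models,
                 classified = classified, associations = assoc,
                 summary = summary, manifest = manifest))
}
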