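#' Area under the ROC curve by pair concordance
#'
#' AUC as the probability that a randomly drawn positive outscores a
#' randomly drawn negative, with half credit for ties, computed from the
#' rank-sum (Mann-Whitney) identity.
#'
#' @param scores Numeric score vector.
#' @param labels Binary labels; the larger of the two observed values
#'   (or \code{TRUE}) is the positive class, unless \code{positive} is
#'   given.
#' @param positive Optional value of \code{labels} to treat as positive.
#' @return AUC in [0, 1]; \code{NA} with a warning if only one class is
#'   present.
#' @export
compute_auc <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  if (is.null(positive)) {
    lv <- sort(unique(labels))
    if (length(lv) < 2L) {
      warning("AUC undefined: only one class present")
      return(NA_real_)
    }
    if (length(lv) > 2L) stop("labels must be binary")
    positive <- lv[2L]
  }
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out evaluation of a classifier
#'
#' Trains on n-1 rows and scores the held-out row, n times; the n
#' held-out predictions are pooled and scored once: AUC for a binary
#' target under the linear pseudoinverse model, error fraction for a
#' multiclass target under the tree.
#'
#' For the linear model the default path uses the closed-form identity
#' \eqn{\hat y_{(i)} = (\hat y_i - h_{ii} y_i) / (1 - h_{ii})} with
#' \eqn{h_{ii}} the leverage of the full fit (aliased columns dropped by
#' pivoted QR first); rows with leverage within \code{1e-8} of 1 fall
#' back to explicit retraining, as does \code{method = "retrain"}. The
#' tree is always retrained explicitly.
#'
#' @param X Design matrix.
#' @param y Label vector (binary codes \{1,2\} for \code{"linear"},
#'   3 or more observed classes for \code{"tree"}).
#' @param model_kind \code{"linear"} or \code{"tree"}.
#' @param method \code{"auto"} (closed form where exact) or
#'   \code{"retrain"} (explicit n-fold refit).
#' @param max_depth,min_leaf Tree hyperparameters.
#' @return An \code{eval_result}: \code{auc} or \code{error_fraction},
#'   \code{n}, and the pooled held-out \code{predictions}.
#' @export
loo_evaluate <- function(X, y, model_kind = c("linear", "tree"),
                         method = c("auto", "retrain"),
                         max_depth = 8, min_leaf = 5) {
  model_kind <- match.arg(model_kind)
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out needs at least 3 rows")
  if (length(unique(y)) < 2L)
    stop_undefined("evaluation undefined: single-class labels")

  if (model_kind == "linear") {
    preds <- if (method == "retrain") loo_linear_retrain(X, y)
             else loo_linear_closed(X, y)
    res <- list(auc = compute_auc(preds, y), error_fraction = NA_real_,
                n = n, curve = NULL, predictions = preds)
  } else {
    preds <- vapply(seq_len(n), function(i) {
      fit <- fit_tree(X[-i, , drop = FALSE], y[-i],
                      max_depth = max_depth, min_leaf = min_leaf)
      predict_tree(fit, X[i, , drop = FALSE])$class
    }, 1L)
    res <- list(auc = NA_real_, error_fraction = mean(preds != y),
                n = n, curve = NULL, predictions = preds)
  }
  structure(res, class = "eval_result")
}

loo_linear_retrain <- function(X, y) {
  vapply(seq_len(nrow(X)), function(i) {
    fit <- fit_linear_pinv(X[-i, , drop = FALSE], y[-i])
    drop(X[i, , drop = FALSE] %*% fit$w)
  }, 1)
}

loo_linear_closed <- function(X, y) {
  n <- nrow(X)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  Xp <- pinv(X)
  h <- rowSums(X * t(Xp))
  yhat <- drop(X %*% (Xp %*% y))
  preds <- (yhat - h * y) / (1 - h)
  exact <- which(1 - h < 1e-8)
  for (i in exact) {
    fit <- fit_linear_pinv(X[-i, , drop = FALSE], y[-i])
    preds[i] <- drop(X[i, , drop = FALSE] %*% fit$w)
  }
  preds
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result> n =", x$n)
  if (!is.na(x$auc)) cat(", LOO AUC =", format(x$auc, digits = 4))
  if (!is.na(x$error_fraction))
    cat(", LOO error fraction =", format(x$error_fraction, digits = 4))
  cat("\n")
  invisible(x)
}

#' Learning curve of leave-one-out AUC
#'
#' For each subsample size m, draws \code{reps} random subsamples of the
#' labelled data and records the mean and standard deviation of the LOO
#' AUC (linear) or error fraction (tree). Subsamples with a single class
#' are redrawn (up to 50 attempts). Sizes below 4 are skipped with a
#' warning.
#'
#' @param X,y Labelled design matrix and labels.
#' @param sizes Integer vector of subsample sizes (each <= n).
#' @param reps Subsamples per size.
#' @param seed RNG seed; the same seed reproduces the curve exactly.
#' @param model_kind As in [loo_evaluate()].
#' @param ... Passed to [loo_evaluate()].
#' @return Tibble with columns \code{m}, \code{mean_auc}, \code{sd_auc}
#'   (named \code{mean_error}/\code{sd_error} for the tree).
#' @export
learning_curve <- function(X, y, sizes, reps = 5, seed = 1,
                           model_kind = "linear", ...) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (max(sizes) > n) stop("subsample sizes cannot exceed nrow(X)")
  if (any(sizes < 4)) {
    warning("sizes below 4 skipped")
    sizes <- sizes[sizes >= 4]
  }
  set.seed(seed)
  metric <- if (model_kind == "linear") "auc" else "error_fraction"
  rows <- lapply(sort(sizes), function(m) {
    vals <- vapply(seq_len(reps), function(r) {
      for (attempt in 1:50) {
        idx <- if (m == n) seq_len(n) else sample.int(n, m)
        if (length(unique(y[idx])) >= 2L) break
      }
      res <- loo_evaluate(X[idx, , drop = FALSE], y[idx],
                          model_kind = model_kind, ...)
      res[[metric]]
    }, 1)
    tibble::tibble(m = m, mean = mean(vals),
                   sd = if (reps > 1) stats::sd(vals) else 0)
  })
  out <- dplyr::bind_rows(rows)
  names(out)[2:3] <- if (metric == "auc") c("mean_auc", "sd_auc")
                     else c("mean_error", "sd_error")
  out
}
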