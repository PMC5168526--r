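#' Moore-Penrose pseudoinverse
#'
#' SVD-based pseudoinverse: singular values below
#' \code{tol * max(singular value)} are treated as zero, so the result is
#' the exact minimum-norm generalized inverse of rank-deficient designs.
#'
#' @param X Numeric matrix.
#' @param tol Relative singular-value cutoff.
#' @return The p x n pseudoinverse of the n x p matrix \code{X}.
#' @export
pinv <- function(X, tol = 1e-10) {
  X <- as.matrix(X)
  if (all(X == 0)) return(matrix(0, ncol(X), nrow(X)))
  s <- svd(X)
  keep <- s$d > tol * s$d[1]
  if (!any(keep)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Fit the pseudoinverse linear classifier
#'
#' Regresses the numeric label codes on the design matrix through the
#' Moore-Penrose pseudoinverse, \code{w = pinv(X) y}: the minimum-norm
#' least-squares solution. Used for the binary codebook variables coded
#' \{1 = absent, 2 = present\}.
#'
#' @param X Design matrix (n x p), e.g. from [featurize()].
#' @param y Numeric label vector of length n.
#' @param target Optional name of the target variable.
#' @return An object of class \code{linear_model} with weights \code{w}.
#' @export
fit_linear_pinv <- function(X, y, target = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 training rows")
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)")
  if (all(X == 0)) {
    warning("degenerate all-zero design matrix; returning zero weights")
    w <- rep(0, ncol(X))
  } else {
    w <- drop(pinv(X) %*% y)
  }
  names(w) <- colnames(X)
  structure(list(w = w, target = target,
                 feature_spec = attr(X, "spec")),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat("<linear_model>", length(x$w), "weights",
      if (!is.null(x$target)) paste0("for '", x$target, "'"), "\n")
  invisible(x)
}

#' Score tweets with a fitted linear model
#'
#' @param model A [fit_linear_pinv()] model.
#' @param X Design matrix built with the same feature spec.
#' @return Numeric vector of raw scores \code{X w}.
#' @export
predict_linear <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$w))
    stop("dimension mismatch: model has ", length(model$w),
         " weights, X has ", ncol(X), " columns")
  drop(X %*% model$w)
}
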