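#' Fit a CART-style classification tree
#'
#' Greedy binary splits minimizing weighted Gini impurity, used for the
#' multiclass sentiment variable. Candidate thresholds are midpoints
#' between consecutive distinct feature values; both children must hold
#' at least \code{min_leaf} rows. Ties between candidate splits break
#' deterministically toward the lowest feature index, then the lowest
#' threshold. Leaves store the class distribution over the codes
#' observed in the training data.
#'
#' @param X Design matrix (n x p).
#' @param y Integer class codes.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param min_leaf Minimum rows per leaf.
#' @return An object of class \code{tree_model}.
#' @export
fit_tree <- function(X, y, max_depth = 8, min_leaf = 5) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  classes <- sort(unique(y))
  root <- grow_node(X, as.integer(y), classes, depth = 0L,
                    max_depth = max_depth, min_leaf = min_leaf)
  structure(list(root = root, classes = classes,
                 max_depth = max_depth, min_leaf = min_leaf,
                 feature_spec = attr(X, "spec")),
            class = "tree_model")
}

make_leaf <- function(y, classes) {
  dist <- tabulate(match(y, classes), length(classes)) / length(y)
  names(dist) <- classes
  list(leaf = TRUE, dist = dist,
       class = classes[which.max(dist)],  # ties -> lowest code
       n = length(y))
}

grow_node <- function(X, y, classes, depth, max_depth, min_leaf) {
  n <- length(y)
  if (depth >= max_depth || n < 2 * min_leaf || length(unique(y)) == 1L)
    return(make_leaf(y, classes))
  sp <- best_gini_split(X, y, classes, min_leaf)
  if (is.null(sp)) return(make_leaf(y, classes))
  left <- X[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = grow_node(X[left, , drop = FALSE], y[left], classes,
                        depth + 1L, max_depth, min_leaf),
       right = grow_node(X[!left, , drop = FALSE], y[!left], classes,
                         depth + 1L, max_depth, min_leaf))
}

# Exhaustive scan over features and midpoint thresholds; returns NULL
# when no split satisfies the min_leaf constraint or improves impurity.
best_gini_split <- function(X, y, classes, min_leaf) {
  n <- length(y)
  k <- length(classes)
  y_idx <- match(y, classes)
  best <- list(score = Inf, feature = NA_integer_, threshold = NA_real_)
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]
    cuts <- which(xs[-n] < xs[-1])          # i: split after position i
    cuts <- cuts[cuts >= min_leaf & (n - cuts) >= min_leaf]
    if (length(cuts) == 0L) next
    Yc <- apply(matrix(as.numeric(
      outer(y_idx[ord], seq_len(k), "==")), n, k), 2L, cumsum)
    L <- Yc[cuts, , drop = FALSE]
    R <- matrix(Yc[n, ], length(cuts), k, byrow = TRUE) - L
    nl <- cuts
    nr <- n - cuts
    g <- (nl - rowSums(L^2) / nl) + (nr - rowSums(R^2) / nr)
    i <- which.min(g)                        # ties -> lowest threshold
    if (g[i] < best$score - 1e-12) {
      best <- list(score = g[i], feature = j,
                   threshold = (xs[cuts[i]] + xs[cuts[i] + 1]) / 2)
    }
  }
  if (!is.finite(best$score)) return(NULL)
  # no-gain guard: impurity of the parent
  parent <- n - sum(tabulate(y_idx, k)^2) / n
  if (best$score >= parent - 1e-12) return(NULL)
  best
}

#' @export
print.tree_model <- function(x, ...) {
  count <- function(nd) if (nd$leaf) 1L else count(nd$left) + count(nd$right)
  cat("<tree_model>", length(x$classes), "classes,", count(x$root),
      "leaves\n")
  invisible(x)
}

#' Predict classes and certainties from a fitted tree
#'
#' Each row is routed to a leaf; the assigned class is the argmax of the
#' leaf class distribution (ties break to the lowest code) and the
#' certainty is the leaf majority fraction.
#'
#' @param model A [fit_tree()] model.
#' @param X Design matrix with the columns the model was trained on.
#' @return Tibble with \code{class} and \code{certainty}; the full leaf
#'   distributions are attached as attribute \code{"dist"}.
#' @export
predict_tree <- function(model, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  cls <- integer(n)
  cert <- numeric(n)
  dist <- matrix(NA_real_, n, length(model$classes),
                 dimnames = list(NULL, model$classes))
  route <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (node$leaf) {
      cls[idx] <<- node$class
      cert[idx] <<- max(node$dist)
      dist[idx, ] <<- matrix(node$dist, length(idx), length(node$dist),
                             byrow = TRUE)
      return()
    }
    left <- X[idx, node$feature] <= node$threshold
    route(node$left, idx[left])
    route(node$right, idx[!left])
  }
  route(model$root, seq_len(n))
  out <- tibble::tibble(class = cls, certainty = cert)
  attr(out, "dist") <- dist
  out
}
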