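test_that("AUC handles separation, ties and the 4-point worked example", {
  expect_equal(compute_auc(c(5, 6, 1, 2), c(2, 2, 1, 1)), 1.0)
  expect_equal(compute_auc(rep(3, 6), c(1, 2, 1, 2, 1, 2)), 0.5)
  expect_equal(compute_auc(c(0.9, 0.8, 0.7, 0.6), c(2, 1, 2, 1)), 0.75)
  expect_warning(a <- compute_auc(1:4, rep(2, 4)), "one class")
  expect_true(is.na(a))
})

test_that("AUC equals brute-force pair concordance, incl. ties", {
  set.seed(60)
  for (n in c(10, 57, 200)) {
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    l <- sample(1:2, n, replace = TRUE)
    expect_equal(compute_auc(s, l), brute_auc(s, l), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(61)
  s <- rnorm(80)
  l <- sample(1:2, 80, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(l, s, levels = c(1, 2),
                                        direction = "<", quiet = TRUE)))
  expect_equal(compute_auc(s, l), ref, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(62)
  s <- rnorm(50)
  l <- sample(1:2, 50, replace = TRUE)
  a <- compute_auc(s, l)
  expect_equal(compute_auc(exp(s), l), a)
  expect_equal(compute_auc(3 * s - 7, l), a)
  expect_equal(compute_auc(rank(s), l), a)
})

test_that("closed-form LOO equals explicit retraining on full-rank designs", {
  set.seed(63)
  for (r in 1:10) {
    n <- sample(8:15, 1)
    p <- sample(2:4, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(1:2, n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- 3L - y[1]
    a <- loo_evaluate(X, y, "linear", method = "auto")
    b <- loo_evaluate(X, y, "linear", method = "retrain")
    expect_equal(a$predictions, b$predictions, tolerance = 1e-8)
    expect_equal(a$auc, b$auc, tolerance = 1e-8)
  }
})

test_that("LOO is perfect on separable data and null on unmarked data", {
  d <- labeled_design(60, marker_strength = 1, seed = 64,
                      vocabulary = side_effect_vocab(),
                      p_side_effects_given_sentiment = rep(0.5, 4))
  y <- d$tweets$latent_side_effects
  expect_equal(loo_evaluate(d$X, y, "linear")$auc, 1.0)

  d0 <- labeled_design(200, marker_strength = 0, seed = 65, vocab = 150)
  y0 <- d0$tweets$latent_side_effects
  a0 <- loo_evaluate(d0$X, y0, "linear")$auc
  n1 <- sum(y0 == 2); n0 <- sum(y0 == 1)
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))  # null SE of the rank-sum AUC
  expect_lt(abs(a0 - 0.5), 3 * se)
})

test_that("single-class labels raise the undefined signal", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(loo_evaluate(X, rep(2L, 10), "tree"),
               class = "vaxtweets_undefined")
  expect_error(loo_evaluate(X, rep(1L, 10), "linear"),
               class = "vaxtweets_undefined")
})

test_that("tree LOO reports an error fraction on multiclass labels", {
  d <- labeled_design(40, marker_strength = 1, seed = 66, vocab = 100)
  y <- d$tweets$latent_sentiment
  res <- loo_evaluate(d$X, y, "tree", min_leaf = 3)
  expect_true(is.na(res$auc))
  expect_gte(res$error_fraction, 0)
  expect_lte(res$error_fraction, 1)
})

test_that("learning curve at m = n with one rep equals plain LOO", {
  d <- labeled_design(30, marker_strength = 0.9, seed = 67,
                      vocabulary = side_effect_vocab(),
                      p_side_effects_given_sentiment = rep(0.5, 4))
  y <- d$tweets$latent_side_effects
  lc <- learning_curve(d$X, y, sizes = nrow(d$X), reps = 1, seed = 1)
  expect_equal(lc$mean_auc, loo_evaluate(d$X, y, "linear")$auc)
  expect_equal(lc$sd_auc, 0)
})

test_that("learning curve is reproducible and non-decreasing when separable", {
  d <- labeled_design(90, marker_strength = 1, seed = 68,
                      vocabulary = side_effect_vocab(),
                      p_side_effects_given_sentiment = rep(0.5, 4))
  y <- d$tweets$latent_side_effects
  lc1 <- learning_curve(d$X, y, sizes = c(20, 40, 80), reps = 3, seed = 9)
  lc2 <- learning_curve(d$X, y, sizes = c(20, 40, 80), reps = 3, seed = 9)
  expect_identical(lc1, lc2)
  expect_true(all(diff(lc1$mean_auc) >= -1e-12))
  expect_warning(learning_curve(d$X, y, sizes = c(3, 20), reps = 1),
                 "skipped")
})

test_that("binary label structure is recovered from a realistic labelled set", {
  d <- labeled_design(1470, marker_strength = 0.8, seed = 69)
  for (v in c("latent_side_effects", "latent_prevention")) {
    auc <- loo_evaluate(d$X, d$tweets[[v]], "linear")$auc
    expect_gte(auc, 0.9)
  }
})
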