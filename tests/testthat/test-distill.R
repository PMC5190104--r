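make_two_class <- function(n = 60, p = 20, informative = 10, delta = 4,
                           seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  X[y == 1, seq_len(informative)] <- X[y == 1, seq_len(informative)] + delta
  list(X = X, y = y)
}

test_that("well-separated classes give near-perfect PCA clustering metrics", {
  d <- make_two_class(seed = 5)
  res <- pca_overview(d$X, d$y, cfg = list(seed = 1))
  expect_gte(res$auc, 0.95)
  expect_gte(res$sensitivity, 0.9)
  expect_gte(res$specificity, 0.9)
})

test_that("PCA overview validates inputs and variance fractions", {
  d <- make_two_class(seed = 6)
  expect_error(pca_overview(d$X, rep(1, nrow(d$X))), "single class")
  Xc <- cbind(d$X, const = 1)
  expect_warning(res <- pca_overview(Xc, d$y), "constant")
  expect_lte(sum(res$explained), 1)
  expect_gte(res$explained[1], res$explained[2])
  expect_true(all(res$explained >= 0))
})

test_that("a pure-noise companion feature is eliminated before the informative one", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 80
    y <- rep(c(0L, 1L), each = n / 2)
    X <- cbind(signal = rnorm(n) + 2.5 * y, noise = rnorm(n))
    r <- rf_iterative_reduce(X, y, cfg = list(n_trees = 200, seed = s))
    first_drop <- r$trace$dropped[1]
    if (is.na(first_drop) || first_drop == "noise") hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("the elimination trace shrinks by one feature per iteration", {
  d <- make_two_class(n = 40, p = 8, informative = 2, delta = 2, seed = 9)
  r <- rf_iterative_reduce(d$X, d$y, cfg = list(n_trees = 200, seed = 2))
  expect_lte(nrow(r$trace), ncol(d$X))
  expect_equal(r$trace$n_features,
               seq(ncol(d$X), by = -1L, length.out = nrow(r$trace)))
  expect_true(all(unlist(r$importance) >= 0))
  expect_true(all(r$selected %in% colnames(d$X)))
  expect_error(rf_iterative_reduce(d$X[, 1, drop = FALSE], d$y), "2 features")
  expect_error(rf_iterative_reduce(d$X, rep(0, nrow(d$X))), "single class")
})

test_that("CART thresholds fall at midpoints between adjacent values", {
  X <- data.frame(x = c(rep(1, 10), rep(3, 10)))
  y <- c(rep(0L, 10), rep(1L, 10))
  ct <- cart_fit(X, y, cfg = list(min_leaf = 2, folds = 5, seed = 1))
  expect_identical(ct$root_feature, "x")
  expect_identical(ct$root_threshold, 2)
})

test_that("CART recovers a planted step threshold inside the empirical gap", {
  set.seed(42)
  x <- runif(100, 0, 70000)
  y <- as.integer(x > 35647)
  ct <- cart_fit(data.frame(area = x), y, cfg = list(seed = 3))
  gap <- c(max(x[y == 0]), min(x[y == 1]))
  expect_identical(ct$root_feature, "area")
  expect_gt(ct$root_threshold, gap[1])
  expect_lt(ct$root_threshold, gap[2])
  expect_equal(ct$metrics$specificity, 100)
  expect_equal(ct$metrics$sensitivity, 100)
})

test_that("pure-noise features prune to a single leaf in most seeds", {
  single <- 0L
  for (s in 1:5) {
    set.seed(s + 100)
    X <- matrix(rnorm(60 * 5), 60, 5,
                dimnames = list(NULL, paste0("n", 1:5)))
    y <- rep(c(0L, 1L), 30)
    ct <- suppressWarnings(cart_fit(X, y, cfg = list(seed = s)))
    if (ct$single_leaf) single <- single + 1L
  }
  expect_gte(single, 4L)
})

test_that("end-to-end distillation recovers a single planted driver", {
  set.seed(7)
  n <- 120
  X <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, paste0("f", 1:30)))
  drv <- runif(n, 0, 70000)
  X[, 12] <- drv; colnames(X)[12] <- "area_pdc_um2"
  y <- as.integer(drv > 35647)
  r <- rf_iterative_reduce(X, y, cfg = list(n_trees = 250, seed = 4))
  expect_true("area_pdc_um2" %in% r$selected)
  ct <- cart_fit(X[, r$selected, drop = FALSE], y, cfg = list(seed = 4))
  expect_identical(ct$root_feature, "area_pdc_um2")
  gap <- c(max(drv[y == 0]), min(drv[y == 1]))
  expect_gt(ct$root_threshold, gap[1])
  expect_lt(ct$root_threshold, gap[2])
})
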