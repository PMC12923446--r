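test_that("constant outputs give a single-leaf tree", {
  set.seed(1)
  X <- matrix(runif(20), 10, 2)
  tr <- fit_tree(X, rep(4.2, 10))
  expect_equal(length(tr$feature), 1L)
  expect_true(is.na(tr$feature[1]))
  expect_equal(predict(tr, matrix(runif(6), 3, 2)), rep(4.2, 3))
})

test_that("an unconstrained tree memorizes distinct examples", {
  X <- matrix(c(0, 1, 2, 3), 4, 1)
  y <- c(5, -1, 2, 7)
  tr <- fit_tree(X, y, n_test = 1)
  expect_equal(predict(tr, X), y)
})

test_that("root split matches the exhaustive enumeration oracle", {
  X <- matrix(c(0, 1, 2), 3, 1)
  y <- c(0, 0, 3)
  w <- c(1, 1, 2)
  set.seed(2)
  tr <- fit_tree(X, y, w, n_test = 1)
  ref <- oracle_best_split(X[, 1], y, w)
  expect_equal(tr$threshold[1], ref$threshold)
  # recorded reduction is per unit of node weight
  expect_equal(tr$reduction[1] * tr$node_w[1], ref$gain)

  # random problems: root gain/threshold match the oracle on each feature
  for (seed in 1:5) {
    set.seed(seed)
    n <- 25
    Xr <- matrix(runif(n), n, 1)
    yr <- rnorm(n)
    wr <- runif(n, 0.2, 2)
    tr <- fit_tree(Xr, yr, wr, n_test = 1, max_height = 2)
    ref <- oracle_best_split(Xr[, 1], yr, wr)
    expect_equal(tr$threshold[1], ref$threshold)
    expect_equal(tr$reduction[1] * tr$node_w[1], ref$gain, tolerance = 1e-10)
  }
})

test_that("constant weight rescaling leaves the tree unchanged", {
  toy <- toy_regression()
  set.seed(31)
  t1 <- fit_tree(toy$X, toy$y, rep(1, 40), n_test = 2)
  set.seed(31)
  t2 <- fit_tree(toy$X, toy$y, rep(7.3, 40), n_test = 2)
  expect_equal(t1$feature, t2$feature)
  expect_equal(t1$threshold, t2$threshold)
  expect_equal(t1$value, t2$value)
})

test_that("example order does not change the fitted tree", {
  toy <- toy_regression(seed = 8)
  perm <- sample(40)
  grid <- matrix(runif(80), 20, 4)
  set.seed(55)
  t1 <- fit_tree(toy$X, toy$y, toy$w, n_test = 2)
  set.seed(55)
  t2 <- fit_tree(toy$X[perm, ], toy$y[perm], toy$w[perm], n_test = 2)
  expect_equal(predict(t1, grid), predict(t2, grid))
})

test_that("tree fitting validates its inputs", {
  X <- matrix(1:4, 2, 2)
  expect_error(fit_tree(X, c(1, 2), w = c(0, 0)),
               class = "sgn_validation_error")
  expect_error(fit_tree(X, c(1, NA)), class = "sgn_validation_error")
  expect_error(fit_tree(X[0, , drop = FALSE], numeric(0)),
               class = "sgn_validation_error")
})

test_that("inner forest shares one sample and excludes the target column", {
  set.seed(3)
  X <- matrix(runif(200), 40, 5)
  forest <- fit_genie3_forest(X, target_gene = 3,
                              params = forest_params(n_subtree = 50))
  expect_length(forest, 50)
  expect_equal(attr(forest, "input_cols"), c(1, 2, 4, 5))
  for (tr in forest) {
    expect_equal(attr(tr, "n_features"), 4L)
    f <- tr$feature[!is.na(tr$feature)]
    expect_true(all(f >= 1 & f <= 4))
  }
})

test_that("a perfectly informative regulator tops aggregate importance", {
  set.seed(4)
  X1 <- runif(60)
  X <- cbind(X1, 2 * X1, matrix(runif(180), 60, 3))
  forest <- fit_genie3_forest(X, target_gene = 2,
                              params = forest_params(n_subtree = 25,
                                                     n_test = 2))
  vi <- variance_importance(forest)
  expect_equal(which.max(vi), 1L)
  ri <- random_input_importance(forest, X[, -2], X[, 2], n_rnd = 3)
  expect_equal(which.max(ri), 1L)
})

test_that("variance importance is exact on a single split and conserved", {
  X <- matrix(c(0, 1, 2), 3, 1)
  y <- c(0, 0, 3)
  w <- c(1, 1, 2)
  set.seed(5)
  tr <- fit_tree(X, y, w, n_test = 1)
  # hand computation: parent SSE 9, children pure, node weight 4
  expect_equal(variance_importance(list(tr), 1), 9)

  toy <- toy_regression(seed = 12)
  set.seed(6)
  trees <- lapply(1:5, function(i) fit_tree(toy$X, toy$y, toy$w, n_test = 2))
  vi <- variance_importance(trees)
  total_mass <- mean(vapply(trees, function(t) {
    int <- !is.na(t$feature)
    sum(t$reduction[int] * t$node_w[int])
  }, numeric(1)))
  expect_equal(sum(vi), total_mass, tolerance = 1e-10)
  # symmetric in tree order
  expect_equal(vi, variance_importance(rev(trees)))
  # a feature never split on scores zero
  Xc <- cbind(toy$X, 0.5)
  set.seed(7)
  tc <- fit_tree(Xc, toy$y, toy$w, n_test = 5)
  expect_equal(variance_importance(list(tc), 5)[5], 0)
})

test_that("permutation importance: unused exactly zero, used positive", {
  toy <- toy_regression(seed = 13)
  Xc <- cbind(toy$X, constant = 0.5)
  set.seed(8)
  tr <- fit_tree(Xc, toy$y, toy$w, n_test = 5)
  sc <- random_input_importance(list(tr), Xc, toy$y, toy$w, n_rnd = 3)
  expect_identical(sc[5], 0)
  # memorizing tree: permuting its informative feature must hurt
  X <- matrix(c(0, 1, 2, 3), 4, 1)
  y <- c(5, -1, 2, 7)
  tm <- fit_tree(X, y, n_test = 1)
  set.seed(9)
  expect_gt(random_input_importance(list(tm), X, y, n_rnd = 5)[1], 0)
})

test_that("permutation importance matches the exhaustive 4! oracle", {
  # single-split tree on 4 examples, scores = mean over all permutations
  X <- matrix(c(0, 1, 2, 3), 4, 1)
  y <- c(0, 0, 1, 1)
  w <- c(1, 2, 1, 1)
  set.seed(10)
  tr <- fit_tree(X, y, w, n_test = 1, max_height = 2)
  W <- sum(w)
  base_pred <- predict(tr, X)
  mse0 <- sum(w * (base_pred - y)^2) / W
  perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  incr <- apply(perms, 1, function(p) {
    pred <- predict(tr, matrix(X[p, 1], 4, 1))
    sum(w * (pred - y)^2) / W - mse0
  })
  set.seed(11)
  mc <- random_input_importance(list(tr), X, y, w, n_rnd = 4000)[1]
  mc_se <- sd(incr) / sqrt(4000)
  expect_lt(abs(mc - mean(incr)), 4 * mc_se + 1e-12)
})

test_that("ensemble JSON serialization round-trips predictions", {
  toy <- toy_regression(seed = 14)
  set.seed(12)
  trees <- lapply(1:3, function(i) fit_tree(toy$X, toy$y, toy$w, n_test = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_ensemble_json(trees, path)
  back <- read_ensemble_json(path)
  grid <- matrix(runif(40), 10, 4)
  for (i in 1:3) expect_equal(predict(back[[i]], grid),
                              predict(trees[[i]], grid))
})
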