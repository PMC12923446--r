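test_that("bootstrap draws uniformly with replacement", {
  expect_equal(boot_indices(1), 1L)
  set.seed(1)
  draws <- boot_indices(50)
  expect_length(draws, 50)
  expect_true(all(draws %in% 1:50))
  # frequency check: 2000 x 5 = 10000 draws, each index ~ Bin(10000, 1/5)
  set.seed(2)
  counts <- tabulate(unlist(replicate(2000, boot_indices(5),
                                      simplify = FALSE)), 5)
  sigma <- sqrt(10000 * 0.2 * 0.8)
  expect_true(all(abs(counts - 2000) < 3 * sigma))
  expect_error(boot_indices(0), class = "sgn_validation_error")
})

test_that("under-sampling cutoffs follow the prefix rule", {
  # all weights 1: both cutoffs are min(|D+|, |D-|)
  u <- undersample_counts(rep(1, 10), rep(1, 4))
  expect_equal(u$k_plus, 4L)
  expect_equal(u$k_minus, 4L)
  expect_equal(u$w_mass_plus, 10)
  expect_equal(u$w_mass_minus, 4)
  # weighted: prefix sums 0.5, 1.0 reach W- = 1 at K+ = 2
  u <- undersample_counts(c(0.5, 0.5, 2.0), 1.0)
  expect_equal(u$k_plus, 2L)
  expect_equal(u$k_minus, 1L)
  # empty side: zero mass forces all cutoffs to zero
  u <- undersample_counts(numeric(0), c(1, 1))
  expect_equal(u$k_plus, 0L)
  expect_equal(u$k_minus, 0L)
  u <- undersample_counts(c(1, 1), numeric(0))
  expect_equal(u$k_plus, 0L)
  expect_equal(u$k_minus, 0L)
})

test_that("tree penalty matches direct recomputation and vanishes when
           signs are honored", {
  # single-leaf trees let us dictate predictions exactly
  leaf_tree <- function(v) structure(
    list(feature = NA_integer_, threshold = NA_real_, left = NA_integer_,
         right = NA_integer_, value = v, reduction = 0, node_w = 1),
    n_features = 2L, class = "sgn_tree")

  Xp <- matrix(runif(6), 3, 2)
  xp <- c(1.0, 0.4, 0.7)
  wp <- c(1, 2, 0.5)
  Xm <- matrix(runif(4), 2, 2)
  xm <- c(0.2, 0.9)
  wm <- c(1.5, 1)

  # prediction above every '+' level and below every '-' level: zero
  expect_equal(tree_penalty(leaf_tree(5), Xp, xp, wp, NULL, NULL, NULL), 0)
  expect_equal(tree_penalty(leaf_tree(0.1), NULL, NULL, NULL, Xm, xm, wm), 0)

  # the printed one-example case: max{-(0.5 - 1), 0} = 0.5
  expect_equal(tree_penalty(leaf_tree(0.5), matrix(0, 1, 2), 1, 1,
                            NULL, NULL, NULL), 0.5)

  # mixed fixture vs term-by-term recomputation
  v <- 0.6
  expected <- sum(wp * pmax(-(v - xp), 0)) + sum(wm * pmax(v - xm, 0))
  expect_equal(tree_penalty(leaf_tree(v), Xp, xp, wp, Xm, xm, wm), expected)

  # monotone: raising the predicted gap cannot increase the '+' hinge
  pens <- sapply(seq(0, 2, by = 0.1), function(v)
    tree_penalty(leaf_tree(v), Xp, xp, wp, NULL, NULL, NULL))
  expect_true(all(diff(pens) <= 1e-12))
  expect_true(all(pens >= 0))
})

test_that("tree selection takes the smallest penalty, ties to the left", {
  expect_equal(select_best_tree(c(3, 1, 2)), 2L)
  expect_equal(select_best_tree(c(1, 1)), 1L)
  expect_equal(select_best_tree(4.2), 1L)
  expect_error(select_best_tree(numeric(0)), class = "sgn_validation_error")
})

test_that("subproblem inference builds exactly n_tree trees and the
           selected penalty is the per-iteration minimum", {
  fx <- make_fixture("tiny", seed = 3)
  subs <- build_subproblems(fx$data)
  params <- forest_params(n_tree = 12, n_subtree = 6, n_rnd = 2)
  set.seed(21)
  res <- infer_subproblem(subs$g2, params, keep_penalties = TRUE)
  expect_length(res$trees, 12)
  expect_length(res$boot_idx, 12)
  expect_equal(res$selected_penalty, apply(res$penalties, 1, min))
  expect_true(all(res$selected_penalty <= res$penalties + 1e-12))
  expect_error(infer_subproblem(
    structure(modifyList(subs$g2, list(sets = list(plus = integer(0),
                                                   minus = integer(0),
                                                   zero = integer(0),
                                                   excluded = integer(0)))),
              class = "sgn_subproblem"), params),
    class = "sgn_no_steady_error")
})

test_that("with empty '+'/'-' sets the pipeline equals modified GENIE3
           under a shared seed", {
  fx <- make_fixture("tiny", seed = 4)
  subs <- build_subproblems(fx$data)
  s <- subs$g3
  s$sets$plus <- integer(0)
  s$sets$minus <- integer(0)
  params <- forest_params(n_tree = 15, n_subtree = 5, n_rnd = 3)
  set.seed(99)
  r1 <- infer_subproblem(s, params)
  set.seed(99)
  c1 <- compute_confidences(r1, params)
  set.seed(99)
  r2 <- infer_subproblem(s, params, genie3_only = TRUE)
  set.seed(99)
  c2 <- compute_confidences(r2, params)
  expect_identical(c1, c2)
})

test_that("the cascade's true regulator of g2 attains top confidence", {
  fx <- make_fixture("tiny", seed = 3)
  net <- infer_network(fx$data, forest_params(), seed = 11)
  g2_edges <- net[net$target == "g2", ]
  expect_equal(g2_edges$regulator[which.max(g2_edges$confidence)], "g1")
})

test_that("confidence averaging over more repetitions is more stable", {
  fx <- make_fixture("tiny", seed = 3)
  subs <- build_subproblems(fx$data)
  set.seed(33)
  res <- infer_subproblem(subs$g2, forest_params(n_tree = 20, n_subtree = 5))
  reps <- function(n_rnd) sapply(1:8, function(i) {
    set.seed(400 + i)
    compute_confidences(res, forest_params(n_tree = 20, n_subtree = 5,
                                           n_rnd = n_rnd))[1]
  })
  expect_lt(sd(reps(25)), sd(reps(1)))
})

test_that("network assembly: self-edges excluded, stimulus only a
           regulator, deterministic under a seed", {
  fx <- make_fixture("tiny", seed = 5, stimulus = TRUE)
  params <- forest_params(n_tree = 10, n_subtree = 4, n_rnd = 2)
  net <- infer_network(fx$data, params, seed = 42)
  N <- 3
  expect_equal(nrow(net), N * (N - 1) + N)
  expect_true(all(net$regulator != net$target))
  expect_false("stimulus" %in% net$target)
  expect_true("stimulus" %in% net$regulator)
  expect_equal(net$rank, seq_len(nrow(net)))
  expect_true(all(diff(net$confidence) <= 0))

  net2 <- infer_network(fx$data, params, seed = 42)
  expect_identical(net, net2)

  fx0 <- make_fixture("tiny", seed = 5)
  net3 <- infer_network(fx0$data, params, seed = 42)
  expect_equal(nrow(net3), N * (N - 1))
})
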