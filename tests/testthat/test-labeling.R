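test_that("local-linear smoother reproduces constants and affine series", {
  set.seed(1)
  pt <- sort(runif(30))
  const <- smooth_series(pt, rep(2.5, 30), span = 0.3)
  expect_equal(const$sm, rep(2.5, 30))
  expect_equal(const$sl, rep(0, 30))

  aff <- smooth_series(pt, 3 * pt + 1, span = 0.4)
  expect_equal(aff$sm, 3 * pt + 1, tolerance = 1e-10)
  expect_equal(aff$sl, rep(3, 30), tolerance = 1e-8)
})

test_that("smoother matches the per-point weighted least-squares oracle", {
  set.seed(7)
  pt <- sort(runif(60))
  x <- sin(2 * pi * pt) + rnorm(60, 0, 0.2)
  fit <- smooth_series(pt, x, span = 0.3)
  for (i in c(1, 7, 23, 30, 44, 60)) {
    ref <- oracle_loclin(pt, x, pt[i], 0.3)
    expect_equal(fit$sm[i], ref[1], tolerance = 1e-8)
    expect_equal(fit$sl[i], ref[2], tolerance = 1e-8)
  }
})

test_that("smoother validates its inputs", {
  expect_error(smooth_series(1:5 / 5, 1:5), class = "sgn_validation_error")
  expect_error(smooth_series(rep(0.5, 12), rnorm(12)),
               class = "sgn_degenerate_error")
  expect_error(smooth_series(sort(runif(12)), rnorm(12), span = 0),
               class = "sgn_validation_error")
  expect_error(smooth_series(sort(runif(12)), c(rnorm(11), NA)),
               class = "sgn_validation_error")
})

test_that("labeling rule follows the printed order", {
  # rule 2: below the band with a steep positive slope
  expect_equal(assign_label(0.8, sm = 1, sl = 1.5, x_avg = 1), "+")
  # rule 4: inside the band with a flat slope
  expect_equal(assign_label(1.0, sm = 1, sl = 0.1, x_avg = 1), "0")
  # rule 1 precedes everything
  expect_equal(assign_label(5, sm = 1, sl = 5, x_avg = 1, q_hi = 4.9), "X")
  # slope fails the 1.2x bar -> falls through to 'X'
  expect_equal(assign_label(0.8, sm = 1, sl = 1.0, x_avg = 1), "X")
  # mirrored '-' rule
  expect_equal(assign_label(1.2, sm = 1, sl = -1.5, x_avg = 1), "-")
})

test_that("labeling is exhaustive, exclusive and scale-consistent", {
  set.seed(11)
  for (rep in 1:200) {
    x_val <- runif(1, 0, 3)
    sm <- runif(1, 0.1, 3)
    sl <- runif(1, -4, 4)
    x_avg <- runif(1, 0.1, 2)
    q_lo <- runif(1, 0, 0.5)
    q_hi <- runif(1, 2.5, 4)
    lab <- assign_label(x_val, sm, sl, x_avg, q_lo, q_hi)
    expect_true(lab %in% c("+", "-", "0", "X"))
    for (c_scale in c(0.01, 3.7, 1000)) {
      expect_identical(
        assign_label(c_scale * x_val, c_scale * sm, c_scale * sl,
                     c_scale * x_avg, c_scale * q_lo, c_scale * q_hi), lab)
    }
  }
})

test_that("subproblems partition every example exactly once", {
  fx <- make_fixture("tiny", seed = 3)
  subs <- build_subproblems(fx$data)
  n_total <- nrow(fx$data$expr)
  for (s in subs) {
    sizes <- lengths(s$sets)
    expect_equal(sum(sizes), n_total)
    expect_equal(sort(unlist(s$sets, use.names = FALSE)), seq_len(n_total))
    # every steady-state cell carries '0'
    expect_true(all(s$y[s$role == "steady"] == "0"))
  }
})

test_that("steady-state-only data gives all-'0' subproblems", {
  set.seed(5)
  expr <- matrix(runif(300, 1, 2), 100, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  data <- expression_dataset(expr, rep(NA_real_, 100))
  subs <- build_subproblems(data)
  for (s in subs) {
    expect_equal(length(s$sets$zero), 100L)
    expect_equal(length(s$sets$plus) + length(s$sets$minus) +
                   length(s$sets$excluded), 0L)
  }
})

test_that("missing '0' data is a hard error, rescued by tail_as_steady", {
  # steep linear genes: slopes far above the flat threshold, so no pseudo
  # cell can be labeled '0', and there are no steady-state cells
  set.seed(9)
  pt <- sort(runif(60))
  expr <- cbind(a = 3 * pt + 0.2 + rnorm(60, 0, 0.01),
                b = 2.5 * pt + 0.1 + rnorm(60, 0, 0.01))
  data <- expression_dataset(expr, pt)
  expect_error(build_subproblems(data), class = "sgn_no_steady_error")
  subs <- build_subproblems(data, tail_as_steady = TRUE)
  for (s in subs) expect_gt(length(s$sets$zero), 0)
})

test_that("rising cascade gene gets '+' early and '0' late", {
  fx <- make_fixture("tiny", seed = 3)
  subs <- build_subproblems(fx$data)
  pt <- fx$data$pseudotime[!fx$data$is_steady]
  plus_pt <- pt[subs$g2$sets$plus]
  expect_gt(length(plus_pt), 0)
  expect_true(all(plus_pt < 0.5))
})

test_that("labels agree with the simulator's true derivative signs", {
  fx <- make_fixture("bench", seed = 2, noise_sd = 0.1)
  subs <- build_subproblems(fx$data)
  agree <- logical(0)
  for (g in seq_along(subs)) {
    s <- subs[[g]]
    true_d <- fx$sim$ref_dxdt[, g]  # pseudo cells, dataset order
    agree <- c(agree, true_d[s$sets$plus] > 0, true_d[s$sets$minus] < 0)
  }
  expect_gt(length(agree), 20)
  expect_gt(mean(agree), 0.9)
})

test_that("out-of-range pseudotime is rescaled with a warning", {
  expr <- matrix(runif(40, 1, 2), 20, 2)
  expect_warning(d <- expression_dataset(expr, seq(0, 10, length.out = 20)),
                 "rescaling")
  expect_equal(range(d$pseudotime), c(0, 1))
})
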