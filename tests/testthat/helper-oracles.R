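# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: lm() for weighted least squares, explicit
# enumeration for splits, thresholds and permutations, RK4 for the ODE.

# tricube local-linear fit at pt0 via lm(): same window rule as the package
# (q nearest points, bandwidth = max distance), independent solver
oracle_loclin <- function(pt, x, pt0, span) {
  n <- length(pt)
  q <- max(2L, as.integer(ceiling(span * n)))
  d <- abs(pt - pt0)
  sel <- order(d)[seq_len(q)]
  h <- max(d[sel])
  w <- (1 - pmin(d[sel] / h, 1)^3)^3
  keep <- w > 0
  fit <- stats::lm(x[sel][keep] ~ I(pt[sel][keep] - pt0),
                   weights = w[keep])
  unname(c(coef(fit)[1], coef(fit)[2]))
}

# exhaustive best split of one feature: every midpoint between consecutive
# distinct sorted values, weighted-SSE decrease
oracle_best_split <- function(x, y, w) {
  xs <- sort(unique(x))
  sse <- function(yy, ww) {
    if (sum(ww) <= 0) return(0)
    sum(ww * yy^2) - sum(ww * yy)^2 / sum(ww)
  }
  best <- list(gain = -Inf, threshold = NA)
  for (i in seq_len(length(xs) - 1)) {
    thr <- (xs[i] + xs[i + 1]) / 2
    l <- x <= thr
    gain <- sse(y, w) - sse(y[l], w[l]) - sse(y[!l], w[!l])
    if (gain > best$gain) best <- list(gain = gain, threshold = thr)
  }
  best
}

# brute-force precision-recall sweep over distinct thresholds
oracle_pr <- function(conf, is_pos) {
  npos <- sum(is_pos)
  t(sapply(sort(unique(conf), decreasing = TRUE), function(thr) {
    sel <- conf >= thr
    tp <- sum(is_pos & sel)
    c(threshold = thr, recall = tp / npos, precision = tp / sum(sel))
  }))
}

# classical RK4 integration of the network ODE
oracle_rk4 <- function(net, x0, t_max, dt) {
  x <- x0
  for (k in seq_len(round(t_max / dt))) {
    k1 <- network_drift(net, x)
    k2 <- network_drift(net, pmax(0, x + dt / 2 * k1))
    k3 <- network_drift(net, pmax(0, x + dt / 2 * k2))
    k4 <- network_drift(net, pmax(0, x + dt * k3))
    x <- pmax(0, x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
  }
  x
}

# small deterministic regression problem used by several forest tests
toy_regression <- function(n = 40, p = 4, seed = 42) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p)
  y <- 2 * X[, 1] - X[, 3] + rnorm(n, 0, 0.05)
  list(X = X, y = y, w = runif(n, 0.5, 2))
}
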