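#' Local-linear (tricube kernel) smoothing of one pseudo time-series
#'
#' Smooths one gene's expression along pseudotime with Cleveland-style
#' local linear regression: at each evaluation point the `ceiling(span * K)`
#' nearest cells (by pseudotime distance) receive tricube weights and a
#' degree-1 weighted least-squares line is fitted. The returned slope is the
#' local fit's slope coefficient, not a finite difference of the smooth.
#'
#' @param pt pseudotime vector (values in [0, 1]).
#' @param x expression vector of one gene, same length as `pt`.
#' @param span fraction of cells in each local window, in (0, 1].
#' @param eval_pt pseudotimes at which to evaluate (default: every `pt`).
#' @return a data.frame with columns `pt`, `sm` (smoothed level) and `sl`
#'   (local slope d sm / d pt).
#' @export
smooth_series <- function(pt, x, span = 0.3, eval_pt = pt) {
  if (length(pt) != length(x))
    sgn_stop("pt and x must have equal length", class = "sgn_validation_error")
  if (length(pt) < 10L)
    sgn_stop("smoothing needs at least 10 cells",
             class = "sgn_validation_error")
  if (any(!is.finite(pt)) || any(!is.finite(x)))
    sgn_stop("pt and x must be finite", class = "sgn_validation_error")
  if (min(pt) < 0 || max(pt) > 1)
    sgn_stop("pseudotime must lie in [0, 1]", class = "sgn_validation_error")
  if (span <= 0 || span > 1)
    sgn_stop("span must be in (0, 1]", class = "sgn_validation_error")
  if (length(unique(pt)) < 2L)
    sgn_stop("need at least 2 distinct pseudotime values",
             class = "sgn_degenerate_error")

  n <- length(pt)
  q0 <- max(2L, as.integer(ceiling(span * n)))
  sm <- sl <- numeric(length(eval_pt))
  for (i in seq_along(eval_pt)) {
    fit <- local_linear_fit(pt, x, eval_pt[i], q0)
    sm[i] <- fit[1]
    sl[i] <- fit[2]
  }
  data.frame(pt = eval_pt, sm = sm, sl = sl)
}

# one weighted degree-1 fit at pt0 over the q nearest points; widens the
# window when the weighted design is singular (e.g. heavy pseudotime ties)
local_linear_fit <- function(pt, x, pt0, q) {
  n <- length(pt)
  d <- abs(pt - pt0)
  ord <- order(d)
  repeat {
    sel <- ord[seq_len(min(q, n))]
    h <- max(d[sel])
    if (h > 0) {
      w <- (1 - pmin(d[sel] / h, 1)^3)^3
      pos <- w > 0
      if (sum(pos) >= 2L && length(unique(pt[sel][pos])) >= 2L) {
        ws <- w[pos]
        ps <- pt[sel][pos] - pt0   # center so intercept = fit at pt0
        xs <- x[sel][pos]
        sw <- sum(ws); swp <- sum(ws * ps); swpp <- sum(ws * ps * ps)
        swx <- sum(ws * xs); swpx <- sum(ws * ps * xs)
        det <- sw * swpp - swp * swp
        if (det > .Machine$double.eps * sw * max(swpp, 1)) {
          a <- (swpp * swx - swp * swpx) / det
          b <- (sw * swpx - swp * swx) / det
          return(c(a, b))
        }
      }
    }
    if (q >= n) {
      # fully degenerate window: flat fit through the weighted mean
      return(c(sum(x) / n, 0))
    }
    q <- min(n, q + max(1L, q %/% 2L))
  }
}

#' Smooth every gene of a dataset along pseudotime
#'
#' Applies [smooth_series()] to each gene over the pseudo time-series cells
#' and collects the per-gene trajectory statistics the labeling rule needs:
#' smoothed levels, local slopes, the trajectory mean, and the exclusion
#' quantiles. All statistics are computed over pseudo time-series cells only.
#'
#' @param data an [expression_dataset()].
#' @param span smoothing span, see [smooth_series()].
#' @param thresholds a [label_thresholds()] object (supplies `q_exclude`).
#' @return an object of class `sgn_smoothed` with matrices `sm`, `sl`
#'   (pseudo-time cells x genes) and vectors `x_avg`, `q_lo`, `q_hi`.
#' @export
smooth_dataset <- function(data, span = 0.3, thresholds = label_thresholds()) {
  stopifnot(inherits(data, "sgn_dataset"))
  keep <- !data$is_steady
  if (sum(keep) == 0L)
    sgn_stop("no pseudo time-series cells to smooth",
             class = "sgn_validation_error")
  pt <- data$pseudotime[keep]
  E <- data$expr[keep, , drop = FALSE]
  sm <- sl <- matrix(NA_real_, nrow(E), ncol(E), dimnames = dimnames(E))
  for (j in seq_len(ncol(E))) {
    fit <- smooth_series(pt, E[, j], span = span)
    sm[, j] <- fit$sm
    sl[, j] <- fit$sl
  }
  q <- thresholds$q_exclude
  structure(list(
    cell_ids = rownames(E),
    pt = pt,
    sm = sm,
    sl = sl,
    x_avg = colMeans(E),
    q_lo = apply(E, 2, quantile, probs = q, names = FALSE),
    q_hi = apply(E, 2, quantile, probs = 1 - q, names = FALSE),
    span = span
  ), class = "sgn_smoothed")
}
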