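#' Forest and ensemble parameters
#'
#' Bundles the tunable parameters of the inference algorithm. The `"paper"`
#' profile uses the published operating point (`n_tree = 1000`,
#' `n_subtree = 50`, `n_rnd = 100`); the `"reduced"` profile
#' (`n_tree = 100`, `n_subtree = 20`, `n_rnd = 10`) is the default for tests
#' and interactive use and trades ranking stability for roughly 10x speed.
#'
#' @param profile `"reduced"` or `"paper"`; starting point for the values.
#' @param n_tree number of trees in the final selected ensemble.
#' @param n_subtree number of trees per inner GENIE3 forest, from which one
#'   tree is selected each iteration.
#' @param n_test number of candidate input columns examined at each tree
#'   node; `NULL` means `ceiling((N - 1) / 3)` where `N` is the number of
#'   input columns + 1 (i.e. the GENIE3 default for an `N`-gene problem).
#' @param n_hmax maximum tree height (root = height 1).
#' @param n_rnd repetitions of the permutation-importance computation whose
#'   averages become confidence values.
#' @return an object of class `sgn_params`.
#' @export
forest_params <- function(profile = c("reduced", "paper"), n_tree = NULL,
                          n_subtree = NULL, n_test = NULL, n_hmax = 32L,
                          n_rnd = NULL) {
  profile <- match.arg(profile)
  def <- if (profile == "paper") {
    list(n_tree = 1000L, n_subtree = 50L, n_rnd = 100L)
  } else {
    list(n_tree = 100L, n_subtree = 20L, n_rnd = 10L)
  }
  p <- list(
    profile = profile,
    n_tree = as.integer(if (is.null(n_tree)) def$n_tree else n_tree),
    n_subtree = as.integer(if (is.null(n_subtree)) def$n_subtree else n_subtree),
    n_test = if (is.null(n_test)) NULL else as.integer(n_test),
    n_hmax = as.integer(n_hmax),
    n_rnd = as.integer(if (is.null(n_rnd)) def$n_rnd else n_rnd)
  )
  if (p$n_tree < 1L || p$n_subtree < 1L || p$n_rnd < 1L || p$n_hmax < 1L)
    sgn_stop("n_tree, n_subtree, n_rnd and n_hmax must all be >= 1")
  if (!is.null(p$n_test) && p$n_test < 1L)
    sgn_stop("n_test must be >= 1")
  structure(p, class = "sgn_params")
}

# resolve n_test for a problem with `p` input columns (= N - 1 for an N-gene
# subproblem, plus any stimulus column)
resolve_n_test <- function(params, p) {
  nt <- params$n_test
  if (is.null(nt)) nt <- as.integer(ceiling(p / 3))
  min(max(1L, nt), p)
}

#' @export
print.sgn_params <- function(x, ...) {
  cat(sprintf(
    "forest parameters (%s profile): n_tree=%d n_subtree=%d n_test=%s n_hmax=%d n_rnd=%d\n",
    x$profile, x$n_tree, x$n_subtree,
    if (is.null(x$n_test)) "ceil((N-1)/3)" else x$n_test, x$n_hmax, x$n_rnd))
  invisible(x)
}

#' Labeling thresholds
#'
#' Constants of the sign-labeling rule. Defaults are the published values:
#' cells in the top/bottom `q_exclude` quantile of a gene are excluded ('X');
#' '+' requires the cell to sit below `band_lo` x smoothed level with slope
#' above `slope_on` x the gene's trajectory mean; '-' mirrors it; '0'
#' requires the cell within `[band_lo, band_hi]` x smoothed level with
#' |slope| below `slope_flat` x mean. Cells with pseudotime above
#' `steady_pt` may be treated as steady state when no separate steady
#' population exists.
#'
#' @param q_exclude tail quantile for exclusion (default 0.05).
#' @param band_lo,band_hi smoothed-level band factors (defaults 0.9, 1.1).
#' @param slope_on slope factor for '+'/'-' (default 1.2).
#' @param slope_flat slope factor for '0' (default 0.6).
#' @param steady_pt pseudotime cutoff for the tail-as-steady-state option.
#' @return a named list of class `sgn_thresholds`.
#' @export
label_thresholds <- function(q_exclude = 0.05, band_lo = 0.9, band_hi = 1.1,
                             slope_on = 1.2, slope_flat = 0.6,
                             steady_pt = 0.85) {
  stopifnot(q_exclude > 0, q_exclude < 0.5, band_lo <= 1, band_hi >= 1,
            slope_on > 0, slope_flat > 0, steady_pt > 0, steady_pt < 1)
  structure(list(q_exclude = q_exclude, band_lo = band_lo, band_hi = band_hi,
                 slope_on = slope_on, slope_flat = slope_flat,
                 steady_pt = steady_pt),
            class = "sgn_thresholds")
}
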