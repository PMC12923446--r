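#' Assign a sign-of-derivative class label to one measurement
#'
#' Applies the labeling rule in its fixed order, per gene and cell:
#' \enumerate{
#'   \item exclusion: `x_val <= q_lo` or `x_val >= q_hi` gives `'X'`;
#'   \item `'+'` when `x_val <= band_lo * sm` and `sl > slope_on * x_avg`;
#'   \item `'-'` when `x_val >= band_hi * sm` and `sl < -slope_on * x_avg`;
#'   \item `'0'` when `band_lo * sm <= x_val <= band_hi * sm` and
#'     `|sl| < slope_flat * x_avg`;
#'   \item otherwise `'X'`.
#' }
#' Boundary equalities resolve exactly as the comparisons above are written.
#' The rule is scale-consistent: rescaling all arguments by a common positive
#' factor leaves the label unchanged. All arguments are vectorised.
#'
#' @param x_val measured expression of the gene in the cell.
#' @param sm smoothed expression level at the cell's pseudotime.
#' @param sl slope of the smoothed level at the cell's pseudotime.
#' @param x_avg the gene's mean expression over the pseudo time-series.
#' @param q_lo,q_hi the gene's exclusion quantiles over the pseudo
#'   time-series (defaults never bind).
#' @param thresholds a [label_thresholds()] object.
#' @return character vector of labels in `c("+", "-", "0", "X")`.
#' @export
assign_label <- function(x_val, sm, sl, x_avg, q_lo = -Inf, q_hi = Inf,
                         thresholds = label_thresholds()) {
  n <- max(length(x_val), length(sm), length(sl), length(x_avg))
  x_val <- rep_len(x_val, n); sm <- rep_len(sm, n); sl <- rep_len(sl, n)
  x_avg <- rep_len(x_avg, n)
  q_lo <- rep_len(q_lo, n); q_hi <- rep_len(q_hi, n)
  if (any(!is.finite(x_val)) || any(!is.finite(sm)) || any(!is.finite(sl)) ||
      any(!is.finite(x_avg)))
    sgn_stop("labeling inputs must be finite", class = "sgn_validation_error")
  if (any(q_lo > q_hi))
    sgn_stop("q_lo must not exceed q_hi", class = "sgn_validation_error")
  th <- thresholds
  lab <- rep("X", n)
  open <- !(x_val <= q_lo | x_val >= q_hi)           # rule 1: exclusion
  plus <- open & x_val <= th$band_lo * sm & sl > th$slope_on * x_avg
  minus <- open & !plus & x_val >= th$band_hi * sm & sl < -th$slope_on * x_avg
  zero <- open & !plus & !minus &
    x_val >= th$band_lo * sm & x_val <= th$band_hi * sm &
    abs(sl) < th$slope_flat * x_avg
  lab[plus] <- "+"
  lab[minus] <- "-"
  lab[zero] <- "0"
  lab
}

#' Decompose a dataset into per-gene labeled subproblems
#'
#' For each target gene `n`, labels every pseudo time-series cell with
#' [assign_label()] on gene `n` and labels every steady-state cell `'0'`,
#' then partitions the examples into the sets `D+`, `D-`, `D0` and `DX`.
#' Example input vectors retain all genes (plus the stimulus column when
#' enabled); the target's own column is dropped only at tree-training time.
#' `DX` is bookkeeping only and is never used in fitting.
#'
#' @param data an [expression_dataset()]; must yield a non-empty `D0` for
#'   every gene (the method cannot run without '0'-labeled examples).
#' @param smoothed optional [smooth_dataset()] result (computed when `NULL`).
#' @param weights optional per-cell nonnegative weights (default all 1); a
#'   hook for downsampling-style example weighting.
#' @param span smoothing span when `smoothed` is `NULL`.
#' @param thresholds a [label_thresholds()] object.
#' @param tail_as_steady if `TRUE`, pseudo-time cells with pseudotime above
#'   `thresholds$steady_pt` are additionally copied into the steady-state
#'   ('0') set -- for datasets without a separate steady-state population.
#' @return a list of `sgn_subproblem` objects, one per gene, each with the
#'   example matrix `X` (cells x inputs), labels `y`, weights `w` and the
#'   partition index list `sets`.
#' @export
build_subproblems <- function(data, smoothed = NULL, weights = NULL,
                              span = 0.3, thresholds = label_thresholds(),
                              tail_as_steady = FALSE) {
  stopifnot(inherits(data, "sgn_dataset"))
  n_cells <- nrow(data$expr)
  if (is.null(weights)) weights <- rep(1, n_cells)
  if (length(weights) != n_cells || any(!is.finite(weights)) ||
      any(weights < 0))
    sgn_stop("weights must be nonnegative, finite, one per cell",
             class = "sgn_validation_error")
  pseudo <- which(!data$is_steady)
  steady <- which(data$is_steady)
  if (length(pseudo) && is.null(smoothed))
    smoothed <- smooth_dataset(data, span = span, thresholds = thresholds)

  tail_cells <- integer(0)
  if (tail_as_steady && length(pseudo))
    tail_cells <- pseudo[data$pseudotime[pseudo] > thresholds$steady_pt]

  Xfull <- input_matrix(data)
  rows <- c(pseudo, steady, tail_cells)
  X <- Xfull[rows, , drop = FALSE]
  w <- weights[rows]
  role <- c(rep("pseudo", length(pseudo)), rep("steady", length(steady)),
            rep("steady", length(tail_cells)))
  cell_ids <- rownames(data$expr)[rows]

  genes <- data$gene_names
  out <- vector("list", length(genes))
  names(out) <- genes
  for (n in seq_along(genes)) {
    y <- rep("0", length(rows))
    if (length(pseudo)) {
      y[seq_along(pseudo)] <- assign_label(
        x_val = data$expr[pseudo, n],
        sm = smoothed$sm[, n], sl = smoothed$sl[, n],
        x_avg = smoothed$x_avg[n],
        q_lo = smoothed$q_lo[n], q_hi = smoothed$q_hi[n],
        thresholds = thresholds)
    }
    sets <- list(plus = which(y == "+"), minus = which(y == "-"),
                 zero = which(y == "0"), excluded = which(y == "X"))
    if (length(sets$zero) == 0L)
      sgn_stop("gene '", genes[n], "' has no '0'-labeled examples; the ",
               "method cannot function without steady-state ('0') data",
               class = "sgn_no_steady_error")
    out[[n]] <- structure(list(target = n, target_name = genes[n],
                               X = X, y = y, w = w, sets = sets,
                               role = role, cell_ids = cell_ids),
                          class = "sgn_subproblem")
  }
  out
}

#' @export
print.sgn_subproblem <- function(x, ...) {
  cat(sprintf("subproblem for gene '%s': |D+|=%d |D-|=%d |D0|=%d |DX|=%d\n",
              x$target_name, length(x$sets$plus), length(x$sets$minus),
              length(x$sets$zero), length(x$sets$excluded)))
  invisible(x)
}

#' Long-format label table
#'
#' @param subproblems result of [build_subproblems()].
#' @return data.frame with columns `cell_id`, `gene`, `label`, `weight`.
#' @export
label_table <- function(subproblems) {
  do.call(rbind, lapply(subproblems, function(s) {
    data.frame(cell_id = s$cell_ids, gene = s$target_name, label = s$y,
               weight = s$w, row.names = NULL)
  }))
}
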