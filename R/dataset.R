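#' Single-cell expression dataset with pseudotime annotations
#'
#' Container for a cells x genes expression matrix where every cell is
#' either a pseudo time-series cell (finite pseudotime in [0, 1]) or a
#' steady-state cell (pseudotime `NA`). An optional stimulus indicator can
#' be appended as an extra input column at training time (1.0 for
#' pseudo-time cells, 0.0 for steady-state cells) to encode an external
#' perturbation shared by the trajectory.
#'
#' @param expr numeric matrix, rows = cells, columns = genes. Row names are
#'   cell ids (generated when absent); column names are gene names.
#' @param pseudotime numeric vector, one entry per cell; `NA` marks a
#'   steady-state cell. Finite values outside [0, 1] are rescaled to [0, 1]
#'   with a warning.
#' @param condition optional per-cell character vector (free-form metadata).
#' @param stimulus logical; if `TRUE`, inference adds the stimulus column.
#' @return an object of class `sgn_dataset`.
#' @export
expression_dataset <- function(expr, pseudotime, condition = NULL,
                               stimulus = FALSE) {
  expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  if (ncol(expr) < 2L)
    sgn_stop("at least 2 genes are required", class = "sgn_validation_error")
  if (anyNA(expr) || any(!is.finite(expr)))
    sgn_stop("expression values must be finite", class = "sgn_validation_error")
  if (any(expr < 0))
    sgn_stop("expression values must be nonnegative",
             class = "sgn_validation_error")
  if (is.null(colnames(expr)))
    colnames(expr) <- paste0("g", seq_len(ncol(expr)))
  if (is.null(rownames(expr)))
    rownames(expr) <- paste0("cell", seq_len(nrow(expr)))
  pseudotime <- as.numeric(pseudotime)
  if (length(pseudotime) != nrow(expr))
    sgn_stop("pseudotime must have one entry per cell",
             class = "sgn_validation_error")
  if (any(!is.na(pseudotime) & !is.finite(pseudotime)))
    sgn_stop("pseudotime values must be finite or NA",
             class = "sgn_validation_error")
  pt <- pseudotime[!is.na(pseudotime)]
  if (length(pt) && (min(pt) < 0 || max(pt) > 1)) {
    warning("pseudotime outside [0, 1]; rescaling to [0, 1]")
    rng <- range(pt)
    if (diff(rng) == 0)
      sgn_stop("cannot rescale constant pseudotime",
               class = "sgn_validation_error")
    pseudotime <- (pseudotime - rng[1]) / diff(rng)
  }
  structure(list(expr = expr,
                 gene_names = colnames(expr),
                 pseudotime = pseudotime,
                 is_steady = is.na(pseudotime),
                 condition = condition,
                 stimulus = isTRUE(stimulus)),
            class = "sgn_dataset")
}

#' @export
print.sgn_dataset <- function(x, ...) {
  cat(sprintf("sgn_dataset: %d cells x %d genes (%d pseudo-time, %d steady-state)%s\n",
              nrow(x$expr), ncol(x$expr), sum(!x$is_steady), sum(x$is_steady),
              if (x$stimulus) ", stimulus column enabled" else ""))
  invisible(x)
}

#' @export
dim.sgn_dataset <- function(x) dim(x$expr)

# Full input matrix used by tree training: expression plus the stimulus
# indicator column (1 pseudo-time, 0 steady) when enabled.
input_matrix <- function(data) {
  X <- data$expr
  if (data$stimulus) {
    X <- cbind(X, stimulus = as.numeric(!data$is_steady))
  }
  X
}

# names of valid regulators (stimulus included) and targets (genes only)
regulator_names <- function(data) colnames(input_matrix(data))
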