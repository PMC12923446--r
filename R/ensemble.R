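#' Uniform bootstrap of a weighted example set
#'
#' Draws `n` indices uniformly with replacement from `1:n`; weights travel
#' with their examples (the caller indexes weights by the returned draw).
#'
#' @param n size of the set being resampled.
#' @return integer vector of length `n` (draw order preserved).
#' @export
boot_indices <- function(n) {
  if (n < 1L) sgn_stop("cannot bootstrap an empty set",
                       class = "sgn_validation_error")
  sample.int(n, n, replace = TRUE)
}

#' Under-sampling cutoffs balancing the '+' and '-' weight masses
#'
#' Given the weights of the bootstrapped '+' and '-' examples in draw
#' order, computes the class weight masses `W+ = sum(w_plus)`,
#' `W- = sum(w_minus)` and the prefix cutoffs: if `W+ >= W-`, `K+` is the
#' smallest prefix of `w_plus` whose sum reaches `W-` and `K- = |D-|`;
#' otherwise symmetrically. With all weights 1 this reduces to
#' `K+ = K- = min(|D+|, |D-|)`. An empty side has mass 0, forcing both
#' cutoffs of the other side's prefix rule to 0.
#'
#' @param w_plus,w_minus nonnegative weight vectors in draw order (may be
#'   empty).
#' @return list with `k_plus`, `k_minus`, `w_mass_plus`, `w_mass_minus`.
#' @export
undersample_counts <- function(w_plus, w_minus) {
  if (any(w_plus < 0) || any(w_minus < 0))
    sgn_stop("weights must be nonnegative", class = "sgn_validation_error")
  wp <- sum(w_plus)
  wm <- sum(w_minus)
  prefix_cut <- function(w, target) {
    # smallest K with sum(w[1:K]) >= target; K = 0 when target <= 0
    if (target <= 0) return(0L)
    cs <- cumsum(w)
    which(cs >= target)[1]
  }
  if (wp >= wm) {
    list(k_plus = prefix_cut(w_plus, wm), k_minus = length(w_minus),
         w_mass_plus = wp, w_mass_minus = wm)
  } else {
    list(k_plus = length(w_plus), k_minus = prefix_cut(w_minus, wp),
         w_mass_plus = wp, w_mass_minus = wm)
  }
}

#' Sign-consistency penalty of one regression tree
#'
#' Weighted hinge sum measuring how often the tree's predicted sign of
#' `G(X_-n) - X_n` contradicts the '+'/'-' labeled examples:
#' `sum_k w_k^+ max(-(G(X_k) - x_k), 0) + sum_k w_k^- max(G(X_k) - x_k, 0)`.
#' A tree whose predictions exceed `x_n` on every '+' example and fall below
#' it on every '-' example scores exactly 0.
#'
#' @param tree an `sgn_tree` predicting the target gene from `X_-n`.
#' @param X_plus,X_minus input matrices (`X_-n`) of the retained '+' / '-'
#'   examples (the first `K+` / `K-` of the bootstrapped sets); may have
#'   zero rows.
#' @param xn_plus,xn_minus the target gene's expression in those examples.
#' @param w_plus,w_minus their weights.
#' @return nonnegative penalty value.
#' @export
tree_penalty <- function(tree, X_plus, xn_plus, w_plus,
                         X_minus, xn_minus, w_minus) {
  pen <- 0
  if (!is.null(X_plus) && nrow(X_plus) > 0) {
    gap <- predict(tree, X_plus) - xn_plus
    pen <- pen + sum(w_plus * pmax(-gap, 0))
  }
  if (!is.null(X_minus) && nrow(X_minus) > 0) {
    gap <- predict(tree, X_minus) - xn_minus
    pen <- pen + sum(w_minus * pmax(gap, 0))
  }
  pen
}

#' Index of the tree with the smallest penalty
#'
#' @param penalties numeric vector of penalties, one per candidate tree.
#' @return index of the minimum; ties broken by the lowest index.
#' @export
select_best_tree <- function(penalties) {
  if (length(penalties) < 1L)
    sgn_stop("no candidate trees", class = "sgn_validation_error")
  which.min(penalties)
}

#' Solve one per-gene subproblem
#'
#' The core iteration, repeated `n_tree` times: bootstrap the '0' set, fit
#' an inner forest of `n_subtree` trees on that identical sample, bootstrap
#' the '+' and '-' sets, balance their weight masses by under-sampling, score
#' every candidate tree with [tree_penalty()] over the retained prefixes, and
#' keep the tree with the smallest penalty (ties to the lowest index). When
#' both `D+` and `D-` are empty every penalty vanishes, the first tree of
#' each inner forest is kept, and the run is exactly a bagged weighted
#' GENIE3 forest.
#'
#' @param sub an `sgn_subproblem` from [build_subproblems()].
#' @param params a [forest_params()] object.
#' @param keep_penalties if `TRUE`, store the full penalty matrix
#'   (`n_tree` x `n_subtree`) for inspection.
#' @param genie3_only if `TRUE`, ignore the '+'/'-' sets (the modified
#'   GENIE3 baseline on '0'-labeled cells).
#' @return an `sgn_subresult`: the selected trees, their bagging samples,
#'   per-iteration selected penalties, and the data needed for confidence
#'   computation.
#' @export
infer_subproblem <- function(sub, params = forest_params(),
                             keep_penalties = FALSE, genie3_only = FALSE) {
  stopifnot(inherits(sub, "sgn_subproblem"))
  zero <- sub$sets$zero
  if (length(zero) == 0L)
    sgn_stop("the method cannot function without gene expression data ",
             "labeled '0'", class = "sgn_no_steady_error")
  plus <- sub$sets$plus
  minus <- sub$sets$minus
  if (genie3_only) plus <- minus <- integer(0)
  use_signs <- length(plus) > 0L || length(minus) > 0L

  target <- sub$target
  input_cols <- setdiff(seq_len(ncol(sub$X)), target)
  X0 <- sub$X[zero, , drop = FALSE]
  Xi0 <- X0[, input_cols, drop = FALSE]
  y0 <- X0[, target]
  w0 <- sub$w[zero]
  Xp <- sub$X[plus, input_cols, drop = FALSE]
  xp <- sub$X[plus, target]
  wp <- sub$w[plus]
  Xm <- sub$X[minus, input_cols, drop = FALSE]
  xm <- sub$X[minus, target]
  wm <- sub$w[minus]
  n_test <- resolve_n_test(params, length(input_cols))

  n_fit <- if (use_signs) params$n_subtree else 1L
  trees <- vector("list", params$n_tree)
  boot_idx <- vector("list", params$n_tree)
  sel_penalty <- numeric(params$n_tree)
  pen_mat <- if (keep_penalties)
    matrix(NA_real_, params$n_tree, params$n_subtree) else NULL

  for (iter in seq_len(params$n_tree)) {
    b0 <- boot_indices(length(zero))                       # Step 2
    forest <- cpp_fit_forest(Xi0[b0, , drop = FALSE],      # Step 3
                             y0[b0], w0[b0], n_fit, n_test, params$n_hmax)
    if (use_signs) {                                       # Steps 4-5
      bp <- if (length(plus)) boot_indices(length(plus)) else integer(0)
      bm <- if (length(minus)) boot_indices(length(minus)) else integer(0)
      cuts <- undersample_counts(wp[bp], wm[bm])
      kp <- seq_len(cuts$k_plus)
      km <- seq_len(cuts$k_minus)
      Xps <- Xp[bp[kp], , drop = FALSE]; xps <- xp[bp[kp]]; wps <- wp[bp[kp]]
      Xms <- Xm[bm[km], , drop = FALSE]; xms <- xm[bm[km]]; wms <- wm[bm[km]]
      pens <- vapply(forest, function(tr) {
        tree_penalty(structure(tr, n_features = length(input_cols),
                               class = "sgn_tree"),
                     Xps, xps, wps, Xms, xms, wms)
      }, numeric(1))
      best <- select_best_tree(pens)
      sel_penalty[iter] <- pens[best]
      if (keep_penalties) pen_mat[iter, ] <- pens
    } else {
      best <- 1L
      sel_penalty[iter] <- 0
    }
    trees[[iter]] <- structure(forest[[best]],
                               n_features = length(input_cols),
                               feature_names = colnames(Xi0),
                               class = "sgn_tree")
    boot_idx[[iter]] <- b0
  }

  structure(list(target = target, target_name = sub$target_name,
                 trees = trees, boot_idx = boot_idx,
                 selected_penalty = sel_penalty, penalties = pen_mat,
                 X0 = Xi0, y0 = y0, w0 = w0,
                 input_cols = input_cols, input_names = colnames(Xi0)),
            class = "sgn_subresult")
}

#' @export
print.sgn_subresult <- function(x, ...) {
  cat(sprintf("sgn_subresult for '%s': %d selected trees over %d inputs\n",
              x$target_name, length(x$trees), length(x$input_cols)))
  invisible(x)
}

#' Confidence values for the regulators of one target gene
#'
#' Runs [random_input_importance()] `n_rnd` times over the selected
#' ensemble -- each tree evaluated on its own Step-2 bagging sample -- and
#' averages element-wise. The target gene itself is not among the returned
#' features (self-regulation has no confidence).
#'
#' @param result an `sgn_subresult` from [infer_subproblem()].
#' @param params a [forest_params()] object (supplies `n_rnd`).
#' @return named numeric vector of confidences, one per candidate regulator.
#' @export
compute_confidences <- function(result, params = forest_params()) {
  stopifnot(inherits(result, "sgn_subresult"))
  score <- random_input_importance(result$trees, result$X0, result$y0,
                                   result$w0, n_rnd = params$n_rnd,
                                   idx = result$boot_idx)
  setNames(score, result$input_names)
}

#' Infer a ranked regulatory network
#'
#' Decomposes the inference problem into one subproblem per gene, solves
#' each with [infer_subproblem()] and [compute_confidences()], and collects
#' all regulator-target confidences into one descending-ranked directed edge
#' list. Subproblems are statistically independent: each consumes its own
#' RNG stream derived from `seed`, so results do not depend on execution
#' order. The stimulus column (when enabled) can act only as a regulator,
#' never as a target; self-edges are excluded by construction.
#'
#' @param data an [expression_dataset()].
#' @param params a [forest_params()] object.
#' @param weights optional per-cell weights (default all 1).
#' @param span smoothing span for the labeling step.
#' @param thresholds a [label_thresholds()] object.
#' @param seed integer seed governing all randomness (per-gene streams are
#'   derived from it); `NULL` uses the current RNG state.
#' @param tail_as_steady see [build_subproblems()].
#' @param genie3_only if `TRUE`, run the modified GENIE3 baseline ('0' cells
#'   only, weighted trees, random-input importance) instead of the
#'   sign-constrained method.
#' @return an `sgn_network`: data.frame with columns `regulator`, `target`,
#'   `confidence`, `rank`, sorted by decreasing confidence.
#' @export
infer_network <- function(data, params = forest_params(), weights = NULL,
                          span = 0.3, thresholds = label_thresholds(),
                          seed = NULL, tail_as_steady = FALSE,
                          genie3_only = FALSE) {
  subs <- build_subproblems(data, weights = weights, span = span,
                            thresholds = thresholds,
                            tail_as_steady = tail_as_steady)
  edges <- vector("list", length(subs))
  for (n in seq_along(subs)) {
    if (!is.null(seed)) set.seed(subproblem_seed(seed, n))
    res <- infer_subproblem(subs[[n]], params, genie3_only = genie3_only)
    conf <- compute_confidences(res, params)
    edges[[n]] <- data.frame(regulator = names(conf),
                             target = subs[[n]]$target_name,
                             confidence = as.numeric(conf),
                             row.names = NULL)
  }
  out <- do.call(rbind, edges)
  out <- out[order(-out$confidence, out$regulator, out$target), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("sgn_network", "data.frame")
  out
}

#' Modified GENIE3 baseline on '0'-labeled cells
#'
#' GENIE3 with the two modifications retained: example weights inside the
#' trees and the random-input (permutation) variable importance. Equivalent
#' to [infer_network()] when the '+' and '-' sets are empty: each iteration
#' bootstraps the '0' set and keeps a single tree, i.e. a bagged forest of
#' `n_tree` trees.
#'
#' @inheritParams infer_network
#' @return an `sgn_network` edge list.
#' @export
modified_genie3 <- function(data, params = forest_params(), weights = NULL,
                            span = 0.3, thresholds = label_thresholds(),
                            seed = NULL, tail_as_steady = FALSE) {
  infer_network(data, params, weights = weights, span = span,
                thresholds = thresholds, seed = seed,
                tail_as_steady = tail_as_steady, genie3_only = TRUE)
}

# deterministic per-subproblem stream, kept below 2^31
subproblem_seed <- function(seed, n) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(n) %% 1000L
}
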