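#' Fit one weighted regression tree
#'
#' CART-style binary regression tree with example weights. At every node
#' `n_test` input columns are sampled without replacement (from R's RNG, so
#' `set.seed()` makes fitting reproducible), candidate thresholds are the
#' midpoints between consecutive distinct sorted values, and the split
#' maximising the weighted variance reduction is kept. Growth stops at
#' `max_height`, at pure nodes, or when no sampled feature admits a split.
#' Leaf predictions are weighted means of the routed training outputs.
#'
#' @param X numeric input matrix (examples x features).
#' @param y numeric output vector.
#' @param w nonnegative example weights with positive sum (default all 1).
#' @param n_test features examined per node (default all).
#' @param max_height maximum tree height, root = 1.
#' @return an object of class `sgn_tree` (parallel node arrays: `feature`,
#'   `threshold`, `left`, `right`, `value`, `reduction`, `node_w`).
#' @export
fit_tree <- function(X, y, w = NULL, n_test = ncol(X), max_height = 32L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(w)) w <- rep(1, nrow(X))
  if (nrow(X) < 1L)
    sgn_stop("at least one example is required", class = "sgn_validation_error")
  if (length(y) != nrow(X) || length(w) != nrow(X))
    sgn_stop("X, y and w must agree in length", class = "sgn_validation_error")
  if (any(!is.finite(X)) || any(!is.finite(y)) || any(!is.finite(w)))
    sgn_stop("non-finite values in training data",
             class = "sgn_validation_error")
  if (any(w < 0) || sum(w) <= 0)
    sgn_stop("weights must be nonnegative with positive sum",
             class = "sgn_validation_error")
  n_test <- min(max(1L, as.integer(n_test)), ncol(X))
  tr <- cpp_fit_tree(X, as.numeric(y), as.numeric(w), n_test,
                     as.integer(max_height))
  structure(tr, n_features = ncol(X), feature_names = colnames(X),
            class = "sgn_tree")
}

#' @export
predict.sgn_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != attr(object, "n_features"))
    sgn_stop("newdata has ", ncol(newdata), " columns, tree expects ",
             attr(object, "n_features"), class = "sgn_validation_error")
  cpp_predict_tree(unclass(object), newdata)
}

#' @export
print.sgn_tree <- function(x, ...) {
  cat(sprintf("sgn_tree: %d nodes (%d leaves), %d features\n",
              length(x$feature), sum(is.na(x$feature)),
              attr(x, "n_features")))
  invisible(x)
}

#' Fit one inner GENIE3 forest for a target gene
#'
#' Trains `n_subtree` regression trees that all share the identical example
#' multiset (the caller's bagging sample) -- unlike classical random forests
#' there is no per-tree resampling here; trees differ only through per-node
#' random feature selection. Inputs are all columns except the target gene
#' (the stimulus column, when present, stays in); outputs are the target
#' gene's expression.
#'
#' @param X example matrix including the target column (examples x inputs).
#' @param target_gene column index of the target gene in `X`.
#' @param w example weights.
#' @param params a [forest_params()] object.
#' @return list of `n_subtree` [fit_tree()] trees; attribute `input_cols`
#'   records which columns of `X` were used as inputs.
#' @export
fit_genie3_forest <- function(X, target_gene, w = NULL, params = forest_params()) {
  X <- as.matrix(X)
  if (nrow(X) < 1L)
    sgn_stop("empty training sample", class = "sgn_validation_error")
  if (is.null(w)) w <- rep(1, nrow(X))
  input_cols <- setdiff(seq_len(ncol(X)), target_gene)
  Xi <- X[, input_cols, drop = FALSE]
  storage.mode(Xi) <- "double"
  y <- as.numeric(X[, target_gene])
  n_test <- resolve_n_test(params, ncol(Xi))
  trees <- cpp_fit_forest(Xi, y, as.numeric(w), params$n_subtree, n_test,
                          params$n_hmax)
  trees <- lapply(trees, function(t)
    structure(t, n_features = ncol(Xi), feature_names = colnames(Xi),
              class = "sgn_tree"))
  attr(trees, "input_cols") <- input_cols
  trees
}

#' Variance-reduction variable importance
#'
#' The classical random-forest importance: for each feature, the sum over
#' all splits on that feature of (weighted variance reduction x weighted
#' node size), averaged over trees. This is the importance the original
#' GENIE3 ranks regulators with; the sign-constrained pipeline uses
#' [random_input_importance()] instead.
#'
#' @param trees list of `sgn_tree` objects over a common feature space.
#' @param n_features number of features (default from the first tree).
#' @return numeric vector of nonnegative per-feature scores.
#' @export
variance_importance <- function(trees,
                                n_features = attr(trees[[1]], "n_features")) {
  score <- numeric(n_features)
  for (tr in trees) {
    internal <- !is.na(tr$feature)
    if (!any(internal)) next
    contrib <- tr$reduction[internal] * tr$node_w[internal]
    f <- tr$feature[internal]
    for (i in seq_along(f)) score[f[i]] <- score[f[i]] + contrib[i]
  }
  score / length(trees)
}

#' Permutation (random-input) variable importance
#'
#' For each feature, the increase in weighted mean squared prediction error
#' when that input column is randomly permuted over the evaluation examples,
#' relative to the unpermuted baseline, averaged over trees (and over
#' `n_rnd` independent permutation draws). A feature no tree ever splits on
#' scores exactly 0; negative averages are kept as computed.
#'
#' @param trees list of `sgn_tree` objects.
#' @param X evaluation input matrix (examples x features).
#' @param y evaluation outputs.
#' @param w evaluation weights (default all 1).
#' @param n_rnd number of permutation repetitions averaged over.
#' @param idx optional list (one integer vector per tree) of row indices of
#'   `X` forming each tree's own evaluation set; default: all rows for
#'   every tree.
#' @return numeric per-feature score vector.
#' @export
random_input_importance <- function(trees, X, y, w = NULL, n_rnd = 1L,
                                    idx = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) < 1L)
    sgn_stop("empty evaluation data", class = "sgn_validation_error")
  if (is.null(w)) w <- rep(1, nrow(X))
  if (is.null(idx)) idx <- rep(list(seq_len(nrow(X))), length(trees))
  stopifnot(length(idx) == length(trees))
  cpp_perm_importance(lapply(trees, unclass), X, as.numeric(y),
                      as.numeric(w), lapply(idx, as.integer),
                      as.integer(n_rnd))
}

#' Serialize a tree ensemble to JSON
#'
#' Writes the node arrays of every tree (feature index, threshold, children,
#' leaf/node value, split variance reduction, node weight) plus the feature
#' names, for inspection and for test fixtures.
#'
#' @param trees list of `sgn_tree` objects.
#' @param path output file path.
#' @export
write_ensemble_json <- function(trees, path) {
  payload <- list(
    version = .sgn_version(),
    n_features = attr(trees[[1]], "n_features"),
    feature_names = attr(trees[[1]], "feature_names"),
    trees = lapply(trees, function(t) unclass(t)[c(
      "feature", "threshold", "left", "right", "value", "reduction",
      "node_w")])
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a tree ensemble written by [write_ensemble_json()]
#' @param path JSON file path.
#' @return list of `sgn_tree` objects.
#' @export
read_ensemble_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(length(payload$trees$feature)), function(i) {
    structure(list(feature = as.integer(payload$trees$feature[[i]]),
                   threshold = as.numeric(payload$trees$threshold[[i]]),
                   left = as.integer(payload$trees$left[[i]]),
                   right = as.integer(payload$trees$right[[i]]),
                   value = as.numeric(payload$trees$value[[i]]),
                   reduction = as.numeric(payload$trees$reduction[[i]]),
                   node_w = as.numeric(payload$trees$node_w[[i]])),
              n_features = payload$n_features,
              feature_names = payload$feature_names,
              class = "sgn_tree")
  })
}
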