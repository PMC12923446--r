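#' Gold-standard edge set
#'
#' @param edges data.frame (or 2-column matrix) with columns `regulator`
#'   and `target`; self-edges are rejected (auto-regulation is excluded
#'   from evaluation).
#' @param genes optional gene universe (default: genes seen in `edges`).
#' @return an `sgn_gold` data.frame with attribute `genes`.
#' @export
gold_standard <- function(edges, genes = NULL) {
  edges <- as.data.frame(edges)
  names(edges)[1:2] <- c("regulator", "target")
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  if (any(edges$regulator == edges$target))
    sgn_stop("gold standard must not contain self-edges",
             class = "sgn_validation_error")
  if (anyDuplicated(paste(edges$regulator, edges$target, sep = "\r")))
    sgn_stop("duplicate edges in gold standard",
             class = "sgn_validation_error")
  if (is.null(genes)) genes <- sort(unique(c(edges$regulator, edges$target)))
  structure(edges[, c("regulator", "target")], genes = genes,
            class = c("sgn_gold", "data.frame"))
}

edge_key <- function(a, b, directed = TRUE) {
  if (directed) return(paste(a, b, sep = "\r"))
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Precision-recall curve of a ranked network
#'
#' Sweeps the confidence threshold over the distinct confidence values of
#' the ranked edge list (descending; tied confidences enter as one group)
#' and reports `recall = TP / (TP + FN)` and `precision = TP / (TP + FP)`
#' at each threshold. In undirected mode an edge is a true positive when
#' its unordered gene pair is in the reference, and recall is counted over
#' reference pairs.
#'
#' @param ranked an `sgn_network` (or data.frame with `regulator`, `target`,
#'   `confidence`).
#' @param gold an [gold_standard()] object with at least one positive.
#' @param directed match edge direction (default `TRUE`).
#' @return data.frame with columns `threshold`, `tp`, `fp`, `fn`, `recall`,
#'   `precision`, ordered by decreasing threshold.
#' @export
pr_curve <- function(ranked, gold, directed = TRUE) {
  ranked <- as.data.frame(ranked)
  if (nrow(gold) == 0L)
    sgn_stop("gold standard has zero positives",
             class = "sgn_validation_error")
  pos_keys <- unique(edge_key(gold$regulator, gold$target, directed))
  npos <- length(pos_keys)
  keys <- edge_key(ranked$regulator, ranked$target, directed)
  is_pos <- keys %in% pos_keys
  ord <- order(-ranked$confidence)
  conf <- ranked$confidence[ord]
  is_pos <- is_pos[ord]
  keys <- keys[ord]

  thresholds <- unique(conf)
  out <- data.frame(threshold = thresholds, tp = NA_real_, fp = NA_real_,
                    fn = NA_real_, recall = NA_real_, precision = NA_real_)
  for (i in seq_along(thresholds)) {
    sel <- conf >= thresholds[i]
    n_sel <- sum(sel)
    if (directed) {
      tp <- sum(is_pos[sel])
      fn <- npos - tp
    } else {
      tp <- sum(is_pos[sel])                     # supported selections
      fn <- npos - length(unique(keys[sel][is_pos[sel]]))  # uncovered pairs
    }
    fp <- n_sel - tp
    out$tp[i] <- tp
    out$fp[i] <- fp
    out$fn[i] <- fn
    out$recall[i] <- tp / (tp + fn)
    out$precision[i] <- tp / (tp + fp)
  }
  out
}

#' Area under the precision-recall curve
#'
#' Trapezoidal integration of precision over recall, anchored at recall 0
#' with the first (highest-threshold) point's precision. Documented so that
#' numbers are comparable across implementations: no interpolation beyond
#' the trapezoids, no end-point extrapolation past the final recall.
#'
#' @param curve output of [pr_curve()].
#' @return area in [0, 1].
#' @export
auprc <- function(curve) {
  if (nrow(curve) < 1L)
    sgn_stop("empty precision-recall curve", class = "sgn_validation_error")
  r <- c(0, curve$recall)
  p <- c(curve$precision[1], curve$precision)
  sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
}

#' Number of candidate regulations
#'
#' For a problem with `N` elements of which one is the external stimulus
#' (and targets of the stimulus are counted while self-regulations and
#' regulations *of* the stimulus are not): `N * (N - 1) - (N - 1)`, i.e.
#' `(N - 1)^2`.
#'
#' @param N element count including the stimulus.
#' @return integer candidate count.
#' @export
candidate_count <- function(N) {
  if (!is.finite(N) || N < 2)
    sgn_stop("N must be at least 2", class = "sgn_validation_error")
  as.integer(round(N * (N - 1) - (N - 1)))
}

#' Expected overlap of a random top-k selection with a reference set
#'
#' Mean of the hypergeometric count: drawing `k` of `M` candidates at
#' random, of which `m` are in the reference, matches `k * m / M` on
#' average.
#'
#' @param k selection size (0 < k <= M).
#' @param m reference edges among the candidates (0 <= m <= M).
#' @param M candidate count.
#' @return expected number of matches.
#' @export
expected_overlap <- function(k, m, M) {
  if (!(M > 0) || m < 0 || m > M || k <= 0 || k > M)
    sgn_stop("require 0 <= m <= M and 0 < k <= M",
             class = "sgn_validation_error")
  k * m / M
}

#' Overlap of the top-k ranked edges with a reference
#'
#' @param ranked an `sgn_network`.
#' @param gold a [gold_standard()] (or STRING-style undirected reference
#'   with `directed = FALSE`).
#' @param k number of top edges to take (default 20).
#' @param directed match direction (default `TRUE`).
#' @return number of top-`k` edges present in the reference.
#' @export
top_overlap <- function(ranked, gold, k = 20L, directed = TRUE) {
  ranked <- as.data.frame(ranked)
  ord <- order(-ranked$confidence)
  top <- ranked[ord[seq_len(min(k, nrow(ranked)))], ]
  pos <- unique(edge_key(gold$regulator, gold$target, directed))
  sum(edge_key(top$regulator, top$target, directed) %in% pos)
}

#' Evaluate a ranked network against a gold standard
#'
#' @inheritParams pr_curve
#' @param k top-list size for the overlap count.
#' @return list with `auprc`, `prevalence` (positives / candidates scored),
#'   `n_candidates`, `top_k`, `top_overlap` and the full `curve`.
#' @export
evaluate_network <- function(ranked, gold, directed = TRUE, k = 20L) {
  curve <- pr_curve(ranked, gold, directed = directed)
  npos <- nrow(unique(as.data.frame(gold)[, c("regulator", "target")]))
  list(auprc = auprc(curve),
       prevalence = npos / nrow(as.data.frame(ranked)),
       n_candidates = nrow(as.data.frame(ranked)),
       top_k = as.integer(k),
       top_overlap = top_overlap(ranked, gold, k = k, directed = directed),
       curve = curve)
}
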