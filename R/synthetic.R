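#' Random sparse signed regulatory network with Hill kinetics
#'
#' Draws a gold-standard digraph plus the kinetic parameters needed to
#' simulate it: each gene obeys
#' `dX_n/dt = F_n(X_-n) - beta_n * X_n` where `F_n` is a basal rate plus a
#' sum of Hill terms over the gene's regulators -- `alpha * x^h / (K^h + x^h)`
#' for activation and `alpha * (1 - x^h / (K^h + x^h))` for repression.
#' The edge count is `round(density * (N - 1)^2)` (the candidate count of an
#' `N`-element problem with one stimulus slot); construction first gives
#' every gene one regulator, then fills the remainder uniformly, so
#' in-degree >= 1 is guaranteed. Parameter ranges (drawn once per network):
#' `alpha ~ U(0.8, 1.6)`, `K ~ U(0.3, 1.0)`, `h = 2`,
#' `basal ~ U(0.05, 0.15)`, `beta ~ U(0.8, 1.5)` -- expression scales of
#' order 1 and relaxation times of order 1 time unit.
#'
#' @param n_genes number of genes (>= 3).
#' @param density edge density in (0, 1] relative to `(N - 1)^2`.
#' @param p_activate probability an edge is activating (default 0.7).
#' @param seed optional seed for reproducibility.
#' @return an `sgn_net`: list with `n`, `gene_names`, `edges` (data.frame
#'   `from`, `to`, `sign`, `alpha`, `K`, `hill`), `basal`, `beta`.
#' @export
make_network <- function(n_genes, density, p_activate = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_genes < 3L)
    sgn_stop("need at least 3 genes", class = "sgn_validation_error")
  if (density <= 0 || density > 1)
    sgn_stop("density must be in (0, 1]", class = "sgn_validation_error")
  n_edges <- round(density * (n_genes - 1)^2)
  if (n_edges < 1)
    sgn_stop("density yields zero edges", class = "sgn_validation_error")
  if (n_edges < n_genes)
    sgn_stop("density too low to give every gene a regulator (need >= ",
             n_genes, " edges, got ", n_edges, ")",
             class = "sgn_validation_error")
  max_edges <- n_genes * (n_genes - 1L)
  if (n_edges > max_edges)
    sgn_stop("density yields more edges than the ", max_edges,
             " available ordered pairs", class = "sgn_validation_error")

  # one regulator per gene, then fill uniformly among remaining pairs
  from <- vapply(seq_len(n_genes), function(g)
    sample(setdiff(seq_len(n_genes), g), 1L), integer(1))
  to <- seq_len(n_genes)
  all_pairs <- expand.grid(from = seq_len(n_genes), to = seq_len(n_genes))
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  used <- paste(from, to)
  avail <- which(!(paste(all_pairs$from, all_pairs$to) %in% used))
  extra <- sample(avail, n_edges - n_genes)
  from <- c(from, all_pairs$from[extra])
  to <- c(to, all_pairs$to[extra])

  m <- length(from)
  edges <- data.frame(
    from = from, to = to,
    sign = ifelse(runif(m) < p_activate, 1L, -1L),
    alpha = runif(m, 0.8, 1.6),
    K = runif(m, 0.3, 1.0),
    hill = rep(2, m))
  structure(list(n = as.integer(n_genes),
                 gene_names = paste0("g", seq_len(n_genes)),
                 edges = edges,
                 basal = runif(n_genes, 0.05, 0.15),
                 beta = runif(n_genes, 0.8, 1.5)),
            class = "sgn_net")
}

#' @export
print.sgn_net <- function(x, ...) {
  cat(sprintf("sgn_net: %d genes, %d edges (%d activating)\n", x$n,
              nrow(x$edges), sum(x$edges$sign > 0)))
  invisible(x)
}

#' Gold-standard edge list of a synthetic network
#' @param net an `sgn_net`.
#' @return an [gold_standard()] object.
#' @export
network_gold <- function(net) {
  gold_standard(data.frame(regulator = net$gene_names[net$edges$from],
                           target = net$gene_names[net$edges$to]),
                genes = net$gene_names)
}

# regulation input F(X) for a matrix of states (cells x genes)
regulation_input <- function(net, X) {
  F <- matrix(rep(net$basal, each = nrow(X)), nrow(X), net$n)
  e <- net$edges
  for (i in seq_len(nrow(e))) {
    x <- X[, e$from[i]]
    h <- x^e$hill[i] / (e$K[i]^e$hill[i] + x^e$hill[i])
    h[x == 0] <- 0
    term <- if (e$sign[i] > 0) h else 1 - h
    F[, e$to[i]] <- F[, e$to[i]] + e$alpha[i] * term
  }
  F
}

#' Deterministic drift of the network dynamics
#' @param net an `sgn_net`.
#' @param X state matrix (cells x genes) or vector.
#' @return matrix of `dX/dt = F(X) - beta * X`, same shape as `X`.
#' @export
network_drift <- function(net, X) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, 1L)
  D <- regulation_input(net, X) - sweep(X, 2L, net$beta, `*`)
  if (vec) D[1L, ] else D
}

#' Simulate single-cell snapshots along a noisy trajectory
#'
#' Integrates `dX = [F(X) - beta X] dt + noise_sd dW` (Euler-Maruyama,
#' reflected at 0) for `n_pseudo` cells started from a common initial state
#' (default: all genes silent, `X = 0`, emulating induction of the network).
#' Each cell contributes one snapshot at a uniformly drawn time in
#' `(0, t_max]`; its pseudotime is the true snapshot time scaled to [0, 1],
#' optionally warped by the strictly monotone map `pt = (t / t_max)^gamma`.
#' The default initial state is a perturbed one -- each gene displaced
#' uniformly between 0 and its maximal attainable level `F_max / beta`
#' (drawn once per run) -- emulating an acutely perturbed population (drug
#' treatment, stimulus switch) relaxing back to equilibrium; relaxation of
#' such a state mixes dynamical modes, so individual genes genuinely rise,
#' fall, or rise-then-fall along the trajectory.
#' The steady-state cohort is drawn by first relaxing the noiseless system
#' to its fixed point (drift residual below `steady_tol`, else an error
#' naming the unstable draw) and then letting each steady cell diffuse
#' around that point for `t_burn` time units.
#'
#' @param net an `sgn_net` from [make_network()].
#' @param n_pseudo number of trajectory cells.
#' @param n_steady number of steady-state cells.
#' @param noise_sd diffusion coefficient of the SDE (also scales the small
#'   initial-state jitter); 0 gives deterministic dynamics.
#' @param dt integration step (time units).
#' @param t_max trajectory duration.
#' @param warp_gamma pseudotime warp exponent (1 = identity).
#' @param init initial state vector (default: the random perturbed state
#'   described above; see also [naive_state()]).
#' @param seed optional seed.
#' @param t_settle maximum relaxation time for the steady-state anchor.
#' @param t_burn diffusion time for steady-state cells around the anchor.
#' @param steady_tol tolerance for the anchor's drift residual.
#' @param x_cap divergence guard: any `|X|` above this aborts.
#' @return an `sgn_sim`: list with the assembled `dataset`
#'   ([expression_dataset()]), `true_time`, `ref_path` (noiseless reference
#'   trajectory), `ref_dxdt` (reference drift at each pseudo cell's
#'   snapshot time, for label-sign ground truth), `cell_drift`,
#'   `steady_anchor`, `steady_residual` and `net`.
#' @export
simulate_cells <- function(net, n_pseudo, n_steady, noise_sd = 0.2,
                           dt = 0.01, t_max = 6, warp_gamma = 1,
                           init = NULL, seed = NULL, t_settle = 40,
                           t_burn = 5, steady_tol = 1e-3, x_cap = 1e6) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(net, "sgn_net"), n_pseudo >= 0, n_steady >= 0, dt > 0)
  if (n_pseudo + n_steady < 1L)
    sgn_stop("need at least one cell", class = "sgn_validation_error")
  N <- net$n
  if (is.null(init)) init <- perturbed_state(net)
  init <- rep_len(as.numeric(init), N)

  clamp0 <- function(X) {        # pmax() would drop the dim attribute
    X[X < 0] <- 0
    X
  }
  check_cap <- function(X) {
    if (any(!is.finite(X)) || max(abs(X)) > x_cap)
      sgn_stop("trajectory diverged (|X| > ", x_cap,
               "): unstable kinetic parameter draw",
               class = "sgn_divergence_error")
  }

  n_steps <- max(1L, as.integer(round(t_max / dt)))

  # noiseless reference path and its drift, for ground-truth derivative signs
  ref_path <- matrix(NA_real_, n_steps + 1L, N)
  ref_drift <- matrix(NA_real_, n_steps + 1L, N)
  x <- init
  ref_path[1L, ] <- x
  ref_drift[1L, ] <- network_drift(net, x)
  for (k in seq_len(n_steps)) {
    x <- clamp0(x + network_drift(net, x) * dt)
    ref_path[k + 1L, ] <- x
    ref_drift[k + 1L, ] <- network_drift(net, x)
    check_cap(x)
  }

  # relax the reference on to the fixed point for the steady-state anchor
  anchor <- x
  extra <- as.integer(round(max(0, t_settle - t_max) / dt))
  for (k in seq_len(extra)) {
    anchor <- clamp0(anchor + network_drift(net, anchor) * dt)
    if (k %% 100L == 0L &&
        max(abs(network_drift(net, anchor))) < steady_tol) break
  }
  check_cap(anchor)
  steady_residual <- max(abs(network_drift(net, anchor)))
  if (steady_residual >= steady_tol)
    sgn_stop("network failed to reach steady state (residual ",
             signif(steady_residual, 3), " after t = ", t_settle,
             "): unstable kinetic parameter draw",
             class = "sgn_divergence_error")

  # pseudo-time cohort: one snapshot per cell at a uniform step
  expr_p <- matrix(NA_real_, n_pseudo, N)
  drift_p <- matrix(NA_real_, n_pseudo, N)
  ref_dxdt <- matrix(NA_real_, n_pseudo, N)
  snap_step <- integer(0)
  if (n_pseudo > 0) {
    snap_step <- sample.int(n_steps, n_pseudo, replace = TRUE)
    X <- matrix(rep(init, each = n_pseudo), n_pseudo, N)
    if (noise_sd > 0)
      X <- clamp0(X + matrix(rnorm(n_pseudo * N, 0, noise_sd * 0.25),
                             n_pseudo, N))
    sq <- noise_sd * sqrt(dt)
    for (k in seq_len(n_steps)) {
      D <- network_drift(net, X)
      X <- X + D * dt
      if (noise_sd > 0)
        X <- X + matrix(rnorm(n_pseudo * N, 0, sq), n_pseudo, N)
      X <- clamp0(X)
      check_cap(X)
      hit <- which(snap_step == k)
      if (length(hit)) {
        expr_p[hit, ] <- X[hit, , drop = FALSE]
        drift_p[hit, ] <- network_drift(net, X[hit, , drop = FALSE])
        ref_dxdt[hit, ] <- matrix(rep(ref_drift[k + 1L, ], each = length(hit)),
                                  length(hit), N)
      }
    }
  }
  true_time <- snap_step * dt
  pt <- if (n_pseudo > 0) (true_time / t_max)^warp_gamma else numeric(0)

  # steady-state cohort: diffusion around the anchor
  expr_s <- matrix(rep(anchor, each = n_steady), n_steady, N)
  if (n_steady > 0 && noise_sd > 0) {
    burn <- as.integer(round(t_burn / dt))
    sq <- noise_sd * sqrt(dt)
    for (k in seq_len(burn)) {
      expr_s <- clamp0(expr_s + network_drift(net, expr_s) * dt +
                         matrix(rnorm(n_steady * N, 0, sq), n_steady, N))
      check_cap(expr_s)
    }
  }

  expr <- rbind(expr_p, expr_s)
  colnames(expr) <- net$gene_names
  rownames(expr) <- c(sprintf("pt_cell%03d", seq_len(n_pseudo)),
                      sprintf("ss_cell%03d", seq_len(n_steady)))
  dataset <- expression_dataset(expr, c(pt, rep(NA_real_, n_steady)))

  structure(list(dataset = dataset, true_time = true_time,
                 ref_path = ref_path, ref_dxdt = ref_dxdt,
                 cell_drift = drift_p, steady_anchor = anchor,
                 steady_residual = steady_residual, noise_sd = noise_sd,
                 dt = dt, t_max = t_max, warp_gamma = warp_gamma, net = net),
            class = "sgn_sim")
}

#' Naive (pre-induction) state of a network
#'
#' The fixed point of each gene with all its regulators silent:
#' `F_n(0) / beta_n`, i.e. `(basal + sum of repressive alphas) / beta`.
#' Activated genes start low and switch on along the trajectory; repressed
#' genes start at their unrepressed level and are pushed down -- giving the
#' trajectory both rising and falling genes, as in real induction or
#' differentiation time courses.
#'
#' @param net an `sgn_net`.
#' @return numeric state vector.
#' @export
naive_state <- function(net) {
  as.numeric(regulation_input(net, matrix(0, 1L, net$n))) / net$beta
}

#' Random strongly perturbed state of a network
#'
#' Each gene drawn uniformly between 0 and its maximal attainable level
#' `F_max / beta = (basal + sum of alphas) / beta`. Uses the current RNG
#' stream.
#'
#' @param net an `sgn_net`.
#' @return numeric state vector.
#' @export
perturbed_state <- function(net) {
  fmax <- net$basal
  for (i in seq_len(nrow(net$edges))) {
    to <- net$edges$to[i]
    fmax[to] <- fmax[to] + net$edges$alpha[i]
  }
  runif(net$n, 0, fmax / net$beta)
}

#' Hand-built three-gene activation cascade
#'
#' `g1 -> g2 -> g3`, all activating, with `g1` driven by a strong basal
#' rate so the network switches on in sequence when started silent.
#' @return an `sgn_net`.
#' @export
cascade_network <- function() {
  structure(list(
    n = 3L, gene_names = c("g1", "g2", "g3"),
    edges = data.frame(from = c(1L, 2L), to = c(2L, 3L),
                       sign = c(1L, 1L), alpha = c(1.2, 1.2),
                       K = c(0.5, 0.5), hill = c(2, 2)),
    basal = c(1.1, 0.08, 0.08),
    beta = c(1.0, 1.0, 1.0)), class = "sgn_net")
}

#' Seeded benchmark fixtures
#'
#' Fully materialised dataset + gold standard, reproducible by seed:
#' \describe{
#'   \item{tiny}{3-gene cascade `g1 -> g2 -> g3`, 80 trajectory + 40
#'     steady-state cells -- smoke tests.}
#'   \item{small}{5 genes at density 0.4 (~6 edges), 150 + 80 cells.}
#'   \item{bench}{10 genes, ~15 edges (density 15/81), 500 trajectory +
#'     300 steady-state cells -- the recovery benchmark.}
#' }
#'
#' @param profile one of `"tiny"`, `"small"`, `"bench"`.
#' @param seed integer seed.
#' @param noise_sd diffusion level passed to [simulate_cells()].
#' @param stimulus enable the stimulus indicator column on the dataset.
#' @return list with `data` ([expression_dataset()]), `gold`
#'   ([gold_standard()]), `net` and `sim`.
#' @export
make_fixture <- function(profile = c("tiny", "small", "bench"), seed = 1L,
                         noise_sd = 0.2, stimulus = FALSE) {
  if (is.character(profile) && length(profile) == 1L &&
      !profile %in% c("tiny", "small", "bench"))
    sgn_stop("unknown fixture profile '", profile, "'",
             class = "sgn_validation_error")
  profile <- match.arg(profile)
  set.seed(seed)
  spec <- switch(profile,
    # start the cascade's driver silent so the network switches on
    tiny = list(net = cascade_network(), n_pseudo = 80L, n_steady = 40L,
                init = c(0, 0.08, 0.08)),
    small = list(net = make_network(5L, 0.4), n_pseudo = 150L,
                 n_steady = 80L, init = NULL),
    bench = list(net = make_network(10L, 15 / 81), n_pseudo = 500L,
                 n_steady = 300L, init = NULL))
  sim <- simulate_cells(spec$net, spec$n_pseudo, spec$n_steady,
                        noise_sd = noise_sd, init = spec$init)
  data <- sim$dataset
  data$stimulus <- isTRUE(stimulus)
  list(data = data, gold = network_gold(spec$net), net = spec$net, sim = sim)
}
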