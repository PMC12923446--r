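---
title: "Sign-constrained random forests for network inference from pseudotime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sign-constrained random forests for network inference from pseudotime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signgenie)
```

## Model and assumptions

The method assumes the regulatory system can be written as a set of
ordinary differential equations, one per gene,

$$\frac{dX_n}{dt} = F_n(\mathbf{X}_{-n}) - \beta_n X_n, \qquad \beta_n > 0,$$

with an arbitrary regulation function $F_n$ of the other genes'
expression levels and first-order decay. Dividing by $\beta_n$ and
writing $G_n = F_n / \beta_n$ gives
$\mathrm{sign}(dX_n/dt) = \mathrm{sign}(G_n(\mathbf{X}_{-n}) - X_n)$.
Two data sources are used:

* **steady-state cells**, where $X_n = G_n(\mathbf{X}_{-n})$ holds, so a
  regression of $X_n$ on $\mathbf{X}_{-n}$ estimates $G_n$ (the GENIE3
  setting);
* **pseudotime-ordered cells**, where absolute derivatives are
  unavailable (pseudotime is only a monotone, not linear, transform of
  time) but derivative *signs* can be read off a smoothed trajectory.

The key inferential assumption is therefore much weaker than in
time-series methods: pseudotime must only order cells correctly, never
measure time. The cost is that sign labels are noisy and many cells are
excluded.

## Labeling

Each gene is smoothed along pseudotime with Cleveland-style tricube
local-linear regression; the slope is the local fit's degree-1
coefficient, not a finite difference of the smooth. Per gene $n$ and
pseudo-time cell, with smoothed level $Sm$, slope $Sl$, trajectory mean
$\bar X_n$ and exclusion quantiles $q_{.05}, q_{.95}$ (all computed over
pseudo-time cells only), the rules apply in order:

1. $x \le q_{.05}$ or $x \ge q_{.95}$: label **X** (excluded);
2. $x \le 0.9\,Sm$ and $Sl > 1.2\,\bar X_n$: label **+**;
3. $x \ge 1.1\,Sm$ and $Sl < -1.2\,\bar X_n$: label **−**;
4. $0.9\,Sm \le x \le 1.1\,Sm$ and $|Sl| < 0.6\,\bar X_n$: label **0**;
5. otherwise **X**.

Boundary equalities resolve exactly as the comparisons are written. All
steady-state cells are labeled **0**. The rationale for rule 2's band
condition: a cell *above* the smooth cannot be confidently said to still
be rising, so only cells below it are trusted as '+'. The constants are
the published operating point and are exposed via `label_thresholds()`
but should rarely be touched. Two open choices were resolved as follows:
the exclusion quantiles and the trajectory mean use pseudo-time cells
only (type-7 quantiles), and the smoothing span (never printed in the
original work) defaults to 0.3 of the cell count, exposed as `span`.

Datasets lacking a separate steady-state population can copy cells with
pseudotime above 0.85 into the '0' set (`tail_as_steady = TRUE`); this
mirrors the observation that trajectory tails sit near equilibrium.

## The ensemble algorithm and its numerical choices

Per target gene, each of `n_tree` iterations bootstraps the '0' cells,
fits `n_subtree` weighted CART regression trees **on that one shared
sample** (per-tree resampling is deliberately absent -- trees differ only
through per-node random feature subsets), bootstraps the '+'/'−' cells,
balances the class weight masses by the prefix under-sampling rule, and
keeps the tree with the smallest hinge penalty $T_n$. Numerical and
tie-break conventions, all chosen for determinism under a seed:

* threshold candidates are midpoints between consecutive distinct sorted
  values (standard CART); equal-gain splits resolve to the lowest feature
  index, then the smallest threshold;
* penalty ties select the lowest tree index;
* weights are normalised to mean 1 inside the fitter (only relative
  weights matter), which makes "all weights equal to a constant" produce
  bit-identical trees to unit weights;
* growth stops at height `n_hmax`, at (numerically) pure nodes, or when
  no sampled feature admits a split;
* per-gene subproblems consume seeds derived deterministically from the
  run seed, so serial and parallel execution orders agree.

A consequence of the under-sampling rule worth stating explicitly: when a
gene has only '+' or only '−' labels (and not both), the empty side's
weight mass is zero, both prefix cutoffs collapse to zero, every penalty
vanishes, and the selection step degenerates to "keep the first tree" --
the method is then *identical in distribution* to the bagged GENIE3
baseline for that gene. The sign constraint only bites for genes whose
trajectory both rises and falls. This is faithful to the under-sampling
arithmetic (an absent class is infinite imbalance, and balancing
prescribes trusting none of the one-sided evidence), and it bounds how
much the method can gain on data dominated by monotone genes.

When '+' and '−' are both entirely absent the implementation skips
fitting the discarded `n_subtree - 1` trees per iteration, which leaves
the RNG stream and results identical to the modified-GENIE3 path (this
equivalence is asserted by a test under a shared seed).

Confidences are permutation ("random-input") importances: the increase in
weighted MSE when one input column is permuted, averaged over trees and
over `n_rnd` independent randomisations. The original description of
this measure lives in prior work not restated here; this package
documents its reading as plain permutation importance, evaluated for each
tree on its own bagging sample (no held-out data is required), with
negative averages kept as computed. Features never split on score
exactly zero. An exact-zero, rather than near-zero, score is guaranteed
because the permuted predictions are bitwise identical to the baseline.

The `reduced` profile (`n_tree = 100`, `n_subtree = 20`, `n_rnd = 10`)
is the package default and the test/CI operating point; `paper` restores
the published values (1000/50/100). The published `n_test =
ceil((N-1)/3)` and `n_hmax = 32` are shared by both.

## What the simulator emulates -- and what it does not

`make_network()` draws sparse signed digraphs with
`round(density * (N-1)^2)` edges, every gene guaranteed one regulator,
and Hill kinetics: activation $\alpha\,x^2/(K^2 + x^2)$, repression
$\alpha\,(1 - x^2/(K^2+x^2))$, basal rate, first-order decay. Parameter
ranges ($\alpha \sim U(0.8,1.6)$, $K \sim U(0.3,1.0)$,
$\beta \sim U(0.8,1.5)$, basal $\sim U(0.05,0.15)$) give expression
scales of order one and relaxation times of order one time unit.

`simulate_cells()` integrates the Euler--Maruyama discretisation of
$dX = [F(X) - \beta X]\,dt + \sigma\,dW$ (reflected at zero,
$dt = 0.01$, horizon 6 time units) from a **perturbed initial state**:
each gene displaced uniformly between zero and its maximal attainable
level, drawn once per run. This emulates an acutely perturbed population
(drug treatment, stimulus switch) relaxing to equilibrium; because such
a displacement mixes relaxation modes, individual genes rise, fall, or
rise-then-fall, as in real induction trajectories. Each trajectory cell
contributes one snapshot at a uniform time; pseudotime is true time
scaled to $[0,1]$, optionally warped by the strictly monotone map
$(t/t_{\max})^\gamma$ to emulate nonlinear pseudotime (sign structure is
invariant under any such warp, which is the method's central premise).
The steady-state cohort diffuses around the noiseless fixed point, whose
drift residual must fall below $10^{-3}$ (otherwise the parameter draw is
rejected with an error). The default diffusion $\sigma = 0.2$ yields
roughly 15% stationary spread relative to expression scale -- moderate
by single-cell standards.

What the simulator does **not** model: mRNA counting noise and dropout,
bursty transcription, branching (bifurcating) trajectories, doublets, or
pseudotime estimation error beyond the monotone warp. A green benchmark
therefore establishes that the pipeline recovers wiring from idealised
trajectory + steady-state snapshots at realistic noise -- not that it is
robust to the full pathology of scRNA-seq data. Two further consequences
of this stated world, measured and worth knowing:

* genes with *both* '+' and '−' labels are rare (most simulated genes
  relax monotonically), so the tree-selection mechanism is exercised
  only on a minority of subproblems and the measured advantage over the
  modified-GENIE3 baseline on the bench fixture is small -- the
  benchmark check of that advantage is directional, not quantitative;
* with zero noise, no cell falls below $0.9 \times$ the smooth, so no
  '+'/'−' labels exist at all; the label-accuracy checks therefore run
  at low (not zero) noise.

## Fixtures and evaluation

`make_fixture()` provides three seeded profiles: `tiny` (hand-built
3-gene cascade, 80 + 40 cells, used for smoke tests and oracle examples),
`small` (5 genes, density 0.4, 150 + 80), `bench` (10 genes, ~15 edges,
500 + 300 -- the recovery benchmark). Precision--recall curves sweep the
distinct confidence values (ties enter as one group); AUPRC is
trapezoidal in recall, anchored at recall zero with the first point's
precision -- stated explicitly since PR interpolation conventions vary.
Auto-regulation is excluded throughout; the stimulus indicator may act
only as a regulator. An undirected matching mode supports
protein-interaction-style references that record no direction.

## Known limitations

* One-sided sign sets neutralise the selection step (see above); data
  whose genes are mostly monotone in pseudotime gain little over
  weighted GENIE3 with random-input importance.
* The hinge penalty compares tree predictions to expression levels of
  non-steady cells -- for trees, an extrapolation beyond the '0'
  training support; with tightly clustered steady-state data many trees
  tie at zero penalty.
* Example weights default to 1; the published companion technique for
  estimating them is out of scope (a weight column hook is provided).
* The CLI reads whole matrices into memory; it targets hundreds to a few
  thousand cells and tens of genes per problem, the regime of the
  original analyses.
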