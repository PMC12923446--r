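Package: signgenie
Title: Gene Regulatory Network Inference from Pseudotime and Steady-State
    Single-Cell Data Using Sign-Constrained Random Forests
Version: 0.1.0
Authors@R:
    person("signgenie", "developers", email = "signgenie@example.org",
           role = c("aut", "cre"))
Description: Infers directed gene regulatory networks from single-cell
    expression snapshots ordered in pseudotime together with a steady-state
    cell population. Each cell is labeled with the estimated sign ('+', '-',
    '0') of the time derivative of every gene's expression, derived from a
    local-linear smoothing of the pseudo time-series. A GENIE3-style weighted
    random forest is trained on the steady-state ('0') cells, and trees are
    retained only when their predictions are consistent with the '+'/'-'
    labeled cells, yielding a tree ensemble from which regulator confidence
    values are computed by permutation (random-input) variable importance.
    Includes a seeded stochastic-kinetics simulator of sparse signed Hill
    networks for benchmarking, precision-recall/AUPRC evaluation against
    gold-standard edge lists, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
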