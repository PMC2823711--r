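Package: ncbench
Title: Realistic Simulation Benchmarks for Non-Coding Sequence Alignment
Version: 0.1.0
Authors@R:
    person("Benchmark", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Generates simulation-based benchmarks for multiple alignment of
    non-coding DNA. Sequences evolve along a phylogeny under the F81
    substitution model with insertions and deletions (mixture-of-geometrics
    lengths) and conserved blocks evolving at a reduced rate, producing leaf
    sequences, the true multiple alignment and a complete per-branch event
    log. Evolutionary parameters (branch-length vectors, substitution:indel
    and insertion:deletion ratios, conserved-block coverage) can be drawn per
    data set from empirical genome-wide distributions rather than fixed at
    their averages. Includes heads-or-tails (HoT) alignment reliability
    scoring with a built-in deterministic progressive aligner, predicted
    versus true alignment accuracy measures (agreement, sensitivity,
    specificity), indel-annotation evaluation measures (ICA, IRA, IAC),
    conserved-block detection from per-column conservation scores, and a
    benchmark generation and evaluation pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
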