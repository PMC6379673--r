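Package: diffmnase
Title: Differential MNase-Seq Simulation and Analysis
Version: 1.0.0
Authors@R:
    person("diffmnase", "developers", email = "diffmnase@example.org",
           role = c("aut", "cre"))
Description: Tools for the differential micrococcal nuclease (MNase)
    sequencing strategy: a stochastic in silico model of MNase digestion of
    nucleosome arrays under partial (low) and complete (high) digestion
    conditions, a genome-scale synthetic data generator with ground truth,
    and the downstream analysis pipeline. The pipeline builds
    midpoint-extended nucleosome occupancy maps from paired-end fragment
    intervals, computes windowed occupancy/GC/mappability statistics with
    GC-aware linear regression and influence filtering, removes digestion GC
    bias by LOESS normalization, calls local MNase hyper-accessible and
    inaccessible sites with FDR control, and profiles dinucleotide
    periodicity around nucleosomal fragments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
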