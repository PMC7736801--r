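Package: dropseqr
Title: Simulation and Analysis of Microdroplet Single-Molecule Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for droplet-ordered single-molecule DNA sequencing, in
    which nucleotides released one at a time from a template are captured
    by a stream of microdroplets and identified by per-channel
    fluorescence. Provides a stochastic simulator of a droplet sequencing
    run (truncated-Poisson base capture, per-colour contamination,
    two-component heavy-tailed intensity mixtures, two-channel
    5-methylcytosine plates), EM fitting of per-channel intensity
    mixtures with crossing-point false-positive/false-negative
    estimation, occupancy calling, reconstruction of reads as ordered
    base multisets with permutation sampling and best-order search,
    Smith-Waterman local alignment with affine gaps and identity
    summaries, two-channel 5-methylcytosine classification, and local
    GC-content profiling by Gaussian filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
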