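Package: nearmedian
Title: Near-Median Genomes for the Breakpoint Median Problem by Adjacency
    Sampling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs "near-median" genomes for sets of k >= 3 signed
    circular genomes under the breakpoint distance.  A seeded two-stage
    adjacency-sampling procedure draws the same fraction of gene
    adjacencies from every input genome, optionally augments the draw with
    residual two-free-end adjacencies resolved by exact maximum matching,
    and completes the set to a full genome.  The package also provides the
    closed-form combinatorial-probability theory behind the construction
    (optimal sampling fraction, binomial/normal success probabilities,
    score bounds under shared-adjacency structure), seeded simulators for
    uniform random genomes and genomes with prescribed shared-adjacency
    fractions, GRIMM-style and adjacency-TSV input/output, broom-style
    tidiers and ggplot2 autoplot methods, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
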