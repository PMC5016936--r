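Package: hervw
Title: Structural, Phylogenetic and Evolutionary Characterization of
    HERV-W Endogenous Retrovirus Loci
Version: 0.1.0
Authors@R:
    person("HERV-W", "Toolkit Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Reference-anchored characterization of HERV-W group
    endogenous retrovirus loci: structural classification of elements as
    proviral insertions, L1-processed pseudogenes or undefined remnants;
    LTR key-position subgroup genotyping; integration dating from Kimura
    2-parameter divergence under a neutral substitution clock;
    neighbor-joining phylogenies with column-resampling bootstrap; primer
    binding site and gammaretroviral motif features; Env putative-protein
    reconstruction with frameshift and stop annotation; and mosaic
    assignment of transcripts to loci by a breakpoint-penalized dynamic
    program.  A synthetic insertion simulator provides ground-truth
    cohorts so the whole pipeline is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    rtracklayer,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
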