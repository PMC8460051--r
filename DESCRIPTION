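Package: poolphylo
Title: Assembly-Free Phylogenies and Haplotype Abundances from Pooled Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the phylogeny, relative abundances and sequencing
    error rate of a known number of haplotypes from an un-barcoded pooled
    short-read alignment, without assembling haplotype sequences. Sites are
    rank-encoded from a SAM/BAM pileup, paired with a high-coverage reference
    site inside non-overlapping windows, and modelled with an infinite-sites
    SNP-pair multinomial likelihood convolved with a uniform sequencing-error
    kernel. Inference is by Metropolis-coupled Markov chain Monte Carlo over
    tree topology, tip abundances and error rate; edge lengths are estimated
    afterwards from per-site mutation-edge posteriors. Includes a synthetic
    mixture simulator (Jukes-Cantor haplotypes, paired-end reads, perfect
    aligner) and a correctness evaluator based on minimum root-mean-square
    abundance pairing under unrooted topology identity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Rsamtools,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    dplyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
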