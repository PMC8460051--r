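#' Simulate a pooled haplotype mixture
#'
#' Generates the study conditions end to end: a random rooted binary tree
#' rescaled to a fixed root-to-tip depth, haplotype sequences evolved
#' site-independently under Jukes-Cantor from a random root sequence, random
#' relative abundances on the simplex subject to a minimum pairwise spacing
#' and a minimum abundance, and paired-end reads with independent uniform
#' per-base errors.  Reads keep their true origin, so a perfect alignment
#' (SAM/BAM) can be emitted without an external aligner; the root sequence is
#' the alignment reference.
#'
#' @param n_hap number of haplotypes (tree tips).
#' @param genome_length haplotype length in bp (default 50000).
#' @param depth root-to-tip tree depth in substitutions/site (default 0.03).
#' @param coverage total read coverage over the pool (default 15000).
#' @param read_length read length in bp (default 150).
#' @param error_rate per-base sequencing error rate (default 0.002; 0 gives
#'   error-free reads).
#' @param insert_mean,insert_sd normal fragment-length distribution
#'   (defaults 400 and 40; fragments are clamped to at least
#'   `2 * read_length` and at most the genome length).
#' @param min_gap minimum pairwise abundance difference (default 0.0033).
#' @param min_abundance minimum single-haplotype abundance (default 1/60,
#'   i.e. the least abundant haplotype keeps 1/60 of the total coverage).
#' @param abundances optional fixed abundance vector (checked against the
#'   constraints' sum-to-one only).
#' @param tree optional fixed tree (`rooted_tree`/`phylo` with branch
#'   lengths); otherwise drawn at random.
#' @param seed optional RNG seed for full reproducibility.
#' @return an object of class `pool_sim`: list with `tree` (phylo, branch
#'   lengths in substitutions/site), `abundances` (named), `haplotypes`
#'   (DNAStringSet), `reference` (root sequence), `reads` (tibble with
#'   fragment id, haplotype, mate, 1-based start, sequence), and `spec`
#'   (the simulation settings).
#' @export
simulate_mixture <- function(n_hap = 5, genome_length = 50000, depth = 0.03,
                             coverage = 15000, read_length = 150,
                             error_rate = 0.002, insert_mean = 400,
                             insert_sd = 40, min_gap = 0.0033,
                             min_abundance = 1 / 60, abundances = NULL,
                             tree = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_hap >= 3, genome_length >= 4 * read_length)

  if (is.null(tree)) {
    phy <- random_depth_tree(n_hap, depth)
  } else {
    phy <- if (inherits(tree, "rooted_tree")) tree$phy else tree
    stopifnot(inherits(phy, "phylo"), !is.null(phy$edge.length))
  }
  if (is.null(phy$tip.label)) phy$tip.label <- paste0("H", seq_len(n_hap))

  if (is.null(abundances)) {
    abundances <- sample_abundances(n_hap, min_gap, min_abundance)
  } else {
    stopifnot(length(abundances) == n_hap,
              abs(sum(abundances) - 1) < 1e-8, all(abundances > 0))
  }
  names(abundances) <- phy$tip.label

  ## haplotypes under JC from a uniform random root sequence
  rootseq <- sample(c("a", "c", "g", "t"), genome_length, replace = TRUE)
  sim <- phangorn::simSeq(phy, l = genome_length, rootseq = rootseq,
                          type = "DNA")
  hap_chr <- toupper(as.character(sim))[phy$tip.label, , drop = FALSE]
  hap_codes <- matrix(match(t(hap_chr), NUC), nrow = genome_length)
  colnames(hap_codes) <- phy$tip.label

  ## paired-end fragments
  n_frag <- max(1L, round(genome_length * coverage / (2 * read_length)))
  hap_of <- sample.int(n_hap, n_frag, replace = TRUE, prob = abundances)
  flen <- pmin(genome_length,
               pmax(2L * read_length,
                    round(stats::rnorm(n_frag, insert_mean, insert_sd))))
  fstart <- 1L + floor(stats::runif(n_frag) * (genome_length - flen + 1))
  r1_start <- fstart
  r2_start <- fstart + flen - read_length

  take_read <- function(starts) {
    idx <- rep.int(starts, rep.int(read_length, length(starts))) +
      rep.int(seq_len(read_length) - 1L, length(starts))
    code <- hap_codes[cbind(idx, rep.int(hap_of,
                                         rep.int(read_length,
                                                 length(starts))))]
    if (error_rate > 0) {
      err <- stats::runif(length(code)) < error_rate
      if (any(err)) {
        shift <- sample.int(3L, sum(err), replace = TRUE)
        code[err] <- ((code[err] - 1L + shift) %% 4L) + 1L
      }
    }
    big <- paste(NUC[code], collapse = "")
    substring(big, (seq_along(starts) - 1L) * read_length + 1L,
              seq_along(starts) * read_length)
  }
  seq1 <- take_read(r1_start)
  seq2 <- take_read(r2_start)

  reads <- tibble::tibble(
    fragment = rep(seq_len(n_frag), 2L),
    haplotype = phy$tip.label[rep(hap_of, 2L)],
    mate = rep(1:2, each = n_frag),
    start = c(r1_start, r2_start),
    seq = c(seq1, seq2)
  )

  structure(
    list(tree = phy, abundances = abundances,
         haplotypes = Biostrings::DNAStringSet(
           stats::setNames(apply(hap_chr, 1L, paste, collapse = ""),
                           phy$tip.label)),
         reference = Biostrings::DNAStringSet(
           stats::setNames(paste(toupper(rootseq), collapse = ""), "ref")),
         reads = reads,
         spec = list(n_hap = n_hap, genome_length = genome_length,
                     depth = depth, coverage = coverage,
                     read_length = read_length, error_rate = error_rate,
                     insert_mean = insert_mean, insert_sd = insert_sd,
                     min_gap = min_gap, min_abundance = min_abundance,
                     seed = seed)),
    class = "pool_sim"
  )
}

#' @export
print.pool_sim <- function(x, ...) {
  cat("<pool_sim> ", x$spec$n_hap, " haplotypes, ", x$spec$genome_length,
      " bp, ", nrow(x$reads), " reads (", x$spec$coverage, "x), error rate ",
      x$spec$error_rate, "\n", sep = "")
  invisible(x)
}

## random labelled rooted binary topology, exponential branch proportions,
## rescaled so the maximum root-to-tip path equals `depth`
random_depth_tree <- function(n, depth = 0.03) {
  st <- random_struct(n, tip_labels = paste0("H", seq_len(n)))
  phy <- struct_to_phylo(st)
  phy$edge.length <- stats::rexp(nrow(phy$edge))
  d <- max(ape::node.depth.edgelength(phy)[seq_len(n)])
  phy$edge.length <- phy$edge.length * depth / d
  phy
}

## uniform draw from the constrained simplex (all entries >= floor, all
## pairwise differences >= min_gap) via the spacings construction: the
## ordered values are floor + gap ladder + rescaled ordered uniform-simplex
## spacings, an affine bijection that preserves the uniform density, then a
## random permutation restores exchangeability.  Exact and rejection-free
## (plain rejection is hopeless at n = 15, acceptance ~ 1e-4).
sample_abundances <- function(n, min_gap = 0.0033, min_abundance = 1 / 60) {
  slack <- 1 - n * min_abundance - min_gap * n * (n - 1) / 2
  if (slack <= 0) {
    stop("infeasible abundance constraints for n = ", n,
         ": floor and spacing need total mass ", round(1 - slack, 3))
  }
  w <- stats::rexp(n)
  w <- sort(w / sum(w))
  a <- min_abundance + min_gap * (seq_len(n) - 1L) + slack * w
  sample(a)
}

#' Write a simulated mixture to disk
#'
#' Emits the reference FASTA, the haplotype FASTA, paired FASTQ files, a
#' truth bundle (newick + abundances as JSON) and — because read origins are
#' known — a perfect alignment as SAM, converted to a sorted and indexed BAM.
#'
#' @param sim a `pool_sim` object.
#' @param dir output directory (created if needed).
#' @param basename file stem (default `"mixture"`).
#' @param fastq also write paired FASTQ files (default `FALSE`; the BAM is
#'   what the pipeline consumes).
#' @return named list of file paths (invisibly: `ref`, `haplotypes`, `sam`,
#'   `bam`, `truth`, and optionally `fastq1`/`fastq2`).
#' @export
write_mixture <- function(sim, dir, basename = "mixture", fastq = FALSE) {
  stopifnot(inherits(sim, "pool_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$ref <- file.path(dir, paste0(basename, "_ref.fasta"))
  Biostrings::writeXStringSet(sim$reference, paths$ref)
  paths$haplotypes <- file.path(dir, paste0(basename, "_haplotypes.fasta"))
  Biostrings::writeXStringSet(sim$haplotypes, paths$haplotypes)

  paths$sam <- file.path(dir, paste0(basename, ".sam"))
  write_perfect_sam(sim, paths$sam)
  paths$bam <- sam_to_bam(paths$sam)

  paths$truth <- file.path(dir, paste0(basename, "_truth.json"))
  jsonlite::write_json(
    list(newick = write_newick(sim$tree),
         abundances = as.list(sim$abundances),
         spec = sim$spec[!vapply(sim$spec, is.null, logical(1))]),
    paths$truth, auto_unbox = TRUE, digits = NA)

  if (fastq) {
    for (m in 1:2) {
      rd <- sim$reads[sim$reads$mate == m, ]
      ss <- Biostrings::DNAStringSet(rd$seq)
      names(ss) <- sprintf("frag%07d/%d", rd$fragment, m)
      f <- file.path(dir, paste0(basename, "_R", m, ".fastq"))
      Biostrings::writeXStringSet(
        ss, f, format = "fastq",
        qualities = Biostrings::BStringSet(
          strrep("I", nchar(rd$seq))))
      paths[[paste0("fastq", m)]] <- f
    }
  }
  invisible(paths)
}

## the "perfect aligner": read positions are known, so alignment records are
## emitted directly (proper pairs, MAPQ 60, all-match CIGAR, Q40 bases)
write_perfect_sam <- function(sim, path) {
  rl <- sim$spec$read_length
  L <- sim$spec$genome_length
  rd <- sim$reads
  r1 <- rd[rd$mate == 1L, ]; r2 <- rd[rd$mate == 2L, ]
  stopifnot(nrow(r1) == nrow(r2))
  qname <- sprintf("frag%07d", r1$fragment)
  tlen <- r2$start + rl - r1$start
  qual <- strrep("I", rl)
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:ref\tLN:", L),
    paste(qname, 99L, "ref", r1$start, 60L, paste0(rl, "M"), "=",
          r2$start, tlen, r1$seq, qual, sep = "\t"),
    paste(qname, 147L, "ref", r2$start, 60L, paste0(rl, "M"), "=",
          r1$start, -tlen, r2$seq, qual, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
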