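# Shared fixtures: the worked-example five-tip tree, hand-written SAM
# builders, and small random-tree generators.  Everything is built in code;
# no binary fixtures.

fig_tree <- function() parse_newick("(A,((B,C),(D,E)));")

fig_R <- c(A = 0.075, B = 0.205, C = 0.205, D = 0.390, E = 0.125)

rand_tree <- function(n) as_rooted_tree(ape::rtree(n))

# write a SAM file from explicit read records and return a BAM-ready path
# reads: data.frame(qname, flag, pos (1-based), mapq, cigar, seq, qual)
write_test_sam <- function(reads, ref_len, path = tempfile(fileext = ".sam")) {
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:ref\tLN:", ref_len),
    vapply(seq_len(nrow(reads)), function(i) {
      r <- reads[i, ]
      paste(r$qname, r$flag, "ref", r$pos, r$mapq, r$cigar, "*", 0, 0,
            r$seq, r$qual, sep = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  path
}

simple_reads <- function(qname, pos, seq, mapq = 60, flag = 0,
                         cigar = NULL, qual = NULL) {
  n <- max(length(qname), length(pos), length(seq))
  seq <- rep_len(seq, n)
  data.frame(
    qname = rep_len(qname, n), flag = rep_len(flag, n),
    pos = rep_len(pos, n), mapq = rep_len(mapq, n),
    cigar = if (is.null(cigar)) paste0(nchar(seq), "M") else
      rep_len(cigar, n),
    seq = seq,
    qual = if (is.null(qual)) strrep("I", nchar(seq)) else rep_len(qual, n),
    stringsAsFactors = FALSE
  )
}

# error-free reads from explicit haplotype strings: `copies` full-length
# reads per haplotype (genome short enough for single reads)
hap_sam <- function(haps, copies, path = tempfile(fileext = ".sam")) {
  seqs <- rep(haps, copies)
  rd <- simple_reads(qname = sprintf("r%04d", seq_along(seqs)),
                     pos = 1L, seq = seqs)
  write_test_sam(rd, ref_len = nchar(haps[[1L]]), path = path)
}

quick_sim_data <- function(..., seed = 1) {
  sim <- simulate_mixture(..., seed = seed)
  paths <- write_mixture(sim, tempfile())
  list(sim = sim,
       data = preprocess_alignment(paths$bam, ref = paths$ref),
       paths = paths)
}
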