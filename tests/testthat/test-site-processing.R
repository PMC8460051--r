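# Alignment ingestion, rank encoding, classification, the infinite-sites
# violation screen, soft-clip masking and window layout, on hand-written
# SAM fixtures and small simulations.

test_that("per-site counts and rank encoding match a hand count", {
  sam <- write_test_sam(
    simple_reads(qname = c("r1", "r2", "r3"), pos = 1L,
                 seq = c("ACG", "ACG", "ATG")),
    ref_len = 3L)
  ac <- build_counts(sam)
  sc <- site_counts(ac)
  expect_equal(sc$coverage, c(3L, 3L, 3L))
  expect_equal(sc$C[sc$pos == 1L], 2L)
  expect_equal(sc$T[sc$pos == 1L], 1L)
  expect_equal(sc$rank0[sc$pos == 1L], "C")
  expect_equal(sc$rank1[sc$pos == 1L], "T")
})

test_that("reads below the MAPQ threshold contribute nothing", {
  sam <- write_test_sam(
    simple_reads(qname = c("r1", "r2"), pos = 1L,
                 seq = c("AAA", "CCC"), mapq = c(60L, 5L)),
    ref_len = 3L)
  ac <- build_counts(sam, min_mapq = 20)
  expect_equal(unname(ac$counts["A", ]), c(1L, 1L, 1L))
  expect_equal(unname(ac$counts["C", ]), c(0L, 0L, 0L))
})

test_that("low base quality and non-ACGT bases are ignored", {
  sam <- write_test_sam(
    simple_reads(qname = "r1", pos = 1L, seq = "ANC",
                 qual = paste0("I", "I", rawToChar(as.raw(33 + 10)))),
    ref_len = 3L)
  ac <- build_counts(sam, min_baseq = 25)
  expect_equal(unname(ac$coverage), c(1, 0, 0))
})

test_that("fragment mode counts mate pairs once per fragment", {
  ## one fragment: mate 1 covers sites 0-2, mate 2 covers sites 2-4; the
  ## shared site 2 must count once per fragment in pair tables
  rd <- rbind(
    simple_reads(qname = "f1", flag = 99L, pos = 1L, seq = "AAC"),
    simple_reads(qname = "f1", flag = 147L, pos = 3L, seq = "CGG"),
    simple_reads(qname = "f2", flag = 99L, pos = 1L, seq = "AAT"),
    simple_reads(qname = "f2", flag = 147L, pos = 3L, seq = "TGG")
  )
  sam <- write_test_sam(rd, ref_len = 5L)
  ac <- build_counts(sam, fragment_mode = TRUE)
  ## pair (site 0, site 4): spans the two mates, only fragment mode sees it
  tab <- pair_counts(ac, 0L, 4L)
  expect_equal(sum(tab), 2L)
  ac1 <- build_counts(sam, fragment_mode = FALSE)
  expect_equal(sum(pair_counts(ac1, 0L, 4L)), 0L)
  ## within-mate pair: counted once per fragment either way
  expect_equal(sum(pair_counts(ac, 0L, 1L)), 2L)
  expect_equal(sum(pair_counts(ac1, 0L, 1L)), 2L)
  ## fragment-mode tables dominate single-mate tables cell-wise here
  for (i in 0:3) for (j in (i + 1):4) {
    expect_true(all(pair_counts(ac, i, j) >= pair_counts(ac1, i, j)))
  }
})

test_that("conflicting mate calls drop the site for that fragment", {
  rd <- rbind(
    simple_reads(qname = "f1", flag = 99L, pos = 1L, seq = "AC"),
    simple_reads(qname = "f1", flag = 147L, pos = 2L, seq = "GT")
  )
  ## site 1 (0-based) is covered by both mates with C vs G
  sam <- write_test_sam(rd, ref_len = 3L)
  ac <- build_counts(sam, fragment_mode = TRUE)
  expect_equal(sum(pair_counts(ac, 0L, 1L)), 0L)
  expect_equal(sum(pair_counts(ac, 0L, 2L)), 1L)
})

test_that("ingestion errors are explicit", {
  expect_error(build_counts(tempfile()), "not found")
  rd <- simple_reads(qname = "r1", pos = 1L, seq = "AAA", mapq = 5L)
  sam <- write_test_sam(rd, ref_len = 3L)
  expect_error(build_counts(sam, min_mapq = 20), "no alignments pass")
})

test_that("classify_invariable follows the single-dominant-nucleotide rule", {
  expect_true(classify_invariable(c(A = 9990, C = 5, G = 3, T = 2),
                                  e_max = 0.01))
  expect_false(classify_invariable(c(A = 700, G = 300)))
  expect_true(classify_invariable(c(A = 100)))
  expect_false(classify_invariable(c(A = 0)))
  ## matrix form, one column per site
  m <- matrix(c(9990, 5, 3, 2, 700, 0, 300, 0), 4)
  expect_equal(classify_invariable(m), c(TRUE, FALSE))
})

test_that("violation screen step 1 flags sites with three common alleles", {
  seqs <- c(rep("A", 6), rep("C", 3), rep("G", 1))
  sam <- write_test_sam(
    simple_reads(qname = sprintf("r%02d", 1:10), pos = 1L, seq = seqs),
    ref_len = 1L)
  ac <- build_counts(sam)
  v <- remove_violating_sites(ac, snp_sites = 0L, min_shared = 1)
  expect_equal(v$pos, 0L)
  expect_equal(v$step, 1L)
})

test_that("violation screen step 2 flags a recurrent-mutation site", {
  ## four haplotypes on tree ((h1,h2),(h3,h4)); site layout (0-based):
  ##  0: recurrent site, derived in h1 and h3 (violates infinite sites)
  ##  1, 2: clade {h1,h2};  3: clade {h3,h4};  4: tip h2
  ## paired with site 0, each of sites 1-3 shows four joint patterns
  haps <- c(h1 = "TCGAA", h2 = "ACGAT", h3 = "TATCA", h4 = "AATCA")
  sam <- hap_sam(haps, copies = c(25, 25, 25, 25))
  ac <- build_counts(sam)
  v <- remove_violating_sites(ac, snp_sites = 0:4, d_partners = 3,
                              min_shared = 50)
  expect_equal(v$pos, 0L)
  expect_equal(v$step, 2L)
  expect_gte(v$n_bad_partners, 3)
  ## with a stricter partner threshold the site survives
  v2 <- remove_violating_sites(ac, snp_sites = 0:4, d_partners = 4,
                               min_shared = 50)
  expect_equal(nrow(v2), 0L)
  ## single-mutation sites are never flagged
  expect_false(any(v$pos %in% 1:4))
})

test_that("soft-clip masking flags heavily trimmed regions only", {
  ## 100 clean reads + 8 soft-clipped reads ending at the same region
  clean <- simple_reads(qname = sprintf("c%03d", 1:100), pos = 1L,
                        seq = strrep("A", 50))
  clipped <- simple_reads(qname = sprintf("s%02d", 1:8), pos = 11L,
                          seq = strrep("A", 50), cigar = "10S40M")
  sam <- write_test_sam(rbind(clean, clipped), ref_len = 60L)
  ac <- build_counts(sam)
  expect_equal(nrow(mask_problem_regions(ac, trim_fraction = 0.2)), 0L)
  m <- mask_problem_regions(ac, trim_fraction = 0.02)
  expect_equal(nrow(m), 1L)
  ## the clipped-away interval precedes the aligned start (0-based 0..9)
  expect_true(m$start[1] <= 1 && m$end[1] >= 9)
  ## an alignment with no clipped reads masks nothing
  sam2 <- write_test_sam(clean, ref_len = 60L)
  expect_equal(nrow(mask_problem_regions(build_counts(sam2),
                                         trim_fraction = 0.02)), 0L)
})

test_that("window layout tiles the alignment and picks reference sites", {
  dd <- quick_sim_data(n_hap = 4, genome_length = 1000, coverage = 150,
                       error_rate = 0.002, seed = 41)
  ac <- dd$data$ac
  snp <- dd$data$classification$pos[dd$data$classification$label == "snp"]
  layout <- layout_windows(ac, snp, d = 100, r = 0.2)
  expect_equal(nrow(layout), 10L)
  expect_equal(layout$start, seq(0L, 900L, by = 100L))
  expect_equal(layout$end, seq(100L, 1000L, by = 100L))
  thr <- max(50, 0.2 * mean(ac$coverage))
  for (w in which(!is.na(layout$ck))) {
    in_win <- snp[snp >= layout$start[w] & snp < layout$end[w]]
    if (isTRUE(layout$threshold_met[w])) {
      ## lowest-coordinate qualifying site
      qual <- in_win[ac$coverage[in_win + 1] >= thr]
      expect_equal(layout$ck[w], qual[1])
    } else {
      ## fallback: highest coverage among the window's SNP sites
      expect_equal(ac$coverage[layout$ck[w] + 1],
                   max(ac$coverage[in_win + 1]))
    }
  }
  ## the reference-coverage rule: max(50, r * cov_avg)
  expect_equal(max(50, 0.2 * 15000), 3000)
})

test_that("rank encoding is invariant under read reordering", {
  set.seed(42)
  seqs <- replicate(30, paste(sample(c("A", "C", "G", "T"), 8,
                                     replace = TRUE), collapse = ""))
  rd <- simple_reads(qname = sprintf("r%02d", 1:30), pos = 1L, seq = seqs)
  sam1 <- write_test_sam(rd, ref_len = 8L)
  sam2 <- write_test_sam(rd[sample(30), ], ref_len = 8L)
  ac1 <- build_counts(sam1); ac2 <- build_counts(sam2)
  expect_equal(ac1$counts, ac2$counts)
  expect_equal(ac1$code_of_rank, ac2$code_of_rank)
})

test_that("per-site counts agree with Rsamtools pileup", {
  sim <- simulate_mixture(n_hap = 4, genome_length = 800, coverage = 100,
                          error_rate = 0.002, seed = 43)
  paths <- write_mixture(sim, tempfile())
  ac <- build_counts(paths$bam, min_baseq = 0)
  pp <- Rsamtools::pileup(
    paths$bam,
    pileupParam = Rsamtools::PileupParam(
      max_depth = 10^6, min_base_quality = 0, min_mapq = 0,
      distinguish_strands = FALSE, include_insertions = FALSE))
  pp <- pp[pp$nucleotide %in% c("A", "C", "G", "T"), ]
  got <- ac$counts
  idx <- cbind(match(as.character(pp$nucleotide), rownames(got)), pp$pos)
  expect_equal(unname(got[idx]), pp$count)
  expect_equal(sum(got), sum(pp$count))
})

test_that("preprocessing output is coherent", {
  dd <- quick_sim_data(n_hap = 4, genome_length = 800, coverage = 200,
                       error_rate = 0.002, seed = 44)
  data <- dd$data
  expect_s3_class(data$sites, "tbl_df")
  ## labels are mutually exclusive and cover every position
  expect_equal(nrow(data$classification), 800L)
  expect_true(all(data$classification$label %in%
                    c("invariable", "snp", "violating", "masked",
                      "low-signal")))
  ## member sites are SNP sites in their window, never the reference
  expect_true(all(data$sites$pos != data$sites$ck))
  win <- data$windows
  for (i in seq_len(nrow(data$sites))) {
    w <- win[win$window == data$sites$window[i], ]
    expect_true(data$sites$pos[i] >= w$start &&
                  data$sites$pos[i] < w$end)
  }
  ## masked or violating sites never enter the likelihood
  bad <- data$classification$pos[data$classification$label %in%
                                   c("masked", "violating")]
  expect_false(any(data$sites$pos %in% bad))
})

test_that("error-free invariable calls equal the constant haplotype columns", {
  sim <- simulate_mixture(n_hap = 4, genome_length = 600, coverage = 200,
                          error_rate = 0, seed = 45,
                          abundances = c(0.4, 0.3, 0.2, 0.1))
  paths <- write_mixture(sim, tempfile())
  ac <- build_counts(paths$bam)
  hap <- as.matrix(Biostrings::DNAStringSet(sim$haplotypes))
  hap <- vapply(seq_len(600), function(i) {
    length(unique(hap[, i])) == 1L
  }, logical(1))
  inv <- classify_invariable(ac$counts, e_max = 0.01)
  covered <- ac$coverage > 0
  expect_equal(inv[covered], hap[covered])
})
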