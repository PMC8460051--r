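## ---- alignment ingestion --------------------------------------------------
##
## Coordinates are 0-based half-open internally; SAM's 1-based positions are
## converted on ingest.  Nucleotide codes are 1..4 for A,C,G,T; per-site rank
## encoding (0 = best supported) is fixed from read-level counts with ties
## broken in the fixed order A < C < G < T.

NUC <- c("A", "C", "G", "T")

## convert a SAM text file to a sorted, indexed BAM next to a tempfile
sam_to_bam <- function(path) {
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
}

## split cigar strings into per-cigar templates:
## refoff/qoff: 0-based reference offsets and 1-based query positions of
## aligned (M/=/X) bases; ref_span: reference bases consumed; lead/trail:
## soft-clip lengths
cigar_templates <- function(cigars) {
  lapply(cigars, function(cg) {
    m <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
    if (!length(m) || paste(m, collapse = "") != cg) {
      stop("unparseable CIGAR: ", cg)
    }
    len <- as.integer(sub("[MIDNSHP=X]", "", m))
    op <- sub("\\d+", "", m)
    refoff <- integer(0); qoff <- integer(0)
    rpos <- 0L; qpos <- 0L
    lead <- 0L; trail <- 0L
    for (i in seq_along(op)) {
      if (op[i] %in% c("M", "=", "X")) {
        refoff <- c(refoff, rpos + seq_len(len[i]) - 1L)
        qoff <- c(qoff, qpos + seq_len(len[i]))
        rpos <- rpos + len[i]; qpos <- qpos + len[i]
      } else if (op[i] %in% c("D", "N")) {
        rpos <- rpos + len[i]
      } else if (op[i] == "I") {
        qpos <- qpos + len[i]
      } else if (op[i] %in% c("S", "H")) {
        if (i == 1L || (i == 2L && op[1L] == "H")) lead <- lead + len[i]
        else trail <- trail + len[i]
        if (op[i] == "S") qpos <- qpos + len[i]
      }
    }
    list(refoff = refoff, qoff = qoff, ref_span = rpos,
         lead = lead, trail = trail)
  })
}

#' Per-site counts and pair-count factory from a read alignment
#'
#' Reads a sorted, indexed BAM (or a SAM, converted on the fly) aligned to a
#' single reference contig and builds the model's sufficient statistics:
#' read-level nucleotide counts per site with the rank encoding (nucleotide
#' with most read support is rank 0, next rank 1, ...), plus a fragment-level
#' long table from which joint pattern counts of any site pair are assembled.
#' Reads below `min_mapq` are discarded; bases below `min_baseq`, deletions
#' and non-ACGT bases are ignored.  With `fragment_mode` the two mates of a
#' fragment count once per site (mate disagreements at a site drop that site
#' for the fragment); otherwise every read counts separately in pair tables.
#'
#' @param aln path to a BAM (sorted + indexed) or SAM file.
#' @param ref optional path to the reference FASTA (used to cross-check the
#'   contig length).
#' @param min_mapq minimum mapping quality (default 20).
#' @param min_baseq minimum base quality (default 25).
#' @param fragment_mode pair mates of one fragment as a single unit
#'   (default `TRUE`).
#' @param contig contig name; required only when the header lists several.
#' @return an object of class `alignment_counts`; see [site_counts()] and
#'   [pair_counts()].
#' @export
build_counts <- function(aln, ref = NULL, min_mapq = 20, min_baseq = 25,
                         fragment_mode = TRUE, contig = NULL) {
  if (!file.exists(aln)) stop("alignment file not found: ", aln)
  bam <- if (grepl("\\.sam$", aln, ignore.case = TRUE)) sam_to_bam(aln) else aln
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam))) {
    stop("missing BAM index (.bai) for ", bam, "; sort and index the file")
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (!length(hdr)) stop("BAM header lists no reference contigs")
  if (is.null(contig)) {
    if (length(hdr) > 1L) {
      stop("multiple contigs in header; name one via `contig`")
    }
    contig <- names(hdr)[1L]
  }
  if (!contig %in% names(hdr)) stop("contig not found in header: ", contig)
  ref_len <- unname(hdr[[contig]])
  if (!is.null(ref)) {
    rs <- Biostrings::readDNAStringSet(ref)
    hit <- if (contig %in% names(rs)) contig else 1L
    if (Biostrings::width(rs)[ifelse(is.character(hit),
                                     match(hit, names(rs)), hit)] != ref_len) {
      stop("reference FASTA length disagrees with BAM header for ", contig)
    }
  }

  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE),
    which = GenomicRanges::GRanges(contig,
                                   IRanges::IRanges(1L, ref_len)))
  b <- Rsamtools::scanBam(bam, param = param)[[1L]]
  keep <- !is.na(b$pos) & !is.na(b$mapq) & b$mapq >= min_mapq &
    !is.na(b$cigar)
  if (!any(keep)) stop("no alignments pass the filters on contig ", contig)
  qname <- b$qname[keep]; pos <- b$pos[keep]; cigar <- b$cigar[keep]
  seqs <- b$seq[keep]; quals <- b$qual[keep]
  n_reads <- length(pos)

  ucig <- unique(cigar)
  tpl <- cigar_templates(ucig)
  tid <- match(cigar, ucig)
  k <- vapply(tpl, function(t) length(t$refoff), integer(1))[tid]

  read_long <- rep.int(seq_len(n_reads), k)
  refoff_long <- unlist(lapply(tpl, `[[`, "refoff")[tid], use.names = FALSE)
  qoff_long <- unlist(lapply(tpl, `[[`, "qoff")[tid], use.names = FALSE)
  pos0 <- (pos[read_long] - 1L) + refoff_long

  widths <- Biostrings::width(seqs)
  qstart <- cumsum(widths) - widths
  gpos <- qstart[read_long] + qoff_long
  seq_raw <- as.integer(charToRaw(paste(as.character(seqs), collapse = "")))
  qual_raw <- as.integer(charToRaw(paste(as.character(quals),
                                         collapse = ""))) - 33L
  code_of_ascii <- rep(NA_integer_, 256L)
  code_of_ascii[utf8ToInt("A")] <- 1L
  code_of_ascii[utf8ToInt("C")] <- 2L
  code_of_ascii[utf8ToInt("G")] <- 3L
  code_of_ascii[utf8ToInt("T")] <- 4L
  code <- code_of_ascii[seq_raw[gpos]]
  bq <- qual_raw[gpos]

  ok <- !is.na(code) & bq >= min_baseq & pos0 >= 0L & pos0 < ref_len
  read_long <- read_long[ok]; pos0 <- pos0[ok]; code <- code[ok]

  ## read-level per-site counts (4 x L) and the rank encoding
  cnt <- matrix(tabulate(pos0 * 4L + code, nbins = 4L * ref_len),
                nrow = 4L, dimnames = list(NUC, NULL))
  coverage <- colSums(cnt)
  code_of_rank <- apply(cnt, 2L, function(x) order(-x, seq_len(4L)))
  rank_of_code <- apply(code_of_rank, 2L, order) - 1L  # 0-based ranks

  ## fragment-level rows: one (unit, site, rank) record per covered site
  unit <- if (fragment_mode) {
    match(qname, unique(qname))[read_long]
  } else {
    read_long
  }
  rank <- rank_of_code[cbind(code, pos0 + 1L)]
  key <- as.numeric(unit) * ref_len + pos0
  o <- order(key, rank, method = "radix")
  key <- key[o]; unit_o <- unit[o]; pos_o <- pos0[o]; rank_o <- rank[o]
  first <- !duplicated(key)
  ## mates disagreeing at a site: drop the site for that fragment
  ref_rank <- rank_o[first][cumsum(first)]
  bad_keys <- unique(key[rank_o != ref_rank])
  keep2 <- first & !(key %in% bad_keys)
  frag_rows <- list(unit = unit_o[keep2], site = pos_o[keep2],
                    rank = rank_o[keep2])

  ## soft-clip ("trimmed") coverage per reference position
  lead <- vapply(tpl, `[[`, integer(1), "lead")[tid]
  trail <- vapply(tpl, `[[`, integer(1), "trail")[tid]
  span <- vapply(tpl, `[[`, integer(1), "ref_span")[tid]
  clip_pos <- integer(0)
  has_lead <- which(lead > 0L)
  if (length(has_lead)) {
    clip_pos <- c(clip_pos, unlist(lapply(has_lead, function(i) {
      seq.int(max(0L, pos[i] - 1L - lead[i]), pos[i] - 2L)
    })))
  }
  has_trail <- which(trail > 0L)
  if (length(has_trail)) {
    clip_pos <- c(clip_pos, unlist(lapply(has_trail, function(i) {
      from <- pos[i] - 1L + span[i]
      seq.int(from, min(ref_len - 1L, from + trail[i] - 1L))
    })))
  }
  clip_pos <- clip_pos[clip_pos >= 0L & clip_pos < ref_len]
  trimmed_cov <- tabulate(clip_pos + 1L, nbins = ref_len)

  structure(
    list(contig = contig, ref_len = ref_len,
         n_reads = n_reads,
         n_fragments = length(unique(unit)),
         counts = cnt, coverage = coverage,
         code_of_rank = code_of_rank, rank_of_code = rank_of_code,
         frag_rows = frag_rows, trimmed_cov = trimmed_cov,
         params = list(min_mapq = min_mapq, min_baseq = min_baseq,
                       fragment_mode = fragment_mode)),
    class = "alignment_counts"
  )
}

#' @export
print.alignment_counts <- function(x, ...) {
  cat("<alignment_counts> contig ", x$contig, " (", x$ref_len, " bp), ",
      x$n_reads, " reads / ", x$n_fragments, " fragments, mean coverage ",
      round(mean(x$coverage), 1), "\n", sep = "")
  invisible(x)
}

#' Per-site count table
#'
#' @param ac an `alignment_counts` object.
#' @return tibble with one row per reference position (`pos`, 0-based):
#'   read-level counts of A,C,G,T, `coverage`, and the rank-0/rank-1
#'   nucleotides.
#' @export
site_counts <- function(ac) {
  stopifnot(inherits(ac, "alignment_counts"))
  tibble::tibble(
    pos = seq_len(ac$ref_len) - 1L,
    A = ac$counts[1L, ], C = ac$counts[2L, ],
    G = ac$counts[3L, ], T = ac$counts[4L, ],
    coverage = as.integer(ac$coverage),
    rank0 = NUC[ac$code_of_rank[1L, ]],
    rank1 = NUC[ac$code_of_rank[2L, ]]
  )
}

#' Joint pattern counts of a site pair
#'
#' The 4x4 table `n(p, q)` of sequencing units (fragments, or reads when
#' `fragment_mode` was off) carrying rank `p` at site `i` and rank `q` at
#' site `j`.
#'
#' @param ac an `alignment_counts` object.
#' @param i,j 0-based reference positions.
#' @return 4x4 integer matrix (rows: rank at `i`; columns: rank at `j`).
#' @export
pair_counts <- function(ac, i, j) {
  stopifnot(inherits(ac, "alignment_counts"))
  fr <- ac$frag_rows
  ri <- fr$site == i
  rj <- fr$site == j
  m <- match(fr$unit[ri], fr$unit[rj])
  hit <- !is.na(m)
  p <- fr$rank[ri][hit]
  q <- fr$rank[rj][m[hit]]
  matrix(tabulate(p * 4L + q + 1L, nbins = 16L), 4L, 4L, byrow = TRUE,
         dimnames = list(as.character(0:3), as.character(0:3)))
}

## ---- site classification --------------------------------------------------

#' Is a site invariable?
#'
#' A site is called invariable when exactly one nucleotide is supported by
#' more than a proportion `e_max` of the reads covering it: any further
#' nucleotides are then attributable to sequencing error.
#'
#' @param counts numeric vector of per-nucleotide read counts (a single
#'   site), or a 4-row matrix of counts (one column per site).
#' @param e_max maximum plausible sequencing error rate (default 0.01).
#' @return logical (vector, for matrix input).
#' @export
classify_invariable <- function(counts, e_max = 0.01) {
  if (is.matrix(counts)) {
    cov <- colSums(counts)
    above <- colSums(sweep(counts, 2L, pmax(cov, 1L), "/") > e_max)
    return(above == 1L & cov > 0L)
  }
  stopifnot(is.numeric(counts))
  cov <- sum(counts)
  if (cov == 0) return(FALSE)
  sum(counts / cov > e_max) == 1L
}

#' Mask problematic regions
#'
#' Positions where the number of reads whose alignment was soft-clipped over
#' the position exceeds `trim_fraction` of the local read coverage are
#' masked; such regions signal reference/read dissimilarity that distorts the
#' local haplotype ratios.
#'
#' @param ac an `alignment_counts` object.
#' @param trim_fraction proportion of the local coverage above which clipped
#'   reads trigger masking (default 0.02).
#' @return tibble of masked intervals (`start`, `end`; 0-based half-open).
#' @export
mask_problem_regions <- function(ac, trim_fraction = 0.02) {
  stopifnot(inherits(ac, "alignment_counts"))
  bad <- ac$trimmed_cov > trim_fraction * pmax(ac$coverage, 1)
  intervals_from_mask(bad)
}

intervals_from_mask <- function(bad) {
  if (!any(bad)) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

in_intervals <- function(pos, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (k in seq_len(nrow(iv))) {
    out <- out | (pos >= iv$start[k] & pos < iv$end[k])
  }
  out
}

#' Flag sites violating the infinite-sites assumption
#'
#' Two-step screen for sites whose history contains more than one mutation.
#' Step 1: a site with more than two nucleotides each supported by at least
#' `e_max` of its reads is flagged.  Step 2: a biallelic SNP site `i` is
#' flagged when at least `d_partners` other SNP sites, each sharing at least
#' `min_shared` sequencing units with `i`, separately produce four or more
#' joint patterns supported by at least 1% (`e_max`) of the shared units —
#' impossible for two single-mutation sites on one tree.
#'
#' @param ac an `alignment_counts` object.
#' @param snp_sites 0-based positions already classified as biallelic SNP
#'   sites.
#' @param d_partners number of incompatible partners required to flag a site
#'   (default 3).
#' @param e_max support threshold (default 0.01).
#' @param min_shared minimum shared units for a pair to be informative
#'   (default 50).
#' @return tibble (`pos`, `step`, `n_bad_partners`) of flagged sites.
#' @export
remove_violating_sites <- function(ac, snp_sites, d_partners = 3,
                                   e_max = 0.01, min_shared = 50) {
  stopifnot(inherits(ac, "alignment_counts"))
  ## step 1: more than two nucleotides above threshold
  prop <- sweep(ac$counts[, snp_sites + 1L, drop = FALSE], 2L,
                pmax(ac$coverage[snp_sites + 1L], 1L), "/")
  step1 <- snp_sites[colSums(prop >= e_max) > 2L]

  ## step 2: pairwise pattern screen among biallelic SNP sites
  two <- setdiff(snp_sites, step1)
  fr <- ac$frag_rows
  sel <- fr$site %in% two
  unit <- fr$unit[sel]; site <- fr$site[sel]; rank <- fr$rank[sel]
  o <- order(unit, site, method = "radix")
  unit <- unit[o]; site <- site[o]; rank <- rank[o]
  n_bad <- integer(0)
  if (length(unit)) {
    runs <- rle(unit)$lengths
    grp_end <- cumsum(runs)
    grp_start <- grp_end - runs + 1L
    pair_i <- vector("list", length(runs))
    pair_j <- vector("list", length(runs))
    for (g in seq_along(runs)) {
      m <- runs[g]
      if (m < 2L) next
      idx <- grp_start[g]:grp_end[g]
      a <- rep(seq_len(m - 1L), times = (m - 1L):1L)
      b <- a + sequence((m - 1L):1L)
      pair_i[[g]] <- idx[a]
      pair_j[[g]] <- idx[b]
    }
    ii <- unlist(pair_i, use.names = FALSE)
    jj <- unlist(pair_j, use.names = FALSE)
    if (length(ii)) {
      L <- ac$ref_len
      pkey <- as.numeric(site[ii]) * L + site[jj]
      code <- rank[ii] * 4L + rank[jj]
      full <- pkey * 16 + code
      s <- sort(full, method = "radix")
      r <- rle(s)
      cell_pair <- floor(r$values / 16)
      cell_n <- r$lengths
      ## per pair: total units and number of cells >= e_max of them
      pr <- rle(cell_pair)
      pend <- cumsum(pr$lengths); pstart <- pend - pr$lengths + 1L
      upair <- pr$values
      n_hat <- vapply(seq_along(upair),
                      function(k) sum(cell_n[pstart[k]:pend[k]]), numeric(1))
      n_combo <- vapply(seq_along(upair), function(k) {
        cc <- cell_n[pstart[k]:pend[k]]
        sum(cc >= e_max * n_hat[k])
      }, numeric(1))
      bad <- n_hat >= min_shared & n_combo > 3
      if (any(bad)) {
        si <- floor(upair[bad] / L)
        sj <- upair[bad] - si * L
        tab <- table(factor(c(si, sj), levels = two))
        n_bad <- as.integer(tab)
        names(n_bad) <- two
      }
    }
  }
  step2 <- if (length(n_bad)) {
    as.integer(names(n_bad)[n_bad >= d_partners])
  } else integer(0)
  dplyr::bind_rows(
    tibble::tibble(pos = as.integer(step1), step = 1L,
                   n_bad_partners = NA_integer_),
    tibble::tibble(pos = step2, step = 2L,
                   n_bad_partners = n_bad[n_bad >= d_partners])
  ) |> dplyr::arrange(.data$pos)
}

#' Partition the alignment into windows and pick reference sites
#'
#' The alignment is tiled with non-overlapping windows of `d` bp.  Within
#' each window the reference site `c_k` is the lowest-coordinate usable SNP
#' site covered by at least `max(50, r * cov_avg)` reads; when no site
#' qualifies, the SNP site with the highest coverage is taken.  Windows
#' without SNP sites get no reference and contribute nothing downstream.
#'
#' @param ac an `alignment_counts` object.
#' @param snp_sites 0-based positions of usable SNP sites.
#' @param d window width in bp (default 100).
#' @param r coverage fraction entering the reference-site threshold
#'   (default 0.2).
#' @return tibble (`window`, `start`, `end`, `ck`, `ck_coverage`,
#'   `threshold_met`).
#' @export
layout_windows <- function(ac, snp_sites, d = 100, r = 0.2) {
  stopifnot(inherits(ac, "alignment_counts"))
  cov_avg <- mean(ac$coverage)
  thr <- max(50, r * cov_avg)
  starts <- seq.int(0L, ac$ref_len - 1L, by = d)
  ends <- pmin(starts + d, ac$ref_len)
  ck <- rep(NA_integer_, length(starts))
  met <- rep(NA, length(starts))
  for (w in seq_along(starts)) {
    s <- snp_sites[snp_sites >= starts[w] & snp_sites < ends[w]]
    if (!length(s)) next
    cov <- ac$coverage[s + 1L]
    qual <- s[cov >= thr]
    if (length(qual)) {
      ck[w] <- qual[1L]          # lowest coordinate
      met[w] <- TRUE
    } else {
      ck[w] <- s[order(-cov, s)[1L]]
      met[w] <- FALSE
    }
  }
  tibble::tibble(window = seq_along(starts), start = starts, end = ends,
                 ck = ck, ck_coverage = ifelse(is.na(ck), NA_integer_,
                                               ac$coverage[ck + 1L]),
                 threshold_met = met)
}

## ---- full preprocessing pipeline -----------------------------------------

#' Preprocess an alignment into model-ready statistics
#'
#' Runs the full preprocessing pipeline: per-site counting and rank encoding
#' ([build_counts()]), soft-clip masking ([mask_problem_regions()]),
#' invariable/SNP classification, the infinite-sites violation screen
#' ([remove_violating_sites()]), window layout ([layout_windows()]), and the
#' assembly of per-window pair-count tables of every usable SNP site against
#' its window reference.  The result feeds [alignment_log_likelihood()],
#' [run_mcmcmc()] and [estimate_lengths()].
#'
#' @inheritParams build_counts
#' @param d window width in bp (default 100).
#' @param r coverage fraction for reference-site selection (default 0.2).
#' @param e_max maximum plausible sequencing error rate (default 0.01).
#' @param d_partners partner threshold of the violation screen (default 3).
#' @param trim_fraction soft-clip masking threshold (default 0.02).
#' @param min_shared minimum shared units for pair screens (default 50).
#' @param keep_counts keep the `alignment_counts` object inside the result
#'   (needed later for edge-length estimation; default `TRUE`).
#' @return an object of class `pooldata`.
#' @export
preprocess_alignment <- function(aln, ref = NULL, d = 100, r = 0.2,
                                 e_max = 0.01, d_partners = 3,
                                 trim_fraction = 0.02, min_mapq = 20,
                                 min_baseq = 25, fragment_mode = TRUE,
                                 min_shared = 50, contig = NULL,
                                 keep_counts = TRUE) {
  ac <- build_counts(aln, ref = ref, min_mapq = min_mapq,
                     min_baseq = min_baseq, fragment_mode = fragment_mode,
                     contig = contig)
  masked <- mask_problem_regions(ac, trim_fraction = trim_fraction)
  pos <- seq_len(ac$ref_len) - 1L
  is_masked <- in_intervals(pos, masked)

  cov <- pmax(ac$coverage, 1L)
  prop <- sweep(ac$counts, 2L, cov, "/")
  invariable <- classify_invariable(ac$counts, e_max = e_max) & !is_masked
  n_atleast <- colSums(prop >= e_max & ac$counts > 0L)
  snp0 <- which(!is_masked & !invariable & n_atleast == 2L &
                  ac$coverage > 0L) - 1L

  viol <- remove_violating_sites(ac, snp0, d_partners = d_partners,
                                 e_max = e_max, min_shared = min_shared)
  ## step-1 screening also applies to sites with >2 alleles that were never
  ## biallelic SNPs; those are already excluded from snp0
  usable <- setdiff(snp0, viol$pos)

  label <- rep("low-signal", ac$ref_len)
  label[is_masked] <- "masked"
  label[invariable] <- "invariable"
  more2 <- which(!is_masked & !invariable & n_atleast > 2L) - 1L
  label[more2 + 1L] <- "violating"
  label[viol$pos + 1L] <- "violating"
  label[usable + 1L] <- "snp"
  classification <- tibble::tibble(pos = pos, label = label,
                                   coverage = as.integer(ac$coverage))

  layout <- layout_windows(ac, usable, d = d, r = r)

  ## pair tables of every usable member site against its window reference
  built <- build_pair_tables(ac, layout, member_sites = usable)

  pr_of_site <- function(p0) {
    cd <- ac$code_of_rank[1:2, p0 + 1L]
    cts <- ac$counts[cbind(cd, p0 + 1L)]
    if (sum(cts) == 0) c(0.5, 0.5) else cts / sum(cts)
  }
  windows <- layout[!is.na(layout$ck), ]
  windows$pr_rc <- lapply(windows$ck, pr_of_site)
  windows$ck_counts <- lapply(windows$ck, function(p0) {
    ac$counts[ac$code_of_rank[, p0 + 1L], p0 + 1L]
  })

  sites <- built$sites
  sites$pr_r <- lapply(sites$pos, pr_of_site)

  out <- list(sites = sites, windows = windows,
              classification = classification, masked = masked,
              cov_avg = mean(ac$coverage), ref_len = ac$ref_len,
              n_skipped = built$n_skipped,
              params = list(d = d, r = r, e_max = e_max,
                            d_partners = d_partners,
                            trim_fraction = trim_fraction,
                            min_mapq = min_mapq, min_baseq = min_baseq,
                            fragment_mode = fragment_mode,
                            min_shared = min_shared))
  out$cpp <- build_cpp_data(sites, windows)
  if (keep_counts) out$ac <- ac
  structure(out, class = "pooldata")
}

## assemble sparse pair-count tables (site vs its window's ck) for the given
## member sites; sites sharing no units with ck are skipped and counted
build_pair_tables <- function(ac, layout, member_sites) {
  L <- ac$ref_len
  win <- layout[!is.na(layout$ck), ]
  ck_of_window <- stats::setNames(win$ck, win$window)
  site_window <- findInterval(member_sites, layout$start)
  keep <- layout$window[site_window] %in% win$window
  member <- member_sites[keep]
  mwin <- layout$window[site_window[keep]]
  mck <- ck_of_window[as.character(mwin)]
  drop_self <- member == mck
  member <- member[!drop_self]; mwin <- mwin[!drop_self]
  mck <- mck[!drop_self]

  fr <- ac$frag_rows
  ck_set <- unique(win$ck)
  is_ck_row <- fr$site %in% ck_set
  ck_key <- as.numeric(fr$unit[is_ck_row]) * L + fr$site[is_ck_row]
  ck_rank <- fr$rank[is_ck_row]

  sel <- fr$site %in% member
  s_unit <- fr$unit[sel]; s_site <- fr$site[sel]; s_rank <- fr$rank[sel]
  widx <- match(s_site, member)
  want_key <- as.numeric(s_unit) * L + mck[widx]
  hit <- match(want_key, ck_key)
  ok <- !is.na(hit)
  p <- s_rank[ok]; q <- ck_rank[hit[ok]]
  sidx <- widx[ok]

  full <- (as.numeric(sidx) - 1) * 16 + p * 4 + q
  s <- sort(full, method = "radix")
  r <- rle(s)
  cell_site <- floor(r$values / 16) + 1
  cell_code <- r$values - (cell_site - 1) * 16
  counts <- r$lengths

  cells_by_site <- split(as.integer(cell_code), cell_site)
  counts_by_site <- split(as.numeric(counts), cell_site)
  got <- as.integer(names(cells_by_site))
  n_skipped <- length(member) - length(got)

  lconst <- vapply(counts_by_site, function(cc) {
    lgamma(sum(cc) + 1) - sum(lgamma(cc + 1))
  }, numeric(1))

  sites <- tibble::tibble(
    pos = member[got],
    window = mwin[got],
    ck = unname(mck[got]),
    n_hat = vapply(counts_by_site, sum, numeric(1)),
    cells = unname(cells_by_site),
    counts = unname(counts_by_site),
    lconst = unname(lconst)
  )
  list(sites = sites, n_skipped = n_skipped)
}

#' @export
print.pooldata <- function(x, ...) {
  lab <- table(x$classification$label)
  cat("<pooldata> ", x$ref_len, " bp, mean coverage ",
      round(x$cov_avg, 1), "\n", sep = "")
  cat("  sites: ", paste(names(lab), as.integer(lab), sep = "=",
                         collapse = ", "), "\n", sep = "")
  cat("  windows with reference site: ", nrow(x$windows),
      "; usable site pairs: ", nrow(x$sites),
      "; skipped (no shared units): ", x$n_skipped, "\n", sep = "")
  invisible(x)
}
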