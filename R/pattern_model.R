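#' Expected single-site state probabilities
#'
#' Forward model for one site under the infinite-sites assumption: a mutation
#' on edge `u` flips the root state `r` for exactly the tips below `u`, so the
#' probability of observing the derived state in the read pool equals the
#' summed relative abundance of that clade.  `u = 0` (no mutation) leaves every
#' read in the root state.
#'
#' @param tree a `rooted_tree`.
#' @param R tip relative abundances, named by tip label or in `tree` tip
#'   order; must be strictly positive and sum to 1.
#' @param u edge index `0..2n-2` (`0` = no mutation).
#' @param r root state, `0` or `1`.
#' @return named numeric vector `c("0" = , "1" = )` summing to 1.
#' @examples
#' tr <- parse_newick("(A,((B,C),(D,E)));")
#' R <- c(A = 0.075, B = 0.205, C = 0.205, D = 0.39, E = 0.125)
#' single_site_probs(tr, R, edge_above(tr, "A"), 0)[["1"]]  # 0.075
#' @export
single_site_probs <- function(tree, R, u, r = 0L) {
  tree <- as_rooted_tree(tree)
  R <- check_abundances(R, tree)
  stopifnot(r %in% c(0L, 1L))
  if (!is.numeric(u) || length(u) != 1L || u < 0L || u > tree$n_edges) {
    stop("edge index out of range: u = ", u)
  }
  derived <- if (u == 0L) 0 else sum(R[tree$clades[u, ]])
  p <- numeric(2L)
  p[1L + (1L - r)] <- derived        # state 1-r: mutated clade
  p[1L + r] <- 1 - derived
  stats::setNames(p, c("0", "1"))
}

#' Expected clean pair-pattern probabilities
#'
#' Joint distribution of the error-free states at two sites `i`, `j` on reads
#' spanning both, given that the mutation at site `i` lies on edge `u`, the
#' mutation at site `j` on edge `v`, and the root states are `r_i`, `r_j`.
#' Each tip's joint state is (`r_i` flipped iff the tip is below `u`,
#' `r_j` flipped iff below `v`), and a cell's probability is the summed
#' abundance of tips in that state.  Because clades of two edges are always
#' nested or disjoint, at most three of the four cells are nonzero.
#'
#' @inheritParams single_site_probs
#' @param v edge index for site `j` (`0` = no mutation).
#' @param r_i,r_j root states at sites `i` and `j`.
#' @return 2x2 numeric matrix; rows = state at site `i` (`0`,`1`),
#'   columns = state at site `j`.
#' @export
pair_pattern_probs <- function(tree, R, u, v, r_i = 0L, r_j = 0L) {
  tree <- as_rooted_tree(tree)
  R <- check_abundances(R, tree)
  stopifnot(r_i %in% c(0L, 1L), r_j %in% c(0L, 1L))
  for (w in c(u, v)) {
    if (!is.numeric(w) || length(w) != 1L || w < 0L || w > tree$n_edges) {
      stop("edge index out of range: ", w)
    }
  }
  in_u <- if (u == 0L) rep(FALSE, tree$n_tips) else tree$clades[u, ]
  in_v <- if (v == 0L) rep(FALSE, tree$n_tips) else tree$clades[v, ]
  p_state <- ifelse(in_u, 1L - r_i, r_i)
  q_state <- ifelse(in_v, 1L - r_j, r_j)
  tab <- matrix(0, 2L, 2L, dimnames = list(c("0", "1"), c("0", "1")))
  for (t in seq_len(tree$n_tips)) {
    tab[p_state[t] + 1L, q_state[t] + 1L] <-
      tab[p_state[t] + 1L, q_state[t] + 1L] + R[t]
  }
  tab
}

## per-base misread kernel: stay with prob 1-e, each of the three error
## ranks with prob e/3
psi_matrix <- function(e) {
  m <- matrix(e / 3, 2L, 4L)
  m[1L, 1L] <- 1 - e
  m[2L, 2L] <- 1 - e
  m
}

#' Convolve a clean pair table with sequencing error
#'
#' Maps the 2x2 error-free pattern table onto the 4x4 table over rank-encoded
#' nucleotides `{0,1,2,3}`: each true base is read correctly with probability
#' `1 - e` and as any particular other rank with probability `e/3`,
#' independently at the two sites.
#'
#' @param clean 2x2 clean pattern table (rows site `i`, columns site `j`).
#' @param e per-base error rate.
#' @param e_max upper bound of the error-rate support (contract check).
#' @return 4x4 numeric matrix summing to 1.
#' @export
error_convolve <- function(clean, e, e_max = 0.01) {
  stopifnot(is.matrix(clean), all(dim(clean) == 2L))
  if (!is.numeric(e) || length(e) != 1L || e < 0 || e > e_max) {
    stop("error rate out of range: e = ", e, " (support [0, ", e_max, "])")
  }
  psi <- psi_matrix(e)
  out <- t(psi) %*% clean %*% psi
  dimnames(out) <- list(as.character(0:3), as.character(0:3))
  out
}

## single-site analogue: 2-vector of clean probs -> 4-vector over ranks
error_convolve_single <- function(clean, e) {
  drop(clean %*% psi_matrix(e))
}

#' Multinomial log likelihood of a pair-pattern count table
#'
#' Reads spanning a site pair are modelled as multinomial draws from the
#' noisy pattern table.  Computed in log space via `lgamma`; returns `-Inf`
#' when a cell with zero probability carries a positive count.
#'
#' @param counts 4x4 (or matching-dimension) non-negative count table.
#' @param probs probability table of the same dimension.
#' @return log likelihood (including the multinomial coefficient).
#' @export
pair_log_likelihood <- function(counts, probs) {
  stopifnot(is.numeric(counts), is.numeric(probs),
            length(counts) == length(probs))
  if (any(counts < 0)) stop("negative counts")
  if (any(counts != round(counts))) stop("counts must be integers")
  n_hat <- sum(counts)
  if (n_hat == 0) return(0)
  pos <- counts > 0
  if (any(probs[pos] <= 0)) return(-Inf)
  lgamma(n_hat + 1) - sum(lgamma(counts[pos] + 1)) +
    sum(counts[pos] * log(probs[pos]))
}

#' Group SNP sites into ratio classes
#'
#' The observed minor-pattern proportion ("SNP ratio") of each biallelic site
#' is grouped into classes whose centres differ by more than `tol`; the "SNP
#' frequency" of a class is the fraction of SNP sites it contains.  The pair
#' is the mixture analogue of a site-frequency spectrum.  Diagnostic only.
#'
#' @param ratios numeric vector of per-site minor ratios in `(0, 0.5]`.
#' @param tol absolute grouping tolerance (default 0.02): sorted ratios are
#'   split into a new class whenever the gap to the running class mean
#'   exceeds `tol`.
#' @return a tibble with columns `ratio` (class mean), `n_sites`,
#'   `frequency`; frequencies sum to 1.
#' @examples
#' snp_spectrum(c(0.25, 0.4, 0.25))  # class 0.25 has frequency 2/3
#' @export
snp_spectrum <- function(ratios, tol = 0.02) {
  stopifnot(is.numeric(ratios), length(ratios) >= 1L)
  if (any(ratios <= 0 | ratios > 0.5)) {
    stop("SNP ratios must lie in (0, 0.5]")
  }
  ord <- order(ratios)
  x <- ratios[ord]
  cls <- integer(length(x))
  cur <- 1L; acc <- x[1L]; k <- 1L
  cls[1L] <- 1L
  if (length(x) > 1L) {
    for (i in 2:length(x)) {
      if (x[i] - acc / k > tol) {
        cur <- cur + 1L; acc <- 0; k <- 0L
      }
      cls[i] <- cur
      acc <- acc + x[i]; k <- k + 1L
    }
  }
  out <- tibble::tibble(ratio = as.numeric(tapply(x, cls, mean)),
                        n_sites = as.integer(table(cls)))
  out$frequency <- out$n_sites / sum(out$n_sites)
  out
}

## shared contract check for abundance vectors
check_abundances <- function(R, tree = NULL) {
  if (!is.numeric(R)) stop("abundances must be numeric")
  if (any(R <= 0)) stop("abundances must be strictly positive")
  if (abs(sum(R) - 1) > 1e-8) {
    stop("abundances must sum to 1 (got ", format(sum(R)), ")")
  }
  if (!is.null(tree)) {
    tree <- as_rooted_tree(tree)
    if (length(R) != tree$n_tips) {
      stop("need one abundance per tip (", tree$n_tips, ")")
    }
    if (!is.null(names(R))) {
      if (!setequal(names(R), tree$tip_labels)) {
        stop("abundance names do not match tip labels")
      }
      R <- R[tree$tip_labels]
    }
  }
  unname(R)
}
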