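## log noisy pattern tables for every (u, v, r_i, r_c) as a matrix with one
## row per combination and 16 columns (pattern codes p*4+q); row index
## ((u*E1 + v)*2 + ri)*2 + rc + 1 with u, v in 0..E (0 = no mutation)
log_prob_matrix <- function(tree, R, e) {
  tree <- as_rooted_tree(tree)
  E1 <- tree$n_edges + 1L
  M <- matrix(-Inf, E1 * E1 * 4L, 16L)
  for (u in 0:(E1 - 1L)) {
    for (v in 0:(E1 - 1L)) {
      for (ri in 0:1) {
        for (rc in 0:1) {
          tab <- error_convolve(pair_pattern_probs(tree, R, u, v, ri, rc),
                                e, e_max = 1)
          idx <- ((u * E1 + v) * 2L + ri) * 2L + rc + 1L
          M[idx, ] <- log(as.vector(t(tab)))  # code p*4+q varies q fastest
        }
      }
    }
  }
  M
}

## single-site log likelihood of rank counts at a reference site for each
## (u, r): multinomial over the noisy single-site distribution
ck_loglik <- function(tree, R, e, counts) {
  tree <- as_rooted_tree(tree)
  E1 <- tree$n_edges + 1L
  out <- matrix(NA_real_, E1, 2L)
  lconst <- lgamma(sum(counts) + 1) - sum(lgamma(counts + 1))
  for (u in 0:(E1 - 1L)) {
    for (r in 0:1) {
      clean <- single_site_probs(tree, R, u, r)
      p4 <- error_convolve_single(clean, e)
      pos <- counts > 0
      out[u + 1L, r + 1L] <- if (any(p4[pos] <= 0)) -Inf else
        lconst + sum(counts[pos] * log(p4[pos]))
    }
  }
  out
}

#' Per-site posterior over mutation edges
#'
#' For the fitted `(T, R, e)`, computes for every requested site the
#' posterior probability that its mutation lies on each edge of the tree
#' (edge 0 being "no mutation").  A window's reference site uses its own
#' rank counts directly; every other site is scored through its pair table
#' with the reference, integrating over the reference's mutation edge with
#' the reference-site posterior as weight — so reference-site posteriors
#' are always computed first.
#'
#' @param data a `pooldata` object built with `keep_counts = TRUE`.
#' @param tree fitted topology (`rooted_tree`/`phylo`, `n` tips).
#' @param R fitted tip abundances.
#' @param e fitted error rate.
#' @param include_invariable also score sites classified invariable (their
#'   mass falls on "no mutation"); default `TRUE`.
#' @return list with `posteriors` (matrix, sites x (2n-1), columns
#'   `eps, e1..e2n-2`), `sites` (0-based positions), `n_skipped`.
#' @export
site_edge_posteriors <- function(data, tree, R, e,
                                 include_invariable = TRUE) {
  stopifnot(inherits(data, "pooldata"))
  if (is.null(data$ac)) {
    stop("pooldata was built with keep_counts = FALSE; ",
         "re-run preprocess_alignment() keeping the counts")
  }
  tree <- as_rooted_tree(tree)
  R <- check_abundances(R, tree)
  E1 <- tree$n_edges + 1L
  ac <- data$ac

  keep_labels <- c("snp", if (include_invariable) c("invariable",
                                                    "low-signal"))
  use <- data$classification$pos[data$classification$label %in% keep_labels]
  layout <- data$windows
  ck_set <- layout$ck

  ## case 2: posterior at each window's reference site
  lpr_rc <- lapply(layout$pr_rc, log)
  ck_post <- matrix(NA_real_, nrow(layout), E1)
  for (w in seq_len(nrow(layout))) {
    llm <- ck_loglik(tree, R, e, layout$ck_counts[[w]])
    lw <- apply(llm + rep(lpr_rc[[w]], each = E1), 1L, log_sum_exp)
    ck_post[w, ] <- exp(lw - log_sum_exp(lw))
  }

  ## pair tables of all non-reference sites against their window reference
  member <- setdiff(use, ck_set)
  built <- build_pair_tables(ac, layout, member_sites = member)
  sites <- built$sites
  M <- log_prob_matrix(tree, R, e)

  pr_of_site <- function(p0) {
    cd <- ac$code_of_rank[1:2, p0 + 1L]
    cts <- ac$counts[cbind(cd, p0 + 1L)]
    if (sum(cts) == 0) c(0.5, 0.5) else cts / sum(cts)
  }

  n_out <- nrow(sites) + nrow(layout)
  post <- matrix(NA_real_, n_out, E1)
  pos_out <- integer(n_out)
  row <- 0L
  for (s in seq_len(nrow(sites))) {
    cvec <- numeric(16L)
    cvec[sites$cells[[s]] + 1L] <- sites$counts[[s]]
    ll <- M %*% cvec                       # one value per (u, v, ri, rc)
    arr <- array(ll, dim = c(2L, 2L, E1, E1))  # dims: rc, ri, v, u
    w <- match(sites$window[s], layout$window)
    lpr_ri <- log(pr_of_site(sites$pos[s]))
    add <- outer(lpr_rc[[w]], lpr_ri, "+")      # rc x ri
    lg <- log(pmax(ck_post[w, ], 1e-300))       # weight over v
    lu <- vapply(seq_len(E1), function(u) {
      x <- arr[, , , u] + as.vector(add) +
        rep(lg, each = 4L)
      log_sum_exp(x)
    }, numeric(1))
    row <- row + 1L
    post[row, ] <- exp(lu - log_sum_exp(lu))
    pos_out[row] <- sites$pos[s]
  }
  for (w in seq_len(nrow(layout))) {
    row <- row + 1L
    post[row, ] <- ck_post[w, ]
    pos_out[row] <- layout$ck[w]
  }
  colnames(post) <- c("eps", paste0("e", seq_len(E1 - 1L)))
  o <- order(pos_out)
  list(posteriors = post[o, , drop = FALSE], sites = pos_out[o],
       n_skipped = built$n_skipped)
}

#' Estimate edge lengths from per-site edge posteriors
#'
#' Two-step protocol: after the topology, abundances and error rate are
#' fitted, the length of each edge is the normalised total posterior mass of
#' mutations assigned to it across sites, including the "no mutation"
#' component — so all lengths sum to 1.  Lengths never feed back into the
#' topology inference.
#'
#' @inheritParams site_edge_posteriors
#' @return an object of class `edge_lengths`: list with `lengths` (named
#'   vector over `eps, e1..e2n-2`, summing to 1), `table` (tibble: edge,
#'   clade, length), `tree` (the input tree with `edge.length` set to the
#'   per-edge lengths), `n_sites`, `n_skipped`.
#' @export
estimate_lengths <- function(data, tree, R, e, include_invariable = TRUE) {
  tree <- as_rooted_tree(tree)
  sp <- site_edge_posteriors(data, tree, R, e,
                             include_invariable = include_invariable)
  tot <- colSums(sp$posteriors)
  len <- tot / sum(tot)
  phy <- tree$phy
  phy$edge.length <- unname(len[-1L])   # postorder edge u = row u
  clades <- vapply(seq_len(tree$n_edges), function(u) {
    paste(sort(tip_clade(tree, u)), collapse = ",")
  }, character(1))
  structure(
    list(lengths = len,
         table = tibble::tibble(edge = c(0L, seq_len(tree$n_edges)),
                                clade = c("(none)", clades),
                                length = unname(len)),
         tree = phy,
         n_sites = nrow(sp$posteriors),
         n_skipped = sp$n_skipped),
    class = "edge_lengths"
  )
}

#' @export
print.edge_lengths <- function(x, ...) {
  cat("<edge_lengths> ", length(x$lengths) - 1L, " edges + no-mutation, ",
      x$n_sites, " sites scored\n", sep = "")
  print(x$table, n = Inf)
  invisible(x)
}

#' True edge-length proportions of a simulated tree
#'
#' Converts branch lengths in substitutions/site into the proportion scale
#' of [estimate_lengths()]: each edge's share of the expected mutations, and
#' a "no mutation" share of `1 - sum(branch lengths)` reflecting the
#' invariable fraction (valid for the short trees the infinite-sites model
#' assumes).
#'
#' @param tree a `phylo`/`rooted_tree` with branch lengths.
#' @return named vector `c(eps, e1..e2n-2)` over post-order edges, sums to 1.
#' @export
true_length_proportions <- function(tree) {
  tree <- as_rooted_tree(tree)
  bl <- tree$phy$edge.length
  if (is.null(bl)) stop("tree has no branch lengths")
  eps <- max(0, 1 - sum(bl))
  out <- c(eps, bl)
  names(out) <- c("eps", paste0("e", seq_along(bl)))
  out / sum(out)
}

## per-edge masses keyed by the unrooted split (tip set through `map`),
## with the two root-child edges pooled onto their shared split
split_masses <- function(tree, masses, map = NULL) {
  tree <- as_rooted_tree(tree)
  masses <- unname(masses)
  labs <- tree$tip_labels
  if (!is.null(map)) labs <- unname(map[labs])
  out <- new.env()
  for (u in seq_len(tree$n_edges)) {
    side <- sort(labs[tree$clades[u, ]])
    other <- sort(labs[!tree$clades[u, ]])
    k1 <- paste(side, collapse = "\r"); k2 <- paste(other, collapse = "\r")
    key <- if (k1 < k2) k1 else k2
    out[[key]] <- (out[[key]] %||% 0) + masses[u]
  }
  unlist(as.list(out))
}

#' Root-mean-square edge-length error against the truth
#'
#' Compares estimated edge-length proportions with
#' [true_length_proportions()] of the simulated tree, on unrooted edges
#' (the two root-child edges of each tree are pooled onto their shared
#' split) plus the no-mutation component, under a tip pairing from
#' [evaluate_estimate()].
#'
#' @param est an `edge_lengths` object.
#' @param est_tree the fitted tree the lengths refer to.
#' @param true_tree simulated tree with branch lengths.
#' @param pairing tibble with columns `est_tip`, `true_tip` (from
#'   [evaluate_estimate()]); identity by default.
#' @return RMS difference (numeric scalar).
#' @export
rms_edge_lengths <- function(est, est_tree, true_tree, pairing = NULL) {
  stopifnot(inherits(est, "edge_lengths"))
  est_tree <- as_rooted_tree(est_tree)
  true_tree <- as_rooted_tree(true_tree)
  map <- if (is.null(pairing)) {
    stats::setNames(est_tree$tip_labels, est_tree$tip_labels)
  } else {
    stats::setNames(pairing$true_tip, pairing$est_tip)
  }
  em <- split_masses(est_tree, est$lengths[-1L], map = map)
  tru <- true_length_proportions(true_tree)
  tm <- split_masses(true_tree, tru[-1L])
  getk <- function(v, k) if (k %in% names(v)) v[[k]] else 0
  keys <- union(names(em), names(tm))
  ev <- c(est$lengths[["eps"]], vapply(keys, getk, numeric(1), v = em))
  tv <- c(tru[["eps"]], vapply(keys, getk, numeric(1), v = tm))
  sqrt(mean((ev - tv)^2))
}
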