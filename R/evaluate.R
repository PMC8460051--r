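## adjacency list of the unrooted version of a rooted tree; node labels are
## "t:<tip label>" for tips and internal ids otherwise
unrooted_adjacency <- function(tree) {
  tree <- as_rooted_tree(tree)
  phy <- ape::unroot(tree$phy)
  n <- length(phy$tip.label)
  m <- n + phy$Nnode
  adj <- vector("list", m)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1L]; b <- phy$edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  list(adj = adj, n_tips = n, tip_labels = phy$tip.label)
}

## all tip bijections t1 -> t2 under which the unrooted topologies are
## identical; each element is a named character vector (names: t1 tips)
enumerate_isomorphisms <- function(t1, t2) {
  A <- unrooted_adjacency(t1)
  B <- unrooted_adjacency(t2)
  if (A$n_tips != B$n_tips) return(list())

  rec <- function(a, pa, b, pb) {
    ka <- setdiff(A$adj[[a]], pa)
    kb <- setdiff(B$adj[[b]], pb)
    if (length(ka) != length(kb)) return(NULL)
    if (length(ka) == 0L) {                      # both leaves
      return(list(stats::setNames(B$tip_labels[b], A$tip_labels[a])))
    }
    if (length(ka) != 2L) return(NULL)
    out <- list()
    for (perm in list(c(1L, 2L), c(2L, 1L))) {
      l1 <- rec(ka[1L], a, kb[perm[1L]], b)
      if (is.null(l1)) next
      l2 <- rec(ka[2L], a, kb[perm[2L]], b)
      if (is.null(l2)) next
      for (x in l1) for (y in l2) out <- c(out, list(c(x, y)))
    }
    if (length(out)) out else NULL
  }

  anchor_a <- 1L                                  # first tip of t1
  na <- A$adj[[anchor_a]][1L]
  maps <- list()
  for (anchor_b in seq_len(B$n_tips)) {
    nb <- B$adj[[anchor_b]][1L]
    sub <- rec(na, anchor_a, nb, anchor_b)
    if (is.null(sub)) next
    for (m in sub) {
      maps <- c(maps, list(c(stats::setNames(B$tip_labels[anchor_b],
                                             A$tip_labels[anchor_a]), m)))
    }
  }
  maps
}

#' Score an estimated tree and abundances against the truth
#'
#' Searches all tip pairings under which the estimated and true unrooted
#' topologies are identical, and among them returns the pairing minimising
#' the root-mean-square abundance difference.  The estimate is *correct*
#' when such a pairing exists with every per-tip abundance difference below
#' `threshold`.
#'
#' @param est_tree,true_tree `rooted_tree`/`phylo` objects (tip labels of
#'   the two trees are unrelated; estimated tips are typically `T1..Tn`).
#' @param est_R,true_R abundance vectors named by the respective tip labels.
#' @param threshold per-tip abundance tolerance for correctness
#'   (default 0.01).
#' @return an object of class `pool_eval`: list with `correct`, `reason`,
#'   `rms_abundance`, `max_abs_delta`, `n_isomorphisms` and `pairing`
#'   (tibble: `est_tip`, `true_tip`, `est_R`, `true_R`, `delta`).
#' @export
evaluate_estimate <- function(est_tree, est_R, true_tree, true_R,
                              threshold = 0.01) {
  est_tree <- as_rooted_tree(est_tree)
  true_tree <- as_rooted_tree(true_tree)
  if (est_tree$n_tips != true_tree$n_tips) {
    return(structure(list(
      correct = FALSE,
      reason = sprintf("tip count mismatch: estimated %d vs true %d",
                       est_tree$n_tips, true_tree$n_tips),
      rms_abundance = NA_real_, max_abs_delta = NA_real_,
      n_isomorphisms = 0L, pairing = NULL), class = "pool_eval"))
  }
  stopifnot(setequal(names(est_R), est_tree$tip_labels),
            setequal(names(true_R), true_tree$tip_labels))
  maps <- enumerate_isomorphisms(est_tree, true_tree)
  if (!length(maps)) {
    return(structure(list(
      correct = FALSE, reason = "unrooted topologies differ",
      rms_abundance = NA_real_, max_abs_delta = NA_real_,
      n_isomorphisms = 0L, pairing = NULL), class = "pool_eval"))
  }
  best <- NULL; best_rms <- Inf
  for (m in maps) {
    delta <- unname(est_R[names(m)] - true_R[unname(m)])
    rms <- sqrt(mean(delta^2))
    if (rms < best_rms) {
      best_rms <- rms
      best <- tibble::tibble(est_tip = names(m), true_tip = unname(m),
                             est_R = unname(est_R[names(m)]),
                             true_R = unname(true_R[unname(m)]),
                             delta = delta)
    }
  }
  ok <- all(abs(best$delta) < threshold)
  structure(list(
    correct = ok,
    reason = if (ok) "topology and abundances match" else
      "topologies identical but abundance difference exceeds threshold",
    rms_abundance = best_rms,
    max_abs_delta = max(abs(best$delta)),
    n_isomorphisms = length(maps),
    pairing = best), class = "pool_eval")
}

#' @export
print.pool_eval <- function(x, ...) {
  cat("<pool_eval> correct: ", x$correct, " (", x$reason, ")\n", sep = "")
  if (!is.null(x$pairing)) {
    cat("  RMS abundance difference: ", signif(x$rms_abundance, 4),
        "; max |delta|: ", signif(x$max_abs_delta, 4),
        "; tip pairings considered: ", x$n_isomorphisms, "\n", sep = "")
  }
  invisible(x)
}
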