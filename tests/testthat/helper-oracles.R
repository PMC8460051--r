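# Independent brute-force oracles shared by the unit and acceptance suites.
# Each oracle recomputes the target quantity from first principles
# (explicit tip enumeration, factorials, permutations) without touching the
# implementation paths it checks.

# all 4x4 count tables with total at most `nmax`, as rows of a matrix
all_count_tables <- function(nmax, cells = 16L) {
  rec <- function(k, m) {
    if (m == 1L) return(matrix(0:k, ncol = 1L))
    out <- lapply(0:k, function(first) {
      rest <- rec(k - first, m - 1L)
      cbind(first, rest[rowSums(rest) <= k - first, , drop = FALSE])
    })
    do.call(rbind, out)
  }
  tab <- rec(nmax, cells)
  tab[rowSums(tab) <= nmax, , drop = FALSE]
}

# window likelihood by direct enumeration over (v, r_ck, u, r_i): pattern
# tables from an explicit tip loop, multinomial mass from dmultinom, the
# displayed max/sum structure applied literally.  Single-site windows.
oracle_window_ll <- function(tab, tree, R, e, pr_r, pr_rc) {
  E <- tree$n_edges
  psi <- function(from, to) if (from == to) 1 - e else e / 3
  noisy_tab <- function(u, v, ri, rj) {
    out <- matrix(0, 4, 4)
    for (p in 0:3) for (q in 0:3) {
      s <- 0
      for (p1 in 0:1) for (q1 in 0:1) {
        cl <- 0
        for (t in seq_len(tree$n_tips)) {
          pt <- if (u > 0 && tree$clades[u, t]) 1 - ri else ri
          qt <- if (v > 0 && tree$clades[v, t]) 1 - rj else rj
          if (pt == p1 && qt == q1) cl <- cl + R[t]
        }
        s <- s + cl * psi(p1, p) * psi(q1, q)
      }
      out[p + 1, q + 1] <- s
    }
    out
  }
  best_v <- -Inf
  for (v in 0:E) {
    tot_rc <- 0
    for (rc in 0:1) {
      best_u <- -Inf
      for (u in 0:E) {
        s_ri <- 0
        for (ri in 0:1) {
          probs <- noisy_tab(u, v, ri, rc)
          lik <- dmultinom(as.vector(t(tab)), prob = as.vector(t(probs)))
          s_ri <- s_ri + lik * pr_r[ri + 1]
        }
        if (log(s_ri) > best_u) best_u <- log(s_ri)
      }
      tot_rc <- tot_rc + exp(best_u) * pr_rc[rc + 1]
    }
    if (log(tot_rc) > best_v) best_v <- log(tot_rc)
  }
  best_v
}

# correctness evaluation by exhaustive search over all tip-label
# permutations (n <= 7)
brute_force_eval <- function(est_tree, est_R, true_tree, true_R,
                             threshold = 0.01) {
  est_tree <- as_rooted_tree(est_tree)
  true_tree <- as_rooted_tree(true_tree)
  tipsA <- est_tree$tip_labels; tipsB <- true_tree$tip_labels
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  best_rms <- Inf; found <- FALSE; best_ok <- FALSE
  for (p in perms(tipsB)) {
    map <- stats::setNames(p, tipsA)
    if (!unrooted_equal(est_tree, true_tree, map)) next
    found <- TRUE
    delta <- unname(est_R[tipsA] - true_R[p])
    rms <- sqrt(mean(delta^2))
    if (rms < best_rms) {
      best_rms <- rms
      best_ok <- all(abs(delta) < threshold)
    }
  }
  list(found = found, rms = best_rms, correct = found && best_ok)
}
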