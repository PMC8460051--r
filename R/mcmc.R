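## ---- proposal kernels on the light struct representation ------------------

## collect all nodes in the subtree rooted at x (x included)
descendants <- function(st, x) {
  out <- x
  stack <- x
  while (length(stack)) {
    node <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    kids <- st$children[, node]
    kids <- kids[kids != 0L]
    out <- c(out, kids)
    stack <- c(stack, kids)
  }
  out
}

## nearest-neighbour interchange: swap a nephew with its uncle across an
## internal edge; 2(n-2) possible moves on every topology, so symmetric
nni_struct <- function(st) {
  internal <- which(st$parent != 0L & st$children[1L, ] != 0L)
  if (!length(internal)) return(NULL)
  c_node <- internal[[sample.int(length(internal), 1L)]]
  p <- st$parent[c_node]
  s <- setdiff(st$children[, p], c_node)
  g <- st$children[sample.int(2L, 1L), c_node]
  st$children[st$children[, p] == s, p] <- g
  st$children[st$children[, c_node] == g, c_node] <- s
  st$parent[g] <- p
  st$parent[s] <- c_node
  st
}

## rooted subtree prune-and-regraft; prune/regraft choices are counted so
## that forward and reverse proposals are equally likely (Hastings ratio 1)
spr_struct <- function(st) {
  par <- st$parent
  cand <- which(par != 0L)
  cand <- cand[par[par[cand]] != 0L]
  if (!length(cand)) return(NULL)
  x <- cand[[sample.int(length(cand), 1L)]]
  p <- par[x]; pp <- par[p]
  s <- setdiff(st$children[, p], x)
  ## detach: pp adopts s, p floats
  st$children[st$children[, pp] == p, pp] <- s
  st$parent[s] <- pp
  sub <- descendants(st, x)
  targets <- which(st$parent != 0L)
  targets <- setdiff(targets, c(sub, p))
  d <- if (length(targets) == 1L) targets else
    targets[[sample.int(length(targets), 1L)]]
  dp <- st$parent[d]
  st$children[st$children[, dp] == d, dp] <- p
  st$parent[p] <- dp
  st$children[, p] <- c(x, d)
  st$parent[d] <- p
  st$parent[x] <- p
  st
}

## transfer mass between two tips; symmetric.  The step width is a mixture
## of a fine scale (local refinement) and a coarse scale (0.3), which lets
## the chain hop between abundance modes separated by likelihood valleys
## (sites re-assign their mutation edges discontinuously as clade masses
## cross, so the marginal posterior of R is multimodal).
exchange_R <- function(R, width) {
  ij <- sample.int(length(R), 2L)
  w <- if (stats::runif(1L) < 0.7) width else 0.3
  delta <- stats::runif(1L, -w, w)
  R[ij[1L]] <- R[ij[1L]] + delta
  R[ij[2L]] <- R[ij[2L]] - delta
  R
}

ldirichlet <- function(x, alpha) {
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

## Dirichlet proposal centred on the current abundances
dirichlet_R <- function(R, conc) {
  alpha <- conc * R
  g <- stats::rgamma(length(R), shape = alpha)
  if (any(g <= 0) || sum(g) <= 0) return(NULL)
  R2 <- g / sum(g)
  lhr <- ldirichlet(R, conc * R2) - ldirichlet(R2, alpha)
  list(R = R2, lhr = lhr)
}

## sliding window on the error rate with reflection at the support bounds
slide_e <- function(e, width, e_max) {
  e2 <- e + stats::runif(1L, -width, width)
  if (e2 < 0) e2 <- -e2
  if (e2 > e_max) e2 <- 2 * e_max - e2
  if (e2 < 0 || e2 > e_max) return(e)   # width > e_max: fold back once more
  e2
}

default_weights <- c(nni = 0.22, spr = 0.10, exchange = 0.25,
                     dirichlet = 0.15, swap = 0.15, error = 0.13)
default_tuning <- list(exchange_width = 0.01, e_width = 0.002,
                       dirichlet_conc = 1000)

#' Propose a new sampler state
#'
#' Draws one of six kernels by weight — topology NNI, rooted subtree
#' prune-and-regraft, pairwise abundance mass exchange, a Dirichlet proposal
#' on the abundance vector, an abundance swap between two tips (a mode-jump
#' between tip relabellings), or a reflected sliding-window move on the
#' error rate — and returns the candidate state with its log Hastings
#' ratio.  All kernels except the Dirichlet one are symmetric.
#'
#' @param state list with elements `tree` (a `rooted_tree`), `R`
#'   (abundances) and `e` (error rate).
#' @param weights named kernel weights (see `default_weights`).
#' @param tuning list with `exchange_width`, `e_width`, `dirichlet_conc`.
#' @param e_max error-rate support bound (default 0.01).
#' @return list with `state` (same shape as the input), `log_hastings`
#'   and `kernel`.
#' @export
propose_move <- function(state, weights = default_weights,
                         tuning = default_tuning, e_max = 0.01) {
  st <- tree_to_struct(state$tree)
  out <- propose_struct(list(st = st, R = state$R, e = state$e),
                        weights, tuning, e_max)
  tr <- as_rooted_tree(struct_to_phylo(out$st))
  list(state = list(tree = tr, R = out$R, e = out$e),
       log_hastings = out$lhr, kernel = out$kernel)
}

## internal version working on structs; returns st/R/e + lhr + kernel;
## moved = "topology"/"R"/"e" lets the caller avoid clade rebuilds
propose_struct <- function(chain, weights, tuning, e_max) {
  kernel <- sample(names(weights), 1L, prob = weights)
  st <- chain$st; R <- chain$R; e <- chain$e
  lhr <- 0
  moved <- "none"
  if (kernel == "nni") {
    st2 <- nni_struct(st)
    if (!is.null(st2)) { st <- st2; moved <- "topology" }
  } else if (kernel == "spr") {
    st2 <- spr_struct(st)
    if (!is.null(st2)) { st <- st2; moved <- "topology" }
  } else if (kernel == "exchange") {
    R <- exchange_R(R, tuning$exchange_width)
    moved <- "R"
  } else if (kernel == "swap") {
    ij <- sample.int(length(R), 2L)
    R[ij] <- R[rev(ij)]
    moved <- "R"
  } else if (kernel == "dirichlet") {
    d <- dirichlet_R(R, tuning$dirichlet_conc)
    if (!is.null(d)) { R <- d$R; lhr <- d$lhr; moved <- "R" }
  } else if (kernel == "error") {
    e <- slide_e(e, tuning$e_width, e_max)
    moved <- "e"
  }
  list(st = st, R = R, e = e, lhr = lhr, kernel = kernel, moved = moved)
}

#' Attempt one state swap between adjacent tempered chains
#'
#' A uniformly chosen adjacent temperature pair exchanges complete states
#' with probability `min(1, exp((beta_a - beta_b) * (logP_b - logP_a)))`,
#' the standard Metropolis-coupling acceptance ratio.
#'
#' @param states list of chain states; each must carry a `log_posterior`
#'   element (the cold-scale, untempered value).
#' @param betas numeric vector of inverse temperatures, one per chain
#'   (position 1 is the cold chain).
#' @return list with `states` (possibly with two entries exchanged),
#'   `pair` (the two chain indices) and `swapped` (logical).
#' @export
swap_chains <- function(states, betas) {
  K <- length(states)
  stopifnot(length(betas) == K)
  if (K < 2L) return(list(states = states, pair = NULL, swapped = FALSE))
  a <- sample.int(K - 1L, 1L)
  b <- a + 1L
  la <- states[[a]]$log_posterior
  lb <- states[[b]]$log_posterior
  lacc <- (betas[a] - betas[b]) * (lb - la)
  swapped <- FALSE
  if (!is.nan(lacc)) {
    swapped <- if (lacc >= 0) TRUE else log(stats::runif(1L)) < lacc
  }
  if (swapped) {
    tmp <- states[[a]]; states[[a]] <- states[[b]]; states[[b]] <- tmp
  }
  list(states = states, pair = c(a, b), swapped = swapped)
}

## spectrum-informed starting abundances: centres of the most populated
## SNP-ratio classes, jittered with a Dirichlet draw
init_abundances <- function(data, n_tips, jitter = 0.3) {
  pr <- data$sites[["pr_r"]] %||% list()
  ratios <- vapply(pr, function(p) min(p), numeric(1))
  ratios <- ratios[ratios > 0 & ratios <= 0.5]
  cand <- NULL
  if (length(ratios) >= n_tips) {
    spec <- snp_spectrum(ratios)
    spec <- spec[order(-spec$n_sites), ]
    if (nrow(spec) >= n_tips) cand <- spec$ratio[seq_len(n_tips)]
  }
  if (is.null(cand)) cand <- stats::rexp(n_tips)
  cand <- cand / sum(cand)
  g <- stats::rgamma(n_tips, 1)
  R0 <- (1 - jitter) * cand + jitter * g / sum(g)
  R0 <- pmax(R0, 1e-4)
  R0 / sum(R0)
}

#' Metropolis-coupled MCMC over topology, abundances and error rate
#'
#' Samples the posterior of `(T, R, e)` given preprocessed pair-pattern data
#' with one cold chain and `n_chains - 1` heated chains (inverse
#' temperatures `1 / (1 + lambda * k)`).  Within-chain updates use
#' [propose_move()]'s kernels against the tempered posterior; every
#' `swap_every` iterations an adjacent pair attempts a state swap
#' ([swap_chains()]).  The cold chain is recorded every `thin` iterations,
#' and the maximum-posterior state seen on the cold chain is reported as the
#' estimate.  Runs are fully reproducible given `seed`.
#'
#' @param data a `pooldata` object.
#' @param n_tips known number of haplotypes.
#' @param iterations iterations per chain.
#' @param n_chains number of coupled chains (default 8).
#' @param thin cold-chain recording interval (default 100).
#' @param seed RNG seed.
#' @param lambda temperature spacing (default 0.1).
#' @param swap_every swap attempt interval (default 10).
#' @param weights,tuning kernel weights and tuning constants
#'   (see [propose_move()]).
#' @param e_max error-rate prior bound (defaults to the preprocessing value).
#' @param init optional list(`tree`, `R`, `e`) initial state; by default a
#'   random topology, spectrum-informed jittered abundances and `e = 0.005`.
#' @param prior_only if `TRUE` the likelihood is held at a constant so the
#'   sampler explores the prior (used to validate the kernels).
#' @return an object of class `poolphylo_fit` with elements `trace`
#'   (tibble), `map` (list: `tree`, `R`, `e`, `log_posterior`, `iteration`),
#'   `acceptance`, `swaps`, `config`.
#' @export
run_mcmcmc <- function(data, n_tips, iterations = 10000, n_chains = 8,
                       thin = 100, seed = NULL, lambda = 0.1,
                       swap_every = 10, weights = default_weights,
                       tuning = default_tuning, e_max = NULL, init = NULL,
                       prior_only = FALSE) {
  stopifnot(n_tips >= 3)
  if (!prior_only && nrow(data$sites) == 0L) {
    stop("no usable windows/site pairs in the data")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(e_max)) e_max <- data$params$e_max %||% 0.01
  weights <- weights / sum(weights)
  betas <- 1 / (1 + lambda * (seq_len(n_chains) - 1L))
  cp <- data$cpp
  lprior_const <- lgamma(n_tips) - log(e_max)

  loglik <- function(clades, R, e) {
    if (prior_only) return(0)
    cpp_alignment_loglik(clades, R, e, cp$site_window, cp$main_off,
                         cp$main_code, cp$main_cnt, cp$err_i, cp$err_c,
                         cp$err_both, cp$lpr_ri, cp$lpr_rc,
                         cp$n_windows) + cp$const_total
  }
  clades_of <- function(st) {
    m <- rbind(FALSE, struct_clades(st))
    storage.mode(m) <- "integer"
    m
  }

  make_state <- function() {
    for (try in 1:20) {
      st <- random_struct(n_tips)
      R <- if (!is.null(init$R)) init$R else init_abundances(data, n_tips)
      if (!is.null(init$tree)) st <- tree_to_struct(init$tree)
      e <- init$e %||% 0.005
      cl <- clades_of(st)
      ll <- loglik(cl, R, e)
      if (is.finite(ll)) {
        return(list(st = st, clades = cl, R = R, e = e, ll = ll,
                    log_posterior = ll + lprior_const, tver = 0L))
      }
    }
    stop("could not find an initial state with finite posterior")
  }
  chains <- lapply(seq_len(n_chains), function(k) make_state())

  n_rec <- iterations %/% thin
  trace <- list(
    iteration = integer(n_rec), log_posterior = numeric(n_rec),
    log_likelihood = numeric(n_rec), e = numeric(n_rec),
    newick = character(n_rec),
    R = matrix(NA_real_, n_rec, n_tips,
               dimnames = list(NULL, paste0("T", seq_len(n_tips))))
  )
  rec <- 0L
  map <- list(log_posterior = -Inf)
  tver_counter <- 0L
  last_tver <- -1L
  last_newick <- ""
  prop_n <- acc_n <- stats::setNames(numeric(length(weights)),
                                     names(weights))
  swap_try <- swap_ok <- 0L

  for (it in seq_len(iterations)) {
    for (k in seq_len(n_chains)) {
      ch <- chains[[k]]
      cand <- propose_struct(ch, weights, tuning, e_max)
      prop_n[cand$kernel] <- prop_n[cand$kernel] + 1
      ok_support <- all(cand$R > 0) && cand$e >= 0 && cand$e <= e_max
      if (ok_support) {
        cl <- if (cand$moved == "topology") clades_of(cand$st) else ch$clades
        ll <- loglik(cl, cand$R, cand$e)
        lacc <- betas[k] * (ll - ch$ll) + cand$lhr
        if (is.finite(lacc) && (lacc >= 0 || log(stats::runif(1L)) < lacc)) {
          tv <- ch$tver
          if (cand$moved == "topology") {
            tver_counter <- tver_counter + 1L
            tv <- tver_counter
          }
          chains[[k]] <- list(st = cand$st, clades = cl, R = cand$R,
                              e = cand$e, ll = ll,
                              log_posterior = ll + lprior_const,
                              tver = tv)
          acc_n[cand$kernel] <- acc_n[cand$kernel] + 1
        }
      }
    }
    if (n_chains > 1L && it %% swap_every == 0L) {
      sw <- swap_chains(chains, betas)
      chains <- sw$states
      swap_try <- swap_try + 1L
      swap_ok <- swap_ok + as.integer(sw$swapped)
    }
    cold <- chains[[1L]]
    if (cold$log_posterior > map$log_posterior) {
      map <- list(tree = cold$st, R = cold$R, e = cold$e,
                  log_posterior = cold$log_posterior, iteration = it)
    }
    if (it %% thin == 0L) {
      rec <- rec + 1L
      trace$iteration[rec] <- it
      trace$log_posterior[rec] <- cold$log_posterior
      trace$log_likelihood[rec] <- cold$ll
      trace$e[rec] <- cold$e
      if (cold$tver != last_tver) {
        last_newick <- write_newick(struct_to_phylo(cold$st))
        last_tver <- cold$tver
      }
      trace$newick[rec] <- last_newick
      trace$R[rec, ] <- cold$R
    }
  }

  trace_tb <- tibble::tibble(
    iteration = trace$iteration,
    log_posterior = trace$log_posterior,
    log_likelihood = trace$log_likelihood,
    e = trace$e
  )
  trace_tb <- dplyr::bind_cols(trace_tb, tibble::as_tibble(trace$R))
  trace_tb$newick <- trace$newick

  map_tree <- struct_to_phylo(map$tree)
  structure(
    list(trace = trace_tb,
         map = list(tree = map_tree,
                    R = stats::setNames(map$R, map_tree$tip.label),
                    e = map$e, log_posterior = map$log_posterior,
                    iteration = map$iteration),
         acceptance = tibble::tibble(kernel = names(weights),
                                     proposed = as.integer(prop_n),
                                     accepted = as.integer(acc_n),
                                     rate = ifelse(prop_n > 0,
                                                   acc_n / prop_n, NA)),
         swaps = list(attempted = swap_try, accepted = swap_ok),
         config = list(iterations = iterations, n_chains = n_chains,
                       thin = thin, seed = seed, lambda = lambda,
                       swap_every = swap_every, weights = weights,
                       tuning = tuning, e_max = e_max,
                       prior_only = prior_only),
         n_tips = n_tips),
    class = "poolphylo_fit"
  )
}

#' @export
print.poolphylo_fit <- function(x, ...) {
  cat("<poolphylo_fit> ", x$n_tips, " tips, ", x$config$iterations,
      " iterations x ", x$config$n_chains, " chains\n", sep = "")
  cat("  MAP log posterior ", format(x$map$log_posterior),
      " at iteration ", x$map$iteration, "; e_hat = ",
      signif(x$map$e, 4), "\n", sep = "")
  cat("  MAP tree: ", write_newick(x$map$tree), "\n", sep = "")
  cat("  MAP abundances: ",
      paste(sprintf("%s=%.4f", names(x$map$R), x$map$R), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
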