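# Sampler correctness: proposal kernels, Metropolis coupling, prior
# recovery, reproducibility, and a single-condition parameter-recovery
# smoke test (the replicated recovery study lives in the acceptance suite).

toy_state <- function(n = 5) {
  tr <- as_rooted_tree(ape::rtree(n))
  list(tree = tr, R = stats::setNames(rep(1 / n, n), tr$tip_labels),
       e = 0.005)
}

test_that("abundance kernels preserve the simplex exactly", {
  set.seed(61)
  st <- toy_state(6)
  for (i in 1:200) {
    out <- propose_move(st)
    expect_equal(sum(out$state$R), 1, tolerance = 1e-12)
    if (out$kernel %in% c("nni", "spr")) {
      expect_equal(sort(unname(out$state$R)), sort(unname(st$R)))
    }
    if (out$kernel == "swap") {
      expect_equal(sort(unname(out$state$R)), sort(unname(st$R)))
      expect_equal(out$log_hastings, 0)
    }
    if (out$kernel %in% c("nni", "spr", "exchange", "swap", "error")) {
      expect_equal(out$log_hastings, 0)
    }
  }
})

test_that("error-rate kernel reflects into the prior support", {
  set.seed(62)
  st <- toy_state(4)
  st$e <- 1e-4
  for (i in 1:200) {
    out <- propose_move(st, weights = c(error = 1), e_max = 0.01)
    expect_gte(out$state$e, 0)
    expect_lte(out$state$e, 0.01)
  }
})

test_that("topology kernels keep trees valid and NNI reaches all", {
  ## validity under repeated random moves
  set.seed(63)
  st <- poolphylo:::tree_to_struct(as_rooted_tree(ape::rtree(7)))
  for (i in 1:300) {
    st <- if (i %% 2 == 0) poolphylo:::nni_struct(st) else
      poolphylo:::spr_struct(st)
    phy <- poolphylo:::struct_to_phylo(st)
    expect_silent(as_rooted_tree(phy))
  }

  ## all 3 unrooted 4-tip topologies reachable within 2 NNI moves
  start <- poolphylo:::tree_to_struct(parse_newick("((A,B),(C,D));"))
  seen <- character(0)
  key_of <- function(s) {
    tr <- as_rooted_tree(poolphylo:::struct_to_phylo(s))
    paste(sort(poolphylo:::unrooted_split_keys(tr)), collapse = "|")
  }
  for (i in 1:200) {
    s1 <- poolphylo:::nni_struct(start)
    s2 <- poolphylo:::nni_struct(s1)
    seen <- union(seen, c(key_of(s1), key_of(s2)))
  }
  expect_equal(length(seen), 3L)
})

test_that("NNI neighbourhoods are symmetric (detailed balance support)", {
  ## t2 reachable from t1 in one move iff t1 reachable from t2, with equal
  ## multiplicity -- estimated by enumeration over repeated draws
  set.seed(64)
  start <- poolphylo:::tree_to_struct(as_rooted_tree(ape::rtree(6)))
  key_of <- function(s) {
    write_newick(as_rooted_tree(poolphylo:::struct_to_phylo(s)))
  }
  k0 <- key_of(start)
  hits <- table(vapply(1:2000, function(i) {
    key_of(poolphylo:::nni_struct(start))
  }, character(1)))
  ## pick a frequent neighbour and count reverse-move frequency
  nb_key <- names(hits)[which.max(hits)]
  nb <- poolphylo:::tree_to_struct(parse_newick(nb_key))
  back <- mean(vapply(1:2000, function(i) {
    key_of(poolphylo:::nni_struct(nb)) == k0
  }, logical(1)))
  fwd <- max(hits) / 2000
  expect_gt(back, 0)
  expect_lt(abs(fwd - back), 4 * sqrt(fwd * (1 - fwd) / 2000) + 0.02)
})

test_that("swap_chains follows the Metropolis-coupling rule", {
  set.seed(65)
  states <- lapply(c(-10, -20, -30), function(lp) list(log_posterior = lp,
                                                       id = lp))
  ## equal temperatures: always swap
  for (i in 1:50) {
    out <- swap_chains(states, betas = c(1, 1, 1))
    expect_true(out$swapped)
    ## the multiset of states is preserved
    expect_setequal(vapply(out$states, `[[`, numeric(1), "id"),
                    c(-10, -20, -30))
    states <- out$states
  }
  ## a hot chain holding a better state always passes it down
  st2 <- list(list(log_posterior = -100), list(log_posterior = -1))
  out <- swap_chains(st2, betas = c(1, 0.5))
  expect_true(out$swapped)
})

test_that("swap acceptance on a two-level toy matches the closed form", {
  ## two chains, fixed log posteriors: acceptance probability is
  ## exp((b1-b2)(lp2-lp1)) when negative
  set.seed(66)
  lp1 <- -5; lp2 <- -9; b <- c(1, 0.6)
  p_theory <- exp((b[1] - b[2]) * (lp2 - lp1))
  acc <- mean(vapply(1:20000, function(i) {
    swap_chains(list(list(log_posterior = lp1), list(log_posterior = lp2)),
                betas = b)$swapped
  }, logical(1)))
  expect_lt(abs(acc - p_theory), 4 * sqrt(p_theory * (1 - p_theory) / 20000))
})

test_that("under a constant likelihood the sampler recovers its priors", {
  toy <- list(sites = tibble::tibble(), windows = tibble::tibble(),
              params = list(e_max = 0.01))
  class(toy) <- "pooldata"
  ## error-rate marginal: uniform on [0, e_max]
  fit <- run_mcmcmc(toy, n_tips = 4, iterations = 50000, n_chains = 1,
                    thin = 5, seed = 67, prior_only = TRUE,
                    weights = c(error = 1),
                    tuning = list(exchange_width = 0.01, e_width = 0.01,
                                  dirichlet_conc = 1000))
  es <- fit$trace$e
  expect_equal(length(es), 10000L)
  set.seed(68)
  ks <- suppressWarnings(stats::ks.test(es, stats::runif(10000, 0, 0.01)))
  expect_gt(ks$p.value, 0.01)

  ## abundance marginal under exchange + swap moves: flat Dirichlet, so
  ## each component is Beta(1, n-1)
  fit2 <- run_mcmcmc(toy, n_tips = 4, iterations = 40000, n_chains = 1,
                     thin = 5, seed = 69, prior_only = TRUE,
                     weights = c(exchange = 0.8, swap = 0.2),
                     tuning = list(exchange_width = 0.2, e_width = 0.01,
                                   dirichlet_conc = 1000))
  r1 <- fit2$trace$T1
  ks2 <- suppressWarnings(
    stats::ks.test(r1, function(q) stats::pbeta(q, 1, 3)))
  expect_gt(ks2$p.value, 0.01)

  ## Dirichlet kernel (non-trivial Hastings ratio) must leave the same
  ## prior invariant
  ## longer thinning: the concentrated proposal mixes more slowly
  fit3 <- run_mcmcmc(toy, n_tips = 4, iterations = 200000, n_chains = 1,
                     thin = 50, seed = 70, prior_only = TRUE,
                     weights = c(dirichlet = 1),
                     tuning = list(exchange_width = 0.01, e_width = 0.01,
                                   dirichlet_conc = 50))
  ks3 <- suppressWarnings(
    stats::ks.test(fit3$trace$T1, function(q) stats::pbeta(q, 1, 3)))
  expect_gt(ks3$p.value, 0.01)
})

test_that("seeded runs are exactly reproducible and traces are coherent", {
  dd <- quick_sim_data(n_hap = 4, genome_length = 1200, coverage = 200,
                       error_rate = 0.002, seed = 71)
  f1 <- run_mcmcmc(dd$data, n_tips = 4, iterations = 2000, n_chains = 2,
                   thin = 50, seed = 72)
  f2 <- run_mcmcmc(dd$data, n_tips = 4, iterations = 2000, n_chains = 2,
                   thin = 50, seed = 72)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$map$R, f2$map$R)

  ## the MAP dominates every recorded posterior value
  expect_true(all(f1$trace$log_posterior <= f1$map$log_posterior))
  ## running maximum of the trace is non-decreasing
  expect_true(!is.unsorted(cummax(f1$trace$log_posterior)))
  ## tidy/glance accessors
  td <- tidy(f1)
  expect_equal(nrow(td), 4L)
  expect_equal(sum(td$estimate), 1, tolerance = 1e-9)
  gl <- glance(f1)
  expect_equal(gl$n_tips, 4L)
  expect_s3_class(autoplot(f1), "ggplot")
})

test_that("degenerate inputs fail loudly", {
  toy <- list(sites = tibble::tibble(), windows = tibble::tibble(),
              params = list(e_max = 0.01))
  class(toy) <- "pooldata"
  expect_error(run_mcmcmc(toy, n_tips = 4, iterations = 10), "no usable")
  expect_error(run_mcmcmc(toy, n_tips = 2, iterations = 10,
                          prior_only = TRUE), "n_tips")
})

test_that("the sampler recovers a known error-free 5-tip mixture", {
  ## fixed tree with all edges long enough to be informative at 3 kb
  tr <- parse_newick(
    "(A:0.03,(B:0.02,(C:0.015,(D:0.01,E:0.01):0.005):0.005):0.01);")
  sim <- simulate_mixture(
    n_hap = 5, genome_length = 3000, coverage = 600, error_rate = 0,
    abundances = c(0.05, 0.1, 0.2, 0.3, 0.35), tree = tr, seed = 73)
  paths <- write_mixture(sim, tempfile())
  data <- preprocess_alignment(paths$bam, ref = paths$ref)
  fit <- run_mcmcmc(data, n_tips = 5, iterations = 8000, n_chains = 4,
                    thin = 100, seed = 74, lambda = 0.3)
  ## at this scale the finite read pool matters: the likelihood estimates
  ## the realised haplotype fractions among the ~6000 sampled fragments
  ## (SD ~ 0.006 around the nominal abundances), so score against those
  frag <- sim$reads[sim$reads$mate == 1L, ]
  realised <- table(factor(frag$haplotype, levels = names(sim$abundances)))
  realised <- as.numeric(realised) / sum(realised)
  names(realised) <- names(sim$abundances)
  ev <- evaluate_estimate(fit$map$tree, fit$map$R, sim$tree, realised)
  expect_true(ev$correct)
  expect_lt(ev$max_abs_delta, 0.01)
})
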