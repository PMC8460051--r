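## integer clade matrix with the "no mutation" row 0 prepended, as the C++
## kernel expects
clades_eps <- function(tree) {
  cl <- if (is.matrix(tree)) tree else as_rooted_tree(tree)$clades
  m <- rbind(rep(FALSE, ncol(cl)), cl)
  storage.mode(m) <- "integer"
  m
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log likelihood of one window
#'
#' Reference-site factorisation of the pair-pattern likelihood for a single
#' window: every member SNP site is paired with the window's reference site
#' `c_k`, and the mutation edges are handled either by the default
#' max-over-edges approximation (`method = "max"`) or by summation weighted
#' with per-edge mutation probabilities (`method = "full"`, the exact variant;
#' slower and needing `edge_probs`).  Pure-R implementation built from the
#' exported pattern-model operations; the whole-alignment path uses the
#' compiled kernel instead.
#'
#' @param data a `pooldata` object from [preprocess_alignment()].
#' @param window window id (row of `data$windows`).
#' @param tree a `rooted_tree` with `n` tips (labels are not interpreted).
#' @param R tip relative abundances.
#' @param e sequencing error rate.
#' @param method `"max"` (default) or `"full"`.
#' @param edge_probs for `method = "full"`: probability of a mutation falling
#'   on each edge, length `2n-1` over `(eps, e1, ..., e_{2n-2})`; defaults to
#'   uniform.
#' @return log likelihood contribution of the window (0 if it has no usable
#'   member sites, with a warning).
#' @export
window_log_likelihood <- function(data, window, tree, R, e,
                                  method = c("max", "full"),
                                  edge_probs = NULL) {
  method <- match.arg(method)
  tree <- as_rooted_tree(tree)
  R <- check_abundances(R, tree)
  wrow <- data$windows[data$windows$window == window, ]
  if (nrow(wrow) != 1L) stop("no such window: ", window)
  sites <- data$sites[data$sites$window == window, ]
  if (nrow(sites) == 0L) {
    warning("window ", window, " has no usable member sites; contributes 0")
    return(0)
  }
  E1 <- tree$n_edges + 1L
  if (is.null(edge_probs)) edge_probs <- rep(1 / E1, E1)
  stopifnot(length(edge_probs) == E1)
  lw <- log(edge_probs)

  per_site <- function(counts, pr_r, v, rc) {
    ## for each u: lse over r_i of loglik + log Pr(r_i); then max (or
    ## weighted sum) over u
    vals_u <- vapply(0:(E1 - 1L), function(u) {
      lr <- vapply(0:1, function(ri) {
        tab <- error_convolve(
          pair_pattern_probs(tree, R, u, v, ri, rc), e, e_max = 1)
        pair_log_likelihood(counts, tab) + log(pr_r[ri + 1L])
      }, numeric(1))
      log_sum_exp(lr)
    }, numeric(1))
    if (method == "max") max(vals_u) else log_sum_exp(vals_u + lw)
  }

  vals_v <- vapply(0:(E1 - 1L), function(v) {
    by_rc <- vapply(0:1, function(rc) {
      tot <- 0
      for (s in seq_len(nrow(sites))) {
        code <- sites$cells[[s]]
        counts <- matrix(0, 4L, 4L)           # rows: rank at i, cols: at ck
        counts[cbind(code %/% 4L + 1L, code %% 4L + 1L)] <- sites$counts[[s]]
        tot <- tot + per_site(counts, sites$pr_r[[s]], v, rc)
      }
      tot + log(wrow$pr_rc[[1L]][rc + 1L])
    }, numeric(1))
    log_sum_exp(by_rc)
  }, numeric(1))
  if (method == "max") max(vals_v) else log_sum_exp(vals_v + lw)
}

#' Log likelihood of the whole alignment
#'
#' Product (sum in log space) of the per-window likelihoods.  The default
#' engine is the compiled kernel used by the sampler; `engine = "r"` runs the
#' pure-R window implementation (identical value, orders of magnitude
#' slower — useful for checking and for `method = "full"`).
#'
#' @inheritParams window_log_likelihood
#' @param engine `"cpp"` (default) or `"r"`.
#' @return total log likelihood.
#' @export
alignment_log_likelihood <- function(data, tree, R, e,
                                     engine = c("cpp", "r"),
                                     method = c("max", "full"),
                                     edge_probs = NULL) {
  engine <- match.arg(engine)
  method <- match.arg(method)
  tree <- as_rooted_tree(tree)
  R <- check_abundances(R, tree)
  if (method == "full" && engine == "cpp") engine <- "r"
  if (engine == "cpp") {
    cp <- data$cpp
    return(cpp_alignment_loglik(clades_eps(tree), R, e,
                                cp$site_window, cp$main_off, cp$main_code,
                                cp$main_cnt, cp$err_i, cp$err_c,
                                cp$err_both, cp$lpr_ri, cp$lpr_rc,
                                cp$n_windows) + cp$const_total)
  }
  tot <- 0
  for (w in data$windows$window) {
    if (!any(data$sites$window == w)) next
    tot <- tot + window_log_likelihood(data, w, tree, R, e,
                                       method = method,
                                       edge_probs = edge_probs)
  }
  ## pure-R path: window_log_likelihood includes multinomial coefficients
  ## through pair_log_likelihood already
  tot
}

#' Unnormalised log posterior
#'
#' Likelihood plus log priors: uniform over rooted topologies, flat
#' Dirichlet(1, ..., 1) over abundances, uniform over `[0, e_max]` for the
#' error rate.  Outside the prior support the value is `-Inf`.
#'
#' @inheritParams alignment_log_likelihood
#' @param e_max upper bound of the error-rate prior (defaults to the value
#'   used during preprocessing).
#' @return unnormalised log posterior.
#' @export
log_posterior <- function(data, tree, R, e, e_max = NULL,
                          engine = c("cpp", "r")) {
  if (is.null(e_max)) e_max <- data$params$e_max %||% 0.01
  if (e < 0 || e > e_max) return(-Inf)
  if (any(R <= 0) || abs(sum(R) - 1) > 1e-8) return(-Inf)
  ll <- alignment_log_likelihood(data, tree, R, e, engine = match.arg(engine))
  ll + lgamma(length(R)) - log(e_max)
}

## flatten the tabular pair-count representation into the arrays the C++
## kernel consumes; called once at the end of preprocessing
build_cpp_data <- function(sites, windows) {
  win_index <- match(sites$window, windows$window) - 1L
  n <- nrow(sites)
  ## decompose each 4x4 count table by rank class: main cells (both ranks
  ## in {0,1}, stored as code p*2+q), counts with an error rank at exactly
  ## one of the two sites (grouped by the non-error rank), and counts with
  ## error ranks at both
  main_code <- vector("list", n)
  main_cnt <- vector("list", n)
  err_i <- matrix(0, 2L, max(n, 1L))
  err_c <- matrix(0, 2L, max(n, 1L))
  err_both <- numeric(max(n, 1L))
  for (s in seq_len(n)) {
    code <- sites$cells[[s]]
    cnt <- sites$counts[[s]]
    p <- code %/% 4L
    q <- code %% 4L
    main <- p <= 1L & q <= 1L
    main_code[[s]] <- as.integer(p[main] * 2L + q[main])
    main_cnt[[s]] <- cnt[main]
    ei <- p <= 1L & q >= 2L
    for (pp in 0:1) err_i[pp + 1L, s] <- sum(cnt[ei & p == pp])
    ec <- p >= 2L & q <= 1L
    for (qq in 0:1) err_c[qq + 1L, s] <- sum(cnt[ec & q == qq])
    err_both[s] <- sum(cnt[p >= 2L & q >= 2L])
  }
  nnz <- lengths(main_code)
  cpp <- list(
    site_window = as.integer(win_index),
    main_off = as.integer(c(0L, cumsum(nnz))),
    main_code = as.integer(unlist(main_code, use.names = FALSE)),
    main_cnt = as.numeric(unlist(main_cnt, use.names = FALSE)),
    err_i = err_i[, seq_len(max(n, 1L)), drop = FALSE],
    err_c = err_c[, seq_len(max(n, 1L)), drop = FALSE],
    err_both = err_both,
    lpr_ri = {
      m <- vapply(sites$pr_r, function(p) log(p), numeric(2))
      if (is.null(dim(m))) m <- matrix(m, nrow = 2L)
      m
    },
    lpr_rc = {
      m <- vapply(windows$pr_rc, function(p) log(p), numeric(2))
      if (is.null(dim(m))) m <- matrix(m, nrow = 2L)
      m
    },
    n_windows = nrow(windows),
    const_total = sum(sites$lconst)
  )
  if (n == 0L) {
    cpp$lpr_ri <- matrix(numeric(0), nrow = 2L)
    cpp$err_i <- cpp$err_c <- matrix(numeric(0), nrow = 2L)
    cpp$err_both <- numeric(0)
    cpp$const_total <- 0
  }
  cpp
}
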