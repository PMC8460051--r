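#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted mixture model
#'
#' One row per tip: the maximum-posterior abundance estimate together with
#' the posterior mean and standard deviation over the recorded cold-chain
#' trace (burn-in removed).
#'
#' @param x a `poolphylo_fit`.
#' @param burn_in fraction of the trace discarded as burn-in (default 0.5).
#' @param ... unused.
#' @return tibble with columns `tip`, `estimate`, `posterior_mean`,
#'   `posterior_sd`.
#' @export
tidy.poolphylo_fit <- function(x, burn_in = 0.5, ...) {
  tips <- paste0("T", seq_len(x$n_tips))
  keep <- x$trace$iteration > burn_in * max(x$trace$iteration)
  tr <- x$trace[keep, tips, drop = FALSE]
  ## abundances are exchangeable across relabellings of the sampled trees;
  ## summarise each trace column as recorded (tips are anonymous anyway)
  tibble::tibble(
    tip = tips,
    estimate = unname(x$map$R[tips]),
    posterior_mean = vapply(tr, mean, numeric(1)),
    posterior_sd = vapply(tr, stats::sd, numeric(1))
  )
}

#' One-row summary of a fitted mixture model
#'
#' @param x a `poolphylo_fit`.
#' @param ... unused.
#' @return tibble with the MAP log posterior, error-rate estimate, sampler
#'   dimensions and swap acceptance.
#' @export
glance.poolphylo_fit <- function(x, ...) {
  tibble::tibble(
    n_tips = x$n_tips,
    log_posterior = x$map$log_posterior,
    e_hat = x$map$e,
    map_iteration = x$map$iteration,
    iterations = x$config$iterations,
    n_chains = x$config$n_chains,
    swap_rate = if (x$swaps$attempted > 0)
      x$swaps$accepted / x$swaps$attempted else NA_real_
  )
}

#' Trace plot of the cold chain
#'
#' @param object a `poolphylo_fit`.
#' @param ... unused.
#' @return a ggplot: log posterior against iteration.
#' @export
autoplot.poolphylo_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration,
                               y = .data$log_posterior)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "iteration", y = "log posterior",
                  title = "Cold-chain trace") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a SNP-ratio spectrum
#'
#' @param spectrum a tibble from [snp_spectrum()].
#' @return a ggplot: class frequency against SNP ratio.
#' @export
plot_snp_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = .data$ratio, y = .data$frequency)) +
    ggplot2::geom_col(width = 0.004, fill = "grey30") +
    ggplot2::labs(x = "SNP ratio (minor-pattern proportion)",
                  y = "SNP frequency") +
    ggplot2::xlim(0, 0.5) +
    ggplot2::theme_minimal()
}

#' Plot estimated edge-length proportions
#'
#' @param est an `edge_lengths` object.
#' @return a ggplot: per-edge mutation share, no-mutation component last.
#' @export
plot_edge_lengths <- function(est) {
  stopifnot(inherits(est, "edge_lengths"))
  tb <- est$table
  tb$edge_label <- factor(ifelse(tb$edge == 0, "none", paste0("e", tb$edge)),
                          levels = c(paste0("e", tb$edge[tb$edge > 0]),
                                     "none"))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$edge_label,
                                   y = .data$length)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "edge", y = "mutation share") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
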