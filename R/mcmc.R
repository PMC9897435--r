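# Generic adaptive random-walk Metropolis sampler used by the skew-normal
# mixed model. Proposal covariance is adapted during warmup (Robbins-Monro
# scaling toward 0.25 acceptance plus empirical covariance once enough
# history is available); adaptation stops at the end of warmup so the kept
# draws target the exact posterior.

#' Adaptive random-walk Metropolis sampling
#'
#' @param log_post Function(theta) returning the unnormalized log posterior.
#' @param init Numeric vector of initial values (or matrix, one row per chain).
#' @param n_draws Post-warmup draws per chain.
#' @param warmup Warmup iterations per chain (adaptation window).
#' @param chains Number of chains.
#' @param seed Integer seed.
#' @param init_scale Initial proposal SD (scalar or per-parameter).
#' @return List with `draws` (array n_draws x chains x dim), `accept_rate`,
#'   and `diagnostics` (R-hat/ESS per parameter).
#' @keywords internal
adaptive_mh <- function(log_post, init, n_draws = 1000, warmup = 500,
                        chains = 2, seed = 1, init_scale = 0.1) {
  init <- rbind(init)
  dim_p <- ncol(init)
  if (nrow(init) < chains) {
    init <- init[rep(seq_len(nrow(init)), length.out = chains), , drop = FALSE]
  }
  draws <- array(NA_real_, c(n_draws, chains, dim_p))
  acc_total <- 0
  with_seed(seed, {
    for (ch in seq_len(chains)) {
      theta <- init[ch, ] + stats::rnorm(dim_p, 0, 0.01)
      lp <- log_post(theta)
      if (!is.finite(lp)) { theta <- init[ch, ]; lp <- log_post(theta) }
      if (!is.finite(lp)) stop("log posterior not finite at initial values")
      scale <- rep_len(init_scale, dim_p)
      log_lambda <- 0
      chol_prop <- diag(scale, dim_p)
      hist <- matrix(NA_real_, warmup, dim_p)
      n_iter <- warmup + n_draws
      acc_ch <- 0
      for (it in seq_len(n_iter)) {
        step <- exp(log_lambda) * drop(crossprod(chol_prop, stats::rnorm(dim_p)))
        prop <- theta + step
        lp_prop <- log_post(prop)
        acc <- is.finite(lp_prop) && log(stats::runif(1)) < (lp_prop - lp)
        if (acc) { theta <- prop; lp <- lp_prop }
        if (it <= warmup) {
          hist[it, ] <- theta
          # Robbins-Monro scale adaptation toward 0.25 acceptance
          log_lambda <- log_lambda + (as.numeric(acc) - 0.25) / sqrt(it)
          if (it >= 150 && (it %% 150 == 0 || it == warmup)) {
            emp <- stats::cov(hist[seq_len(it), , drop = FALSE])
            emp <- emp + diag(1e-8 + 1e-6 * mean(diag(emp)), dim_p)
            ch_try <- tryCatch(chol(2.38^2 / dim_p * emp), error = function(e) NULL)
            if (!is.null(ch_try)) chol_prop <- ch_try
          }
        } else {
          draws[it - warmup, ch, ] <- theta
          acc_ch <- acc_ch + as.numeric(acc)
        }
      }
      acc_total <- acc_total + acc_ch / n_draws
    }
  })
  list(draws = draws,
       accept_rate = acc_total / chains,
       diagnostics = mcmc_diagnostics(draws))
}

# Flatten an iter x chain x dim array into a (iter*chain) x dim matrix.
flatten_draws <- function(arr) {
  d <- dim(arr)
  matrix(aperm(arr, c(1, 2, 3)), d[1] * d[2], d[3])
}
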