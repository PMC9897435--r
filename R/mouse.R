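# Longitudinal mouse analysis: cage filtering for pooled urine, PCA by
# tumour-progression timepoint with bivariate-t confidence ellipses, and a
# Bayesian mixed model (timepoint fixed effect, unit random intercept,
# conjugate Gibbs sampling) for per-feature percent change vs baseline.

mouse_timepoints <- c("baseline", "localized", "postop", "metastasis")

#' Filter pooled urine rows to complete cages
#'
#' Pooled urine from a metabolic cage is interpretable only while both mice
#' are alive; rows flagged `alive_pair = FALSE` are removed. Plasma rows are
#' never dropped by this rule.
#'
#' @param table Long-format mouse table (see [generate_mouse()]).
#' @return Filtered table.
#' @export
cage_filter <- function(table) {
  drop <- table$fluid == "urine" & !table$alive_pair
  table[!drop, , drop = FALSE]
}

#' PCA of GAGome profiles by timepoint
#'
#' Principal components of the scaled features with per-timepoint 95%
#' confidence ellipses from a bivariate t distribution fitted to the first
#' two PC coordinates (df = points - 2, minimum 3).
#'
#' @param table Long-format table with `timepoint` and feature columns.
#' @param features Feature columns (default: the 17 concentrations).
#' @param level Ellipse confidence level.
#' @return Object of class `gag_pca`: `scores` (with timepoint),
#'   `explained` (% variance per PC), `loadings`, `ellipses` (per timepoint:
#'   center, covariance, df, boundary path).
#' @export
pca_timepoints <- function(table, features = gag_conc_features, level = 0.95) {
  X <- as.matrix(table[, features, drop = FALSE])
  keep_col <- apply(X, 2, function(v) stats::sd(v, na.rm = TRUE) > 0)
  pc <- stats::prcomp(X[, keep_col, drop = FALSE], center = TRUE, scale. = TRUE)
  expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  sc <- as.data.frame(pc$x)
  sc$timepoint <- table$timepoint
  ellipses <- lapply(split(sc, sc$timepoint), function(d) {
    z <- as.matrix(d[, c("PC1", "PC2")])
    n <- nrow(z)
    ctr <- colMeans(z)
    cv <- stats::cov(z)
    df <- max(n - 2, 3)
    r2 <- 2 * stats::qf(level, 2, df)
    theta <- seq(0, 2 * pi, length.out = 100)
    ch <- tryCatch(chol(cv), error = function(e) chol(cv + diag(1e-10, 2)))
    path <- t(ctr + t(sqrt(r2) * cbind(cos(theta), sin(theta)) %*% ch))
    list(center = ctr, cov = cv, df = df, path = path, n = n)
  })
  structure(list(scores = sc, explained = expl, loadings = pc$rotation,
                 ellipses = ellipses, level = level),
            class = "gag_pca")
}

#' @export
print.gag_pca <- function(x, ...) {
  cat(sprintf("GAGome PCA: PC1 %.1f%%, PC2 %.1f%% explained variance\n",
              x$explained[1], x$explained[2]))
  invisible(x)
}

#' @export
plot.gag_pca <- function(x, ...) {
  tps <- unique(x$scores$timepoint)
  cols <- stats::setNames(seq_along(tps), tps)
  graphics::plot(x$scores$PC1, x$scores$PC2,
                 col = cols[x$scores$timepoint], pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", x$explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", x$explained[2]), ...)
  for (tp in names(x$ellipses)) {
    graphics::lines(x$ellipses[[tp]]$path, col = cols[tp])
  }
  graphics::legend("topright", legend = names(cols), col = cols, pch = 19,
                   cex = 0.8)
  invisible(x)
}

#' Percent change vs baseline from a Bayesian mixed model
#'
#' Standardizes the feature, fits y ~ N(mu_timepoint + b_unit, sigma^2) with
#' unit random intercepts by conjugate Gibbs sampling (normal priors on
#' timepoint means, inverse-gamma on variances), back-transforms the
#' timepoint-mean draws to the raw concentration scale, and reports the
#' posterior percent change 100 * (level_t - level_baseline)/level_baseline
#' per timepoint with 95% credible intervals. Draws with a non-positive raw
#' baseline level are undefined and make the estimate missing.
#'
#' @param table Long-format table for one fluid.
#' @param feature Feature column to analyse.
#' @param n_draws,warmup Gibbs draws kept/discarded.
#' @param seed Integer seed.
#' @return Object of class `gag_trend`: per-timepoint table (pct_change,
#'   cri_low, cri_high) plus the draws.
#' @export
fit_trend <- function(table, feature, n_draws = 3000, warmup = 500, seed = 1) {
  tp <- factor(table$timepoint, levels = intersect(mouse_timepoints,
                                                   unique(table$timepoint)))
  unit <- factor(table$unit_id)
  y_raw <- table[[feature]]
  keep <- !is.na(y_raw)
  y_raw <- y_raw[keep]; tp <- droplevels(tp[keep]); unit <- droplevels(unit[keep])
  if (nlevels(tp) < 2) stop("need >= 2 timepoints", call. = FALSE)
  if (nlevels(unit) < 5) stop("need >= 5 units", call. = FALSE)
  m0 <- mean(y_raw); s0 <- stats::sd(y_raw)
  if (s0 == 0) stop("constant feature", call. = FALSE)
  y <- (y_raw - m0) / s0
  Tn <- nlevels(tp); U <- nlevels(unit)
  ti <- as.integer(tp); ui <- as.integer(unit)
  n <- length(y)
  # conjugate Gibbs: mu_t ~ N(0, 5^2), b_u ~ N(0, tau2), sigma2/tau2 ~ IG(2, 0.5)
  mu <- tapply(y, ti, mean); b <- rep(0, U); sigma2 <- 0.5; tau2 <- 0.25
  prior_mu_var <- 25
  keep_draws <- matrix(NA_real_, n_draws, Tn)
  with_seed(seed, {
    for (it in seq_len(warmup + n_draws)) {
      # timepoint means
      for (t_ in seq_len(Tn)) {
        idx <- which(ti == t_)
        prec <- length(idx) / sigma2 + 1 / prior_mu_var
        mean_t <- sum(y[idx] - b[ui[idx]]) / sigma2 / prec
        mu[t_] <- stats::rnorm(1, mean_t, sqrt(1 / prec))
      }
      # unit intercepts
      for (u_ in seq_len(U)) {
        idx <- which(ui == u_)
        prec <- length(idx) / sigma2 + 1 / tau2
        mean_u <- sum(y[idx] - mu[ti[idx]]) / sigma2 / prec
        b[u_] <- stats::rnorm(1, mean_u, sqrt(1 / prec))
      }
      res <- y - mu[ti] - b[ui]
      sigma2 <- 1 / stats::rgamma(1, 2 + n / 2, 0.5 + sum(res^2) / 2)
      tau2 <- 1 / stats::rgamma(1, 2 + U / 2, 0.25 + sum(b^2) / 2)
      if (it > warmup) keep_draws[it - warmup, ] <- mu
    }
  })
  colnames(keep_draws) <- levels(tp)
  raw_draws <- m0 + s0 * keep_draws  # back-transform to concentration scale
  base <- raw_draws[, 1]
  ok <- base > 0
  out <- data.frame(timepoint = levels(tp)[-1],
                    pct_change = NA_real_, cri_low = NA_real_, cri_high = NA_real_)
  if (any(ok)) {
    for (j in 2:ncol(raw_draws)) {
      pct <- 100 * (raw_draws[ok, j] - base[ok]) / base[ok]
      out[j - 1, 2:4] <- c(stats::median(pct),
                           stats::quantile(pct, c(0.025, 0.975), names = FALSE))
    }
  } else {
    warning("baseline level <= 0 in all draws; percent change undefined",
            call. = FALSE)
  }
  structure(list(table = out, feature = feature,
                 mean_draws = raw_draws, standardization = c(mean = m0, sd = s0),
                 n_units = U, pct_defined = any(ok)),
            class = "gag_trend")
}

#' @export
print.gag_trend <- function(x, ...) {
  cat(sprintf("Percent change vs baseline for %s (%d units):\n",
              x$feature, x$n_units))
  tab <- transform(x$table, pct_change = round(pct_change, 1),
                   cri_low = round(cri_low, 1), cri_high = round(cri_high, 1))
  print(tab, row.names = FALSE)
  invisible(x)
}
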