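# Shared fixtures, memoised so expensive synthetic cohorts are built once per
# test run. All fixtures are generated in code; no stored data.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# default development-style cohort with computed features + detectability
dev_cohort <- function(seed = 42) {
  memo(paste0("dev", seed), {
    syn <- generate_development_cohort(seed = seed)
    cohort <- add_features(syn$cohort)
    list(syn = syn, cohort = cohort, detect = detectability_filter(cohort))
  })
}

# named 17-concentration vector, all zero unless given
panel_with <- function(...) {
  x <- stats::setNames(numeric(length(gag_conc_features)), gag_conc_features)
  vals <- list(...)
  x[names(vals)] <- unlist(vals)
  x
}

# quick logistic dataset with planted informative features
logit_data <- function(n = 500, p = 10, beta = c(1, 1), seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    eta <- drop(X[, seq_along(beta), drop = FALSE] %*% beta) - 0.3
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    list(X = X, y = y)
  })
}

# standardized feature vector with a planted group shift, for ROPE tests
rope_data <- function(shift, n_per_group = 200, alpha = 3, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    grp <- factor(rep(c("healthy", "CA"), each = n_per_group),
                  levels = c("healthy", "CA"))
    batch <- paste0("b", sample(1:3, n, TRUE))
    z <- rsn(n, 0, 1, alpha)
    z <- (z - mean(z)) / stats::sd(z)
    z[grp == "CA"] <- z[grp == "CA"] + shift
    list(z = z, grp = grp, batch = batch)
  })
}

# reduced-effort ROPE config for simulation suites (fewer draws; decisions
# depend on the difference draws, whose effective size stays adequate)
fast_rope_config <- function() rope_config(chains = 2, draws = 1250, warmup = 750)
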