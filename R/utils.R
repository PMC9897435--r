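# Internal utilities: seeding, hashing, provenance headers, MCMC diagnostics.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the previous RNG
#' state afterwards, so seeded helpers do not disturb the caller's stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Derive a child seed from a base seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483629)
}

# FNV-1a hash of an R object's deparsed form; used for provenance headers only.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

provenance_header <- function(seed = NULL, config = NULL) {
  c(
    sprintf("# gagmced %s", as.character(utils::packageVersion("gagmced"))),
    sprintf("# created %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    if (!is.null(seed)) sprintf("# seed %d", as.integer(seed)),
    if (!is.null(config)) sprintf("# config_hash %s", config_hash(config))
  )
}

# Write a data.frame as TSV/CSV with a provenance comment header.
write_table_prov <- function(df, path, sep = "\t", seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(provenance_header(seed = seed, config = config), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- MCMC diagnostics -------------------------------------------------------

#' Split R-hat for a set of chains
#'
#' Potential scale reduction factor computed on split chains (each chain halved),
#' the convergence diagnostic used throughout the package's samplers.
#'
#' @param draws Matrix of posterior draws, iterations x chains.
#' @return Scalar R-hat (NA if fewer than 4 split-halves of length 2).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sp <- cbind(draws[seq_len(half), , drop = FALSE],
              draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(ifelse(B <= 0, 1, Inf))
  var_plus <- (half - 1) / half * W + B / half
  sqrt(var_plus / W)
}

#' Effective sample size for a set of chains
#'
#' Stan-style ESS from combined-chain autocorrelations with Geyer's initial
#' positive sequence truncation.
#'
#' @param draws Matrix of posterior draws, iterations x chains.
#' @return Scalar effective sample size.
#' @export
ess_basic <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws); m <- ncol(draws)
  if (n < 4) return(NA_real_)
  vars <- apply(draws, 2, stats::var)
  means <- colMeans(draws)
  W <- mean(vars)
  B <- if (m > 1) n * stats::var(means) else 0
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus <= 0) return(n * m)
  # mean autocovariance across chains
  max_lag <- min(n - 1, 1000)
  acov <- matrix(0, max_lag + 1, m)
  for (j in seq_len(m)) {
    ac <- stats::acf(draws[, j], lag.max = max_lag, plot = FALSE,
                     type = "covariance", demean = TRUE)$acf[, 1, 1]
    acov[, j] <- ac
  }
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus
  # Geyer initial positive sequence on paired sums
  tau <- 1
  t <- 1
  repeat {
    if (t > max_lag) break
    r1 <- rho[t + 1]
    r2 <- if (t + 1 <= max_lag) rho[t + 2] else 0
    if (is.na(r1 + r2) || (r1 + r2) < 0) break
    tau <- tau + 2 * (r1 + r2)
    t <- t + 2
  }
  max(n * m / tau, 1)
}

# Diagnostics for a 3-d array of draws (iter x chain x param).
mcmc_diagnostics <- function(arr, par_names = NULL) {
  d <- dim(arr)
  k <- d[3]
  rhat <- numeric(k); ess <- numeric(k)
  for (j in seq_len(k)) {
    m <- arr[, , j, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = d[2])
    rhat[j] <- split_rhat(m)
    ess[j] <- ess_basic(m)
  }
  data.frame(parameter = par_names %||% sprintf("par%d", seq_len(k)),
             rhat = rhat, ess = ess)
}

# Population SD (divide by n), the standardization convention used throughout.
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
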