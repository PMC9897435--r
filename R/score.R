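# MCED score construction: projection-predictive forward selection on a
# Bayesian logistic reference model, one-standard-error size rule, 400-draw
# projection of the selected submodel, and specificity-anchored cutoffs. The
# fitted object is an S3 `mced_model` with print/summary/coef/predict methods.

#' Fit the Bayesian logistic reference model
#'
#' Thin wrapper around [bayes_logreg()] that records the candidate feature
#' list; the reference model is the starting point for projection-predictive
#' selection.
#'
#' @param X Standardized candidate feature matrix.
#' @param y Binary response (1 = cancer).
#' @param prior List with `df` and `scale` of the t prior (defaults 7, 2.5).
#' @param chains,draws Sampler settings (defaults mirror 4 chains x 4000
#'   iterations with half warmup: 500 kept draws per chain).
#' @param seed Integer seed.
#' @return A `bayes_logreg` fit with a `candidates` field.
#' @export
fit_reference <- function(X, y, prior = list(df = 7, scale = 2.5),
                          chains = 4, draws = 500, seed = 1) {
  fit <- bayes_logreg(X, y, prior_df = prior$df, prior_scale = prior$scale,
                      chains = chains, draws = draws, seed = seed)
  fit$candidates <- colnames(X)
  fit
}

# Cluster reference draws (on the coefficient scale) for cheap projections
# during selection; returns centroid coefficients and weights.
cluster_draws <- function(fit, nclusters = 10, seed = 1) {
  dm <- fit$draws
  nclusters <- min(nclusters, nrow(dm))
  km <- with_seed(seed, stats::kmeans(dm, centers = nclusters, nstart = 2,
                                      iter.max = 30))
  list(centers = km$centers, weights = km$size / sum(km$size))
}

#' Project the reference model onto a feature subset
#'
#' For each (thinned) posterior draw with fitted probabilities p_s, the
#' projected coefficients minimize the sum of KL divergences from
#' Bernoulli(p_s(x_i)) to the submodel Bernoulli(q(x_i)) — a logistic fit with
#' p_s as soft labels. Projecting onto the full candidate set reproduces the
#' reference predictions exactly; the empty subset gives the intercept-only
#' KL minimizer logit(mean(p_s)).
#'
#' @param fit Reference `bayes_logreg` fit.
#' @param features Character vector of selected features (may be empty).
#' @param ndraws Number of projected draws (default 400).
#' @param seed Seed (used only when draws must be resampled).
#' @return Matrix ndraws x (k+1) of projected coefficients (intercept first).
#' @export
project_submodel <- function(fit, features, ndraws = 400, seed = 1) {
  S <- nrow(fit$draws)
  idx <- if (S >= ndraws) {
    unique(round(seq(1, S, length.out = ndraws)))
  } else {
    with_seed(seed, sample.int(S, ndraws, replace = TRUE))
  }
  while (length(idx) < ndraws) idx <- c(idx, idx[seq_len(ndraws - length(idx))])
  Xd_full <- cbind(1, fit$X)
  p_all <- stats::plogis(tcrossprod(fit$draws[idx, , drop = FALSE], Xd_full))
  if (length(features) == 0) {
    b0 <- stats::qlogis(rowMeans(p_all))
    return(matrix(b0, ncol = 1, dimnames = list(NULL, "(Intercept)")))
  }
  miss <- setdiff(features, colnames(fit$X))
  if (length(miss)) stop("features not in reference model: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  Xs <- cbind(1, fit$X[, features, drop = FALSE])
  out <- matrix(NA_real_, length(idx), ncol(Xs))
  start <- NULL
  for (s in seq_along(idx)) {
    out[s, ] <- proj_logit(Xs, p_all[s, ], start = start)
    start <- out[s, ]
  }
  colnames(out) <- c("(Intercept)", features)
  out
}

# K-fold cross-validated pointwise elpd of a projected submodel. Projections
# use clustered reference draws restricted to the training rows of each fold;
# the reference posterior itself is not refit per fold (documented
# approximation to full cross-validated selection).
submodel_cv_elpd <- function(fit, features, folds, clusters) {
  n <- length(fit$y)
  Xd_full <- cbind(1, fit$X)
  elpd <- numeric(n)
  for (k in sort(unique(folds))) {
    test <- which(folds == k); train <- which(folds != k)
    p_tr <- stats::plogis(clusters$centers %*% t(Xd_full[train, , drop = FALSE]))
    if (length(features) == 0) {
      q_te <- matrix(stats::qlogis(rowMeans(p_tr)), ncol = 1)
      q_te <- stats::plogis(matrix(q_te, nrow(p_tr), length(test)))
    } else {
      Xs_tr <- cbind(1, fit$X[train, features, drop = FALSE])
      Xs_te <- cbind(1, fit$X[test, features, drop = FALSE])
      q_te <- matrix(NA_real_, nrow(p_tr), length(test))
      start <- NULL
      for (c_i in seq_len(nrow(p_tr))) {
        bc <- proj_logit(Xs_tr, p_tr[c_i, ], start = start, tol = 1e-8)
        start <- bc
        q_te[c_i, ] <- stats::plogis(drop(Xs_te %*% bc))
      }
    }
    w <- clusters$weights
    for (j in seq_along(test)) {
      i <- test[j]
      py <- if (fit$y[i] == 1) q_te[, j] else 1 - q_te[, j]
      elpd[i] <- log(sum(w * py))
    }
  }
  elpd
}

#' Projection-predictive forward selection
#'
#' Greedy forward search: at each step the candidate whose projected submodel
#' maximizes cross-validated elpd is added. The reference elpd is estimated by
#' truncated importance-sampling LOO; submodel elpd by K-fold re-projection
#' with clustered draws. Per-size elpd differences to the reference are
#' recorded with their standard errors (sqrt(n) * sd of pointwise
#' differences). Ties are broken toward the feature with the larger absolute
#' posterior-mean reference coefficient.
#'
#' @param fit Reference fit from [fit_reference()].
#' @param cap Maximal submodel size.
#' @param K Number of cross-validation folds.
#' @param nclusters Number of posterior-draw clusters used during selection.
#' @param seed Integer seed (fold assignment and clustering).
#' @return Object of class `mced_selection`: data.frame path (size 0 =
#'   intercept-only first row) with `elpd`, `elpd_diff`, `diff_se`.
#' @export
forward_select <- function(fit, cap = NULL, K = 10, nclusters = 10, seed = 1) {
  n <- length(fit$y)
  if (n < 2 * K) stop("too few observations for ", K, "-fold selection", call. = FALSE)
  p <- ncol(fit$X)
  cap <- min(cap %||% p, p)
  if (cap < 1) stop("cap must be >= 1", call. = FALSE)
  folds <- with_seed(derive_seed(seed, 1),
                     sample(rep_len(seq_len(K), n)))
  clusters <- cluster_draws(fit, nclusters, seed = derive_seed(seed, 2))
  ref_elpd <- loo_elpd(fit)
  post_mean <- colMeans(fit$draws)[-1]
  selected <- character(0)
  remaining <- colnames(fit$X)
  rows <- list()
  record <- function(size, feature, elpd_i) {
    d <- elpd_i - ref_elpd
    data.frame(size = size, feature = feature,
               elpd = sum(elpd_i), elpd_diff = sum(d),
               diff_se = sqrt(n) * stats::sd(d))
  }
  rows[[1]] <- record(0L, NA_character_,
                      submodel_cv_elpd(fit, character(0), folds, clusters))
  for (step in seq_len(cap)) {
    # candidate order: larger |reference coefficient| first (tie-break rule)
    remaining <- remaining[order(-abs(post_mean[remaining]))]
    elpds <- vapply(remaining, function(f) {
      sum(submodel_cv_elpd(fit, c(selected, f), folds, clusters))
    }, numeric(1))
    best <- remaining[which.max(elpds)]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    rows[[step + 1]] <- record(step, best,
                               submodel_cv_elpd(fit, selected, folds, clusters))
  }
  path <- do.call(rbind, rows)
  rownames(path) <- NULL
  structure(path, cap = cap, K = K, nclusters = nclusters,
            class = c("mced_selection", "data.frame"))
}

#' One-standard-error size rule
#'
#' Chooses the smallest submodel size whose elpd difference to the reference
#' model is at most one standard error below zero. If no size qualifies the
#' cap is returned with a warning.
#'
#' @param path An `mced_selection` path (or data.frame with `size`,
#'   `elpd_diff`, `diff_se`).
#' @return Integer size.
#' @export
choose_size <- function(path) {
  ok <- path$elpd_diff >= -path$diff_se
  if (!any(ok)) {
    warning("no size within one SE of the reference; using the cap", call. = FALSE)
    return(max(path$size))
  }
  min(path$size[ok])
}

#' Specificity-anchored score cutoffs
#'
#' For each requested specificity level, the smallest threshold such that the
#' fraction of control scores at or below it is at least the level (ties
#' broken upward: the returned cutoff is the midpoint to the next distinct
#' score, or just above the maximum when no control exceeds it). Samples
#' scoring strictly above the cutoff are called positive.
#'
#' @param control_scores Scores of the control (healthy) samples.
#' @param specificity Target specificity levels.
#' @return Named numeric cutoffs with attribute `achieved_specificity`.
#' @export
set_cutoffs <- function(control_scores, specificity = c(0.95, 0.99)) {
  s <- sort(control_scores)
  n <- length(s)
  out <- numeric(length(specificity))
  ach <- numeric(length(specificity))
  for (i in seq_along(specificity)) {
    lev <- specificity[i]
    stopifnot(lev > 0, lev <= 1)
    k <- ceiling(lev * n)
    t0 <- s[k]
    above <- s[s > t0]
    cut <- if (length(above)) (t0 + min(above)) / 2 else t0 + 2e-8 * max(1, abs(t0))
    out[i] <- cut
    ach[i] <- mean(control_scores <= cut)
  }
  names(out) <- paste0("spec", round(100 * specificity))
  attr(out, "achieved_specificity") <- stats::setNames(ach, names(out))
  out
}

#' Restrict candidates to independently measured features
#'
#' Keeps only semi-absolute concentration features (ug/mL), dropping
#' fractions, charges, ratios and totals-derived compositions; totals are
#' concentrations and are kept. Accepts `plasma_`/`urine_` prefixed names.
#'
#' @param candidates Character vector of candidate feature names.
#' @return Pruned character vector.
#' @export
prune_to_independent <- function(candidates) {
  base <- sub("^(plasma|urine)_", "", candidates)
  keep <- base %in% c(gag_conc_features, "total_cs", "total_hs")
  out <- candidates[keep]
  if (!length(out)) stop("no concentration features among candidates", call. = FALSE)
  out
}

#' Build an MCED score model
#'
#' The package's main fitting function: fits the Bayesian logistic reference
#' model on the standardized candidate features, runs projection-predictive
#' forward selection with the one-SE size rule, projects 400 posterior draws
#' onto the selected subset, and anchors 95%/99%-specificity cutoffs on the
#' control scores. The score of a sample is the mean projected linear
#' predictor — the log-odds of any-type cancer.
#'
#' @param X Standardized candidate feature matrix (samples x features).
#' @param y Binary response (1 = cancer).
#' @param prior t prior (list with `df`, `scale`).
#' @param cap Maximal submodel size (default: all candidates, at most 15).
#' @param K,nclusters Selection settings (see [forward_select()]).
#' @param ndraws Number of projected draws (default 400).
#' @param chains,draws Reference sampler settings.
#' @param standardizer Optional `gag_standardizer` (or per-fluid list) stored
#'   for scoring raw cohorts.
#' @param fluid Label ("plasma", "urine", "combined") carried in the model.
#' @param seed Integer seed.
#' @return Object of class `mced_model`.
#' @export
build_score <- function(X, y, prior = list(df = 7, scale = 2.5), cap = NULL,
                        K = 10, nclusters = 10, ndraws = 400,
                        chains = 4, draws = 500,
                        standardizer = NULL, fluid = NA_character_, seed = 1) {
  X <- as.matrix(X)
  cap <- cap %||% min(ncol(X), 15)
  ref <- fit_reference(X, y, prior = prior, chains = chains, draws = draws,
                       seed = derive_seed(seed, 11))
  path <- forward_select(ref, cap = cap, K = K, nclusters = nclusters,
                         seed = derive_seed(seed, 12))
  size <- choose_size(path)
  features <- path$feature[path$size >= 1 & path$size <= size]
  proj <- project_submodel(ref, features, ndraws = ndraws,
                           seed = derive_seed(seed, 13))
  scores <- drop(cbind(1, X[, features, drop = FALSE]) %*% colMeans(proj))
  cutoffs <- set_cutoffs(scores[y == 0])
  structure(list(features = features, projected_draws = proj,
                 path = path, size = size, cutoffs = cutoffs,
                 prior = prior, fluid = fluid, seed = seed,
                 standardizer = standardizer,
                 reference_summary = list(bayes_r2 = ref$bayes_r2,
                                          accept_rate = ref$accept_rate,
                                          candidates = ref$candidates),
                 display_cap = c(-6, 6),
                 version = as.character(utils::packageVersion("gagmced"))),
            class = "mced_model")
}

#' @export
print.mced_model <- function(x, ...) {
  cat(sprintf("Free GAGome MCED score (%s): %d features, %d projected draws\n",
              x$fluid, length(x$features), nrow(x$projected_draws)))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  cat(sprintf("  cutoffs: %.3f (95%% spec), %.3f (99%% spec)\n",
              x$cutoffs[["spec95"]], x$cutoffs[["spec99"]]))
  invisible(x)
}

#' @export
summary.mced_model <- function(object, ...) {
  cf <- apply(object$projected_draws, 2, function(v) {
    c(mean = mean(v), sd = stats::sd(v),
      q2.5 = unname(stats::quantile(v, 0.025)),
      q97.5 = unname(stats::quantile(v, 0.975)))
  })
  out <- list(coefficients = t(cf), path = object$path, size = object$size,
              cutoffs = object$cutoffs,
              bayes_r2 = object$reference_summary$bayes_r2)
  class(out) <- "summary.mced_model"
  out
}

#' @export
print.summary.mced_model <- function(x, ...) {
  cat("Projected coefficient summary:\n")
  print(round(x$coefficients, 3))
  cat("\nSelection path (elpd difference vs reference +/- SE):\n")
  print(transform(x$path, elpd_diff = round(elpd_diff, 2),
                  diff_se = round(diff_se, 2)))
  cat(sprintf("\nChosen size (one-SE rule): %d | reference Bayesian R2: %.3f\n",
              x$size, x$bayes_r2))
  invisible(x)
}

#' @export
coef.mced_model <- function(object, ...) colMeans(object$projected_draws)

#' Score new samples with an MCED model
#'
#' @param object An `mced_model`.
#' @param newdata Matrix/data.frame with the model's feature columns, already
#'   on the standardized scale unless the model carries a standardizer and
#'   `standardized = FALSE`.
#' @param type `"score"` (mean projected log-odds), `"prob"`, or `"class"`
#'   (positive when the score exceeds the requested specificity cutoff).
#' @param cutoff Cutoff name for `type = "class"` (`"spec95"` or `"spec99"`).
#' @param standardized Set `FALSE` to apply the stored standardizer first.
#' @param ... Unused.
#' @return Numeric scores/probabilities or 0/1 calls.
#' @export
predict.mced_model <- function(object, newdata, type = c("score", "prob", "class"),
                               cutoff = "spec95", standardized = TRUE, ...) {
  type <- match.arg(type)
  if (!standardized) {
    if (is.null(object$standardizer)) stop("model has no stored standardizer", call. = FALSE)
    newdata <- predict(object$standardizer, as.data.frame(newdata))
  }
  nd <- as.data.frame(newdata)
  miss <- setdiff(object$features, names(nd))
  if (length(miss)) stop("newdata lacks features: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  Xs <- cbind(1, as.matrix(nd[, object$features, drop = FALSE]))
  eta <- tcrossprod(Xs, object$projected_draws)  # n x ndraws
  score <- rowMeans(eta)
  switch(type,
         score = score,
         prob = stats::plogis(score),
         class = as.integer(score > object$cutoffs[[cutoff]]))
}

#' Capped scores for display
#'
#' Caps scores to the display interval (default (-6, 6)); affects plots only,
#' never classification.
#'
#' @param model An `mced_model`.
#' @param scores Numeric scores.
#' @return Capped scores.
#' @export
display_scores <- function(model, scores) {
  pmin(pmax(scores, model$display_cap[1]), model$display_cap[2])
}
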