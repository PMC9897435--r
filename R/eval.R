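# Discrimination and clinical-usefulness metrics: AUC with DeLong confidence
# intervals, sensitivity at fixed specificity with binomial (Wald or exact)
# CIs, screening PPV/NPV arithmetic, scaled Brier score, bootstrap internal
# validation with optimism estimates, and Kendall permutation tests for
# confounder correlations with Holm correction.

#' ROC AUC with DeLong confidence interval
#'
#' AUC by the rank statistic with tie correction (equivalent to exhaustive
#' pair counting with ties scoring 1/2); the CI uses DeLong's asymptotic
#' covariance of the placement values.
#'
#' @param scores Numeric scores (higher = more cancer-like).
#' @param labels Binary labels (1 = case).
#' @param conf_level Confidence level.
#' @return Object of class `gag_roc`: `auc`, `ci`, `se`, and the ROC `curve`
#'   (FPR/TPR per threshold).
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes required", call. = FALSE)
  x <- scores[labels == 1]  # cases
  y <- scores[labels == 0]  # controls
  m <- length(x); n <- length(y)
  # placement values (DeLong): psi(x_i, y_j) = 1, 1/2, 0
  v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n, numeric(1))
  v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m, numeric(1))
  auc <- mean(v10)
  se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * zq * se, 0), 1)
  th <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, th),
    tpr = c(0, vapply(th, function(t) mean(x >= t), numeric(1))),
    fpr = c(0, vapply(th, function(t) mean(y >= t), numeric(1))))
  structure(list(auc = auc, se = se, ci = ci, conf_level = conf_level,
                 n_cases = m, n_controls = n, curve = curve),
            class = "gag_roc")
}

#' @export
print.gag_roc <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%g%% CI: %.3f-%.3f); %d cases vs %d controls\n",
              x$auc, 100 * x$conf_level, x$ci[1], x$ci[2],
              x$n_cases, x$n_controls))
  invisible(x)
}

#' @export
plot.gag_roc <- function(x, ...) {
  graphics::plot(x$curve$fpr, x$curve$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Sensitivity at fixed specificity
#'
#' Anchors the cutoff on the controls via [set_cutoffs()] and reports the
#' detection rate among cases with a binomial confidence interval: Wald
#' (normal approximation, the default) or exact Clopper-Pearson.
#'
#' @param scores,labels Scores and binary labels (1 = case).
#' @param specificity Target specificity.
#' @param ci `"wald"` or `"exact"`.
#' @param conf_level Confidence level.
#' @return One-row data.frame: sensitivity, CI, n detected/cases, cutoff,
#'   achieved specificity, CI method.
#' @export
sensitivity_at_specificity <- function(scores, labels, specificity = 0.95,
                                       ci = c("wald", "exact"),
                                       conf_level = 0.95) {
  ci <- match.arg(ci)
  labels <- as.integer(labels)
  n_cases <- sum(labels == 1)
  if (n_cases == 0) stop("no cases", call. = FALSE)
  if (sum(labels == 0) == 0) stop("no controls to anchor the cutoff", call. = FALSE)
  cutoff <- set_cutoffs(scores[labels == 0], specificity)[[1]]
  detected <- sum(scores[labels == 1] > cutoff)
  ci_b <- binomial_ci(detected, n_cases, method = ci, conf_level = conf_level)
  if (detected %in% c(0L, n_cases) && ci == "wald") {
    warning("degenerate Wald interval at boundary sensitivity", call. = FALSE)
  }
  data.frame(specificity = specificity, sensitivity = detected / n_cases,
             ci_low = ci_b[1], ci_high = ci_b[2], detected = detected,
             n_cases = n_cases, cutoff = cutoff,
             achieved_specificity = mean(scores[labels == 0] <= cutoff),
             ci_method = ci)
}

#' Binomial confidence interval
#'
#' @param x Successes.
#' @param n Trials.
#' @param method `"wald"` (p +/- z*sqrt(p(1-p)/n), truncated to \[0,1\]) or
#'   `"exact"` (Clopper-Pearson).
#' @param conf_level Confidence level.
#' @return Length-2 vector (low, high).
#' @export
binomial_ci <- function(x, n, method = c("wald", "exact"), conf_level = 0.95) {
  method <- match.arg(method)
  p <- x / n
  if (method == "wald") {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    half <- z * sqrt(p * (1 - p) / n)
    return(c(max(0, p - half), min(1, p + half)))
  }
  a <- (1 - conf_level) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

#' Screening PPV and NPV
#'
#' Post-test probabilities at a stated prevalence:
#' PPV = sens*pi / (sens*pi + (1-spec)(1-pi));
#' NPV = spec(1-pi) / (spec(1-pi) + (1-sens)pi).
#'
#' @param sens,spec Sensitivity and specificity in \[0,1\].
#' @param prevalence Disease prevalence in \[0,1\].
#' @return Named vector `ppv`, `npv` (NA with a warning when undefined).
#' @export
ppv_npv <- function(sens, spec, prevalence) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1,
            prevalence >= 0, prevalence <= 1)
  d1 <- sens * prevalence + (1 - spec) * (1 - prevalence)
  d2 <- spec * (1 - prevalence) + (1 - sens) * prevalence
  ppv <- if (d1 > 0) sens * prevalence / d1 else { warning("PPV undefined (no positives)", call. = FALSE); NA_real_ }
  npv <- if (d2 > 0) spec * (1 - prevalence) / d2 else { warning("NPV undefined (no negatives)", call. = FALSE); NA_real_ }
  c(ppv = ppv, npv = npv)
}

#' Scaled Brier score
#'
#' 1 - Brier / Brier_null, where the null predictor is the observed case
#' fraction (prevalence-based reference): Brier_null = mean((y - ybar)^2).
#'
#' @param prob Predicted probabilities.
#' @param y Binary outcomes.
#' @return Scalar scaled Brier score (1 = perfect, 0 = no better than
#'   prevalence).
#' @export
scaled_brier <- function(prob, y) {
  y <- as.numeric(y)
  brier <- mean((prob - y)^2)
  bnull <- mean((y - mean(y))^2)
  if (bnull == 0) return(NA_real_)
  1 - brier / bnull
}

#' Full evaluation report for a score
#'
#' AUC with CI, sensitivity at the requested specificities, per-subgroup
#' sensitivities re-using the cutoffs fixed on all controls (never refit per
#' subgroup), and screening PPV/NPV at a stated prevalence.
#'
#' @param scores,labels Scores and binary labels.
#' @param specificity Specificity levels.
#' @param subgroups Optional factor (NA for controls): per-level sensitivities.
#' @param prevalence Screening prevalence for PPV/NPV (default 0.01).
#' @param ci CI method for sensitivities.
#' @return Object of class `mced_eval`.
#' @export
evaluate_score <- function(scores, labels, specificity = c(0.95, 0.99),
                           subgroups = NULL, prevalence = 0.01,
                           ci = "wald") {
  roc <- roc_auc(scores, labels)
  sens <- do.call(rbind, lapply(specificity, function(sp) {
    sensitivity_at_specificity(scores, labels, sp, ci = ci)
  }))
  pn <- t(vapply(seq_len(nrow(sens)), function(i) {
    ppv_npv(sens$sensitivity[i], sens$specificity[i], prevalence)
  }, numeric(2)))
  sens$ppv <- pn[, 1]; sens$npv <- pn[, 2]
  sub_tab <- NULL
  if (!is.null(subgroups)) {
    labels <- as.integer(labels)
    rows <- list()
    for (sp in specificity) {
      cutoff <- set_cutoffs(scores[labels == 0], sp)[[1]]
      for (g in stats::na.omit(unique(subgroups[labels == 1]))) {
        idx <- which(labels == 1 & subgroups == g)
        det <- sum(scores[idx] > cutoff)
        cib <- binomial_ci(det, length(idx), method = ci)
        rows[[length(rows) + 1]] <- data.frame(
          subgroup = as.character(g), specificity = sp,
          sensitivity = det / length(idx),
          ci_low = cib[1], ci_high = cib[2], n = length(idx))
      }
    }
    sub_tab <- do.call(rbind, rows)
  }
  structure(list(roc = roc, sensitivity = sens, subgroups = sub_tab,
                 prevalence = prevalence), class = "mced_eval")
}

#' @export
print.mced_eval <- function(x, ...) {
  print(x$roc)
  df <- x$sensitivity
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  sens at %g%% spec: %.1f%% (CI %.1f-%.1f%%); PPV %.1f%% / NPV %.1f%% at %g%% prevalence\n",
                100 * df$specificity[i], 100 * df$sensitivity[i],
                100 * df$ci_low[i], 100 * df$ci_high[i],
                100 * df$ppv[i], 100 * df$npv[i], 100 * x$prevalence))
  }
  if (!is.null(x$subgroups)) {
    cat("  subgroup sensitivities (cutoff fixed on all controls):\n")
    print(x$subgroups, row.names = FALSE)
  }
  invisible(x)
}

#' Bootstrap internal validation of the score-building pipeline
#'
#' Repeats the whole construction (reference fit, forward selection with the
#' one-SE rule under a size cap, projection, scoring) on bootstrap resamples
#' and records AUC, sensitivity at 95% specificity and scaled Brier on the
#' bootstrap, original and assessment (out-of-bag) sets, plus the selected
#' size. Optimism is reported under both conventions: mean(bootstrap -
#' original) and mean(bootstrap - assessment).
#'
#' @param X,y Candidate matrix and labels of the original cohort.
#' @param B Number of bootstraps (>= 1; scaled-down runs are recorded as such).
#' @param prior t prior; the historical default here is df = 3.
#' @param cap_fluid Fluid-specific cap (51 plasma, 22 urine, 18 combined).
#' @param K,nclusters,draws,chains,ndraws Reduced-effort settings passed to
#'   the inner builds.
#' @param seed Integer seed.
#' @return Object of class `mced_bootstrap`: per-bootstrap table, apparent
#'   metrics, optimism estimates and optimism-corrected AUC.
#' @export
bootstrap_validate <- function(X, y, B = 100, prior = list(df = 3, scale = 2.5),
                               cap_fluid = 18, K = 5, nclusters = 5,
                               draws = 150, chains = 2, ndraws = 100,
                               seed = 1) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  X <- as.matrix(X); y <- as.integer(y)
  n <- length(y)
  build_once <- function(Xb, yb, sd) {
    cap <- max(1, min(floor(sum(yb == 1) / 10), cap_fluid, ncol(Xb)))
    build_score(Xb, yb, prior = prior, cap = cap, K = K,
                nclusters = nclusters, ndraws = ndraws,
                chains = chains, draws = draws, seed = sd)
  }
  metrics <- function(model, Xe, ye) {
    sc <- predict(model, as.data.frame(Xe))
    c(auc = roc_auc(sc, ye)$auc,
      sens95 = sensitivity_at_specificity(sc, ye, 0.95)$sensitivity,
      brier_s = scaled_brier(stats::plogis(sc), ye))
  }
  apparent_model <- build_once(X, y, derive_seed(seed, 0))
  apparent <- metrics(apparent_model, X, y)
  rows <- vector("list", B)
  b <- 0; tries <- 0
  while (b < B) {
    tries <- tries + 1
    if (tries > 20 * B) stop("too many degenerate bootstrap samples", call. = FALSE)
    idx <- with_seed(derive_seed(seed, tries), sample.int(n, n, replace = TRUE))
    if (length(unique(y[idx])) < 2) next  # one-class resample: redraw
    oob <- setdiff(seq_len(n), unique(idx))
    if (length(oob) < 10 || length(unique(y[oob])) < 2) next
    b <- b + 1
    model <- build_once(X[idx, , drop = FALSE], y[idx], derive_seed(seed, 1000 + b))
    mb <- metrics(model, X[idx, , drop = FALSE], y[idx])
    mo <- metrics(model, X, y)
    ma <- metrics(model, X[oob, , drop = FALSE], y[oob])
    rows[[b]] <- data.frame(bootstrap = b, size = model$size,
                            auc_boot = mb[1], auc_orig = mo[1], auc_assess = ma[1],
                            sens_boot = mb[2], sens_orig = mo[2], sens_assess = ma[2],
                            brier_boot = mb[3], brier_orig = mo[3], brier_assess = ma[3])
  }
  tab <- do.call(rbind, rows)
  optim_orig <- colMeans(tab[, c("auc_boot", "sens_boot", "brier_boot")]) -
    colMeans(tab[, c("auc_orig", "sens_orig", "brier_orig")])
  optim_assess <- colMeans(tab[, c("auc_boot", "sens_boot", "brier_boot")]) -
    colMeans(tab[, c("auc_assess", "sens_assess", "brier_assess")])
  names(optim_orig) <- names(optim_assess) <- c("auc", "sens95", "brier_s")
  structure(list(B = B, table = tab, apparent = apparent,
                 optimism_vs_original = optim_orig,
                 optimism_vs_assessment = optim_assess,
                 corrected_auc = unname(apparent["auc"] - optim_orig["auc"]),
                 mean_assessment_auc = mean(tab$auc_assess),
                 prior = prior, seed = seed),
            class = "mced_bootstrap")
}

#' @export
print.mced_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap internal validation (B = %d)\n", x$B))
  cat(sprintf("  apparent AUC %.3f | optimism (vs original) %.3f | corrected AUC %.3f\n",
              x$apparent["auc"], x$optimism_vs_original["auc"], x$corrected_auc))
  cat(sprintf("  mean assessment (out-of-bag) AUC %.3f | median selected size %g\n",
              x$mean_assessment_auc, stats::median(x$table$size)))
  invisible(x)
}

#' Kendall correlation with permutation test and Holm correction
#'
#' Kendall's tau-b between a score and one or more covariates, permutation
#' p-values p = (1 + #{|tau_perm| >= |tau_hat|}) / (n_perm + 1), Holm-adjusted
#' across covariates.
#'
#' @param score Numeric score vector.
#' @param covariates Data.frame (or single vector) of covariates.
#' @param n_perm Number of permutations (>= 999).
#' @param seed Integer seed.
#' @return Data.frame: covariate, tau, p_perm, p_holm.
#' @export
kendall_confounder_test <- function(score, covariates, n_perm = 999, seed = 1) {
  if (!is.data.frame(covariates)) covariates <- data.frame(covariate = covariates)
  if (length(score) < 10) stop("need n >= 10", call. = FALSE)
  if (n_perm < 999) stop("need n_perm >= 999", call. = FALSE)
  taus <- numeric(ncol(covariates)); ps <- numeric(ncol(covariates))
  with_seed(seed, {
    for (j in seq_len(ncol(covariates))) {
      v <- covariates[[j]]
      ok <- !is.na(v) & !is.na(score)
      if (length(unique(v[ok])) < 2) stop("constant covariate: ",
                                          names(covariates)[j], call. = FALSE)
      t0 <- stats::cor(score[ok], v[ok], method = "kendall")
      tp <- replicate(n_perm,
                      stats::cor(score[ok], sample(v[ok]), method = "kendall"))
      taus[j] <- t0
      ps[j] <- (1 + sum(abs(tp) >= abs(t0))) / (n_perm + 1)
    }
  })
  data.frame(covariate = names(covariates), tau = taus, p_perm = ps,
             p_holm = stats::p.adjust(ps, method = "holm"))
}
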