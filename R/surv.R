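# Overall-survival machinery: Kaplan-Meier estimation with reverse-KM median
# follow-up, log-rank testing, Cox proportional-hazards models with a 3-knot
# restricted cubic spline for age (Efron ties), score dichotomization at the
# 95%-specificity cutoff, Schoenfeld proportional-hazards checks, and
# bootstrap internal validation of the Cox model via Somers' Dxy optimism.

#' Restricted cubic spline basis (3 knots)
#'
#' Harrell's restricted cubic spline with knots at the 0.1/0.5/0.9 quantiles
#' by default: a linear term plus one nonlinear term, both scaled to SD 1
#' ("scaled splined" covariate).
#'
#' @param x Numeric vector.
#' @param knots Optional length-3 knot vector.
#' @return Matrix with columns `lin` and `nl`, attribute `knots`.
#' @export
rcs3 <- function(x, knots = NULL) {
  knots <- knots %||% unname(stats::quantile(x, c(0.1, 0.5, 0.9), na.rm = TRUE))
  stopifnot(length(knots) == 3)
  k1 <- knots[1]; k2 <- knots[2]; k3 <- knots[3]
  cub <- function(u) pmax(u, 0)^3
  nl <- (cub(x - k1) - cub(x - k2) * (k3 - k1) / (k3 - k2) +
           cub(x - k3) * (k2 - k1) / (k3 - k2)) / (k3 - k1)^2
  b <- cbind(lin = x, nl = nl)
  b <- scale(b)
  attr(b, "knots") <- knots
  b
}

#' Kaplan-Meier estimates with median follow-up
#'
#' Product-limit survival curves per group, median survival, and median
#' follow-up time by the reverse Kaplan-Meier method (censoring indicator
#' flipped).
#'
#' @param time Follow-up times (months).
#' @param event Event indicator (1 = death).
#' @param group Optional grouping factor.
#' @return Object of class `gag_km`: `fit` (a [survival::survfit] object),
#'   `table` (time, at-risk, survival, CI per group), `median_survival`,
#'   `median_followup`.
#' @export
km_estimate <- function(time, event, group = NULL) {
  stopifnot(all(time >= 0, na.rm = TRUE))
  df <- data.frame(time = time, event = as.integer(event))
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
  } else {
    df$group <- factor(group)
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  }
  s <- summary(fit)
  tab <- if (length(s$time)) {
    data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
               survival = s$surv, ci_low = s$lower, ci_high = s$upper,
               group = if (!is.null(s$strata)) as.character(s$strata) else "all")
  } else {
    data.frame(time = numeric(0), n_risk = numeric(0), n_event = numeric(0),
               survival = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
               group = character(0))
  }
  med <- summary(fit)$table
  med_surv <- if (is.matrix(med)) med[, "median"] else med[["median"]]
  rev_fit <- survival::survfit(survival::Surv(time, 1 - as.integer(event)) ~ 1, data = df)
  med_fu <- unname(summary(rev_fit)$table["median"])
  structure(list(fit = fit, table = tab, median_survival = med_surv,
                 median_followup = med_fu),
            class = "gag_km")
}

#' @export
print.gag_km <- function(x, ...) {
  cat("Kaplan-Meier estimate; median follow-up (reverse KM):",
      round(x$median_followup, 1), "months\n")
  print(x$fit)
  invisible(x)
}

#' @export
plot.gag_km <- function(x, ...) {
  graphics::plot(x$fit, xlab = "Months", ylab = "Overall survival", ...)
  invisible(x)
}

#' Log-rank test
#'
#' @param time,event Survival outcome.
#' @param group Grouping factor (>= 2 non-empty groups).
#' @return List: `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (any(table(group) == 0) || nlevels(droplevels(group)) < 2) {
    stop("log-rank test needs >= 2 non-empty groups", call. = FALSE)
  }
  df <- data.frame(time = time, event = as.integer(event), group = group)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  dfree <- length(sd_$n) - 1
  list(chisq = sd_$chisq, df = dfree,
       p = stats::pchisq(sd_$chisq, dfree, lower.tail = FALSE))
}

#' Multivariable Cox proportional-hazards fit
#'
#' Cox model with Efron tie handling on a survival design: score (continuous
#' or dichotomized), age as a scaled 3-knot restricted cubic spline, sex,
#' late-stage indicator and optional cancer-type indicator. Warns when there
#' are fewer than 10 events per covariate; flags monotone likelihood
#' (separation).
#'
#' @param time,event Survival outcome (months, 1 = death).
#' @param covariates Data.frame of covariates; a numeric `age` column is
#'   expanded to the spline basis automatically.
#' @param spline_age Expand `age` with [rcs3()]?
#' @param ties Tie-handling method for [survival::coxph] (default Efron).
#' @return Object of class `gag_cox`: coefficient table with HRs and 95% CIs,
#'   the underlying [survival::coxph] fit, log-rank/Wald p-values.
#' @export
cox_fit <- function(time, event, covariates, spline_age = TRUE, ties = "efron") {
  df <- as.data.frame(covariates)
  keep <- stats::complete.cases(df) & !is.na(time) & !is.na(event)
  n_drop <- sum(!keep)
  if (n_drop > 0) message("omitting ", n_drop, " rows with missing data")
  df <- df[keep, , drop = FALSE]
  time <- time[keep]; event <- as.integer(event)[keep]
  if (sum(event) == 0) stop("no events", call. = FALSE)
  if (spline_age && "age" %in% names(df)) {
    b <- rcs3(df$age)
    df$age <- NULL
    df$age_lin <- b[, "lin"]; df$age_nl <- b[, "nl"]
  }
  n_cov <- ncol(df)
  if (sum(event) < 10 * n_cov) {
    warning(sprintf("only %d events for %d covariates (< 10 per covariate)",
                    sum(event), n_cov), call. = FALSE)
  }
  df$.time <- time; df$.event <- event
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(setdiff(names(df), c(".time", ".event")),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties)
  sf <- summary(fit)
  separated <- any(abs(stats::coef(fit)) > 15, na.rm = TRUE)
  if (separated) warning("possible monotone likelihood (separation)", call. = FALSE)
  tab <- data.frame(term = rownames(sf$coefficients),
                    coef = sf$coefficients[, "coef"],
                    hr = sf$coefficients[, "exp(coef)"],
                    se = sf$coefficients[, "se(coef)"],
                    hr_low = exp(sf$coefficients[, "coef"] - 1.96 * sf$coefficients[, "se(coef)"]),
                    hr_high = exp(sf$coefficients[, "coef"] + 1.96 * sf$coefficients[, "se(coef)"]),
                    p = sf$coefficients[, "Pr(>|z|)"])
  rownames(tab) <- NULL
  structure(list(fit = fit, coefficients = tab,
                 logrank_p = sf$sctest[["pvalue"]],
                 wald_p = sf$waldtest[["pvalue"]],
                 loglik = fit$loglik[2], n = fit$n, n_events = sum(event),
                 ties = ties, separated = separated),
            class = "gag_cox")
}

#' @export
print.gag_cox <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): %d subjects, %d events; log-rank p = %.3g\n",
              x$ties, x$n, x$n_events, x$logrank_p))
  print(transform(x$coefficients, coef = round(coef, 3), hr = round(hr, 3),
                  hr_low = round(hr_low, 3), hr_high = round(hr_high, 3),
                  se = round(se, 3), p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
coef.gag_cox <- function(object, ...) stats::coef(object$fit)

#' Dichotomize scores at a cutoff and compare survival
#'
#' Splits patients into "high" (score above the cutoff, i.e. detected) vs
#' "low" groups, fits Kaplan-Meier curves, estimates the hazard ratio of the
#' low vs high group from a single-covariate Cox model and reports the
#' log-rank p-value. The cutoff is taken as given (e.g. the 95%-specificity
#' cutoff fixed on the full control set) and is never re-derived on subsets.
#'
#' @param scores Numeric scores.
#' @param cutoff Score cutoff (e.g. `model$cutoffs[["spec95"]]`).
#' @param time,event Survival outcome.
#' @return Object of class `gag_km_compare`: `km`, `hr_low_vs_high` with CI,
#'   `logrank`.
#' @export
dichotomize_and_compare <- function(scores, cutoff, time, event) {
  grp <- factor(ifelse(scores > cutoff, "high", "low"), levels = c("high", "low"))
  if (any(table(grp) == 0)) {
    stop("single stratum: all scores on one side of the cutoff", call. = FALSE)
  }
  km <- km_estimate(time, event, grp)
  cx <- cox_fit(time, event, data.frame(low = as.integer(grp == "low")),
                spline_age = FALSE)
  lr <- logrank_test(time, event, grp)
  structure(list(km = km, cutoff = cutoff,
                 hr_low_vs_high = cx$coefficients$hr[1],
                 hr_ci = c(cx$coefficients$hr_low[1], cx$coefficients$hr_high[1]),
                 logrank = lr, cox = cx),
            class = "gag_km_compare")
}

#' @export
print.gag_km_compare <- function(x, ...) {
  cat(sprintf("Low vs high score: HR = %.2f (95%% CI %.2f-%.2f), log-rank p = %.3g\n",
              x$hr_low_vs_high, x$hr_ci[1], x$hr_ci[2], x$logrank$p))
  invisible(x)
}

#' Proportional-hazards check (Schoenfeld residuals)
#'
#' Tests correlation between scaled Schoenfeld residuals and transformed
#' survival time (KM transform by default), per covariate and globally.
#'
#' @param fit A `gag_cox` object.
#' @param transform Time transform passed to [survival::cox.zph].
#' @param alpha Significance threshold used in the report (default 0.01).
#' @return Data.frame: term, chisq, df, p, plus `global_ok` attribute
#'   (global p > alpha).
#' @export
ph_check <- function(fit, transform = "km", alpha = 0.01) {
  if (fit$n_events == 0) stop("no events", call. = FALSE)
  z <- survival::cox.zph(fit$fit, transform = transform)
  tab <- as.data.frame(z$table)
  tab$term <- rownames(z$table)
  rownames(tab) <- NULL
  structure(tab[, c("term", "chisq", "df", "p")],
            global_ok = tab$p[tab$term == "GLOBAL"] > alpha,
            alpha = alpha)
}

#' Bootstrap internal validation of a Cox model (Somers' Dxy)
#'
#' Refits the Cox model on bootstrap resamples, compares Somers' Dxy rank
#' correlation on the bootstrap sample (apparent) vs the original data
#' (test), and reports the optimism and the relative correction; corrections
#' below 20% of the apparent Dxy are conventionally acceptable.
#'
#' @param time,event,covariates As in [cox_fit()].
#' @param B Number of bootstraps.
#' @param seed Integer seed.
#' @param spline_age Passed to [cox_fit()].
#' @return List: `dxy_apparent`, `optimism`, `dxy_corrected`,
#'   `correction_fraction`, `B`.
#' @export
cox_internal_validation <- function(time, event, covariates, B = 100, seed = 1,
                                    spline_age = TRUE) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  covariates <- as.data.frame(covariates)
  full <- cox_fit(time, event, covariates, spline_age = spline_age)
  d_app <- 2 * (survival::concordance(full$fit)$concordance - 0.5)
  opt <- numeric(B)
  n <- length(time)
  b <- 0; tries <- 0
  while (b < B) {
    tries <- tries + 1
    if (tries > 20 * B) stop("too many degenerate bootstrap samples", call. = FALSE)
    idx <- with_seed(derive_seed(seed, tries), sample.int(n, n, replace = TRUE))
    if (sum(event[idx]) < 5) next
    fb <- tryCatch(
      suppressWarnings(cox_fit(time[idx], event[idx],
                               covariates[idx, , drop = FALSE],
                               spline_age = spline_age)),
      error = function(e) NULL)
    if (is.null(fb)) next
    b <- b + 1
    d_boot <- 2 * (survival::concordance(fb$fit)$concordance - 0.5)
    # evaluate the bootstrap model on the original data
    lp_orig <- tryCatch({
      nd <- covariates
      if (spline_age && "age" %in% names(nd)) {
        bb <- rcs3(nd$age, knots = NULL)
        nd$age <- NULL; nd$age_lin <- bb[, "lin"]; nd$age_nl <- bb[, "nl"]
      }
      keep <- stats::complete.cases(nd)
      drop(as.matrix(nd[keep, fb$coefficients$term, drop = FALSE]) %*%
             fb$coefficients$coef)
    }, error = function(e) NULL)
    if (is.null(lp_orig)) { b <- b - 1; next }
    keep <- stats::complete.cases(covariates)
    cc <- survival::concordance(
      survival::Surv(time[keep], event[keep]) ~ lp_orig, reverse = TRUE)
    d_orig <- 2 * (cc$concordance - 0.5)
    opt[b] <- d_boot - d_orig
  }
  optimism <- mean(opt)
  corrected <- d_app - optimism
  list(dxy_apparent = d_app, optimism = optimism, dxy_corrected = corrected,
       correction_fraction = if (abs(d_app) > 0) optimism / d_app else NA_real_,
       B = B)
}
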