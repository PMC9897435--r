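# Survival machinery: hand-computed product-limit and partial-likelihood
# oracles, dichotomized comparisons, proportional-hazards checks, Dxy
# optimism validation.

test_that("Kaplan-Meier equals the hand-computed product limit", {
  # no censoring: S = 2/3, 1/3, 0
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$table$survival, c(2/3, 1/3, 0))
  # censored fixture, computed by hand:
  # t=1 (event, 5 at risk) -> 4/5; t=3 (event, 3 at risk) -> 4/5 * 2/3
  # t=5 (event, 1 at risk) -> 0
  km2 <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
  expect_equal(km2$table$survival, c(4/5, 4/5 * 2/3, 0))
  # no events: survival stays at 1 (no event rows in the table)
  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(km3$table), 0L)
  # identical groups give identical curves
  tm <- c(1, 2, 3, 4); ev <- c(1, 1, 0, 1)
  km4 <- km_estimate(c(tm, tm), c(ev, ev), rep(c("a", "b"), each = 4))
  sa <- km4$table[km4$table$group == "group=a", "survival"]
  sb <- km4$table[km4$table$group == "group=b", "survival"]
  expect_equal(sa, sb)
})

test_that("median follow-up uses the reverse Kaplan-Meier", {
  # everyone censored at their time: reverse KM is the plain KM of times
  km <- km_estimate(c(2, 4, 6, 8), c(0, 0, 0, 0))
  expect_equal(km$median_followup, 5)
})

test_that("log-rank matches a hand-computed table and the Cox score test", {
  # hand-worked 2-group example, no ties:
  # group A times 1,3 (events), group B times 2,4 (events)
  # observed A = 2; expected A = 2/4 + 1/3 + 0/2 + ... computed stepwise:
  # t=1: atrisk A2 B2, eA=1/2; t=2: A1 B2, eA=1/3; t=3: A1 B1, eA=1/2; t=4: eA=0
  time <- c(1, 3, 2, 4); event <- rep(1, 4); grp <- c("A", "A", "B", "B")
  lr <- logrank_test(time, event, grp)
  eA <- 1/2 + 1/3 + 1/2
  vA <- (1/2) * (1/2) + (1/3) * (2/3) + (1/2) * (1/2)  # hypergeometric vars
  expect_equal(lr$chisq, (2 - eA)^2 / vA, tolerance = 1e-9)
  # equivalence with the Cox score test on untied data
  withr::with_seed(41, {
    tm <- stats::rexp(60); ev <- stats::rbinom(60, 1, 0.7); g <- rep(0:1, 30)
  })
  lr2 <- logrank_test(tm, ev, g)
  cx <- survival::coxph(survival::Surv(tm, ev) ~ g, ties = "efron")
  expect_equal(lr2$chisq, summary(cx)$sctest[["test"]], tolerance = 1e-6)
  expect_error(logrank_test(tm, ev, rep("a", 60)), "2 non-empty")
})

test_that("Cox coefficients match an independent partial-likelihood oracle", {
  withr::with_seed(42, {
    n <- 50
    x1 <- stats::rnorm(n); x2 <- stats::rbinom(n, 1, 0.5)
    tm <- stats::rexp(n, exp(0.7 * x1 - 0.4 * x2))
    ev <- stats::rbinom(n, 1, 0.8)
  })
  fit <- suppressWarnings(cox_fit(tm, ev, data.frame(x1 = x1, x2 = x2),
                                  spline_age = FALSE))
  # independent oracle: direct optimisation of the Breslow/Efron-free partial
  # likelihood (data are untied, so all tie conventions coincide)
  neg_pl <- function(b) {
    eta <- b[1] * x1 + b[2] * x2
    s <- 0
    for (i in which(ev == 1)) {
      rs <- tm >= tm[i]
      s <- s - eta[i] + log(sum(exp(eta[rs])))
    }
    s
  }
  oracle <- stats::optim(c(0, 0), neg_pl, method = "BFGS",
                         control = list(reltol = 1e-14))$par
  expect_lt(max(abs(unname(fit$coefficients$coef) - oracle)), 1e-4)
  # duplicated data: same estimate, SE shrinks by ~sqrt(2). Duplication makes
  # every event time tied, so the comparison uses Breslow ties, under which
  # the duplicated partial likelihood is a constant shift of the original.
  fit <- suppressWarnings(cox_fit(tm, ev, data.frame(x1 = x1, x2 = x2),
                                  spline_age = FALSE, ties = "breslow"))
  fit2 <- suppressWarnings(cox_fit(c(tm, tm), c(ev, ev),
                                   data.frame(x1 = c(x1, x1), x2 = c(x2, x2)),
                                   spline_age = FALSE, ties = "breslow"))
  expect_equal(fit$coefficients$coef, fit2$coefficients$coef, tolerance = 1e-6)
  expect_equal(fit$coefficients$se / fit2$coefficients$se, rep(sqrt(2), 2),
               tolerance = 0.02)
})

test_that("null covariates produce HR intervals covering 1", {
  withr::with_seed(43, {
    cover <- vapply(1:10, function(s) {
      n <- 150
      x <- stats::rnorm(n)
      tm <- stats::rexp(n); ev <- stats::rbinom(n, 1, 0.7)
      cf <- suppressWarnings(cox_fit(tm, ev, data.frame(x = x), spline_age = FALSE))
      cf$coefficients$hr_low[1] <= 1 && cf$coefficients$hr_high[1] >= 1
    }, logical(1))
    expect_gte(mean(cover), 0.9)
  })
})

test_that("age enters as a scaled 3-knot restricted cubic spline", {
  withr::with_seed(44, age <- stats::runif(300, 35, 85))
  b <- rcs3(age)
  expect_equal(colnames(b), c("lin", "nl"))
  expect_equal(unname(apply(b, 2, stats::sd)), c(1, 1), tolerance = 1e-9)
  # linear beyond the last knot: second differences of nl vanish there
  ks <- attr(b, "knots")
  xs <- seq(ks[3] + 1, ks[3] + 10, by = 1)
  nl <- rcs3(c(age, xs), knots = ks)[301:310, "nl"]
  expect_lt(max(abs(diff(diff(nl)))), 1e-8)
  # cox_fit expands age automatically
  withr::with_seed(45, {
    tm <- stats::rexp(300); ev <- stats::rbinom(300, 1, 0.6)
  })
  cf <- suppressWarnings(cox_fit(tm, ev, data.frame(age = age, sex = rep(0:1, 150))))
  expect_true(all(c("age_lin", "age_nl") %in% cf$coefficients$term))
})

test_that("dichotomized comparison recovers a planted HR and guards degenerate input", {
  withr::with_seed(46, {
    hits <- vapply(1:20, function(s) {
      high <- stats::runif(400) < 0.5
      sv <- generate_survival(high, hr_low_vs_high = 0.6, seed = 300 + s)
      cmp <- dichotomize_and_compare(ifelse(high, 1, -1), 0,
                                     sv$os_months, sv$os_event)
      cmp$hr_ci[1] <= 0.6 && 0.6 <= cmp$hr_ci[2]
    }, logical(1))
    expect_gte(mean(hits), 0.9)
  })
  expect_error(dichotomize_and_compare(c(-1, -2, -3), 0, c(1, 2, 3), c(1, 1, 0)),
               "single stratum")
})

test_that("Schoenfeld check separates proportional from time-varying hazards", {
  withr::with_seed(47, {
    ok_prop <- vapply(1:10, function(s) {
      n <- 300
      x <- stats::rnorm(n)
      tm <- stats::rexp(n, exp(0.5 * x)); ev <- rep(1, n)
      fit <- suppressWarnings(cox_fit(tm, ev, data.frame(x = x), spline_age = FALSE))
      tab <- ph_check(fit)
      tab$p[tab$term == "GLOBAL"] > 0.01
    }, logical(1))
    expect_gte(mean(ok_prop), 0.9)
    # planted non-proportionality: crossing Weibull hazards between groups
    bad <- vapply(1:10, function(s) {
      n <- 500
      x <- stats::rbinom(n, 1, 0.5)
      tm <- ifelse(x == 1, stats::rweibull(n, shape = 3, scale = 1),
                   stats::rweibull(n, shape = 0.6, scale = 1))
      fit <- suppressWarnings(cox_fit(tm, rep(1, n), data.frame(x = x),
                                      spline_age = FALSE))
      tab <- ph_check(fit)
      tab$p[tab$term == "GLOBAL"] < 0.01
    }, logical(1))
    expect_gte(mean(bad), 0.8)
  })
  expect_error(cox_fit(c(1, 2), c(0, 0), data.frame(x = 1:2), spline_age = FALSE),
               "no events")
})

test_that("Cox internal validation reports Dxy optimism", {
  withr::with_seed(48, {
    n <- 250
    x <- stats::rnorm(n)
    tm <- stats::rexp(n, exp(0.9 * x))
    ev <- as.integer(tm < stats::quantile(tm, 0.6))
  })
  civ <- suppressWarnings(suppressMessages(
    cox_internal_validation(tm, ev, data.frame(score = x), B = 30, seed = 49,
                            spline_age = FALSE)))
  expect_lt(abs(civ$correction_fraction), 0.2)  # strong signal, large n
  expect_equal(civ$dxy_corrected, civ$dxy_apparent - civ$optimism)
  expect_error(cox_internal_validation(tm, ev, data.frame(score = x), B = 0),
               "B must be")
})
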