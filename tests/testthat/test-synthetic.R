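# Synthetic cohort generators: reproducibility, null soundness, marginal
# shape, confounder calibration, survival and mouse ground truth.

test_that("identical (config, seed) regenerates identical cohorts", {
  a <- generate_development_cohort(seed = 7)
  b <- generate_development_cohort(seed = 7)
  expect_identical(a$cohort, b$cohort)
  c <- generate_development_cohort(seed = 8)
  expect_false(identical(a$cohort, c$cohort))
  # generator emits only raw concentrations; derived features come later
  expect_false("total_cs" %in% names(a$cohort))
})

test_that("all-zero effects make cancer and healthy distributions equal in law", {
  cfg <- gag_sim_config(effects = gagmced:::zero_effects())
  ps <- vapply(1:5, function(s) {
    syn <- generate_development_cohort(cfg, seed = 100 + s)
    pl <- syn$cohort[syn$cohort$fluid == "plasma", ]
    suppressWarnings(stats::ks.test(pl$cs_0s[pl$diagnosis == "healthy"],
                                    pl$cs_0s[pl$diagnosis == "cancer"])$p.value)
  }, numeric(1))
  # p-values should look uniform, not pile up at 0
  expect_gt(max(ps), 0.2)
  expect_gt(mean(ps > 0.01), 0.5)
})

test_that("unknown feature in the effect matrix is rejected", {
  eff <- default_effects()
  colnames(eff$plasma)[1] <- "cs_9s"
  expect_error(gag_sim_config(effects = eff), "unknown feature")
})

test_that("healthy marginals carry the configured skewness", {
  cfg <- gag_sim_config(n_healthy = 2000, n_per_type = 0, fluids = "plasma")
  syn <- generate_development_cohort(cfg, seed = 5)
  x <- syn$cohort$cs_0s
  g1 <- mean((x - mean(x))^3) / stats::sd(x)^3
  expect_equal(g1, gagmced:::sn_moments(4)$skewness, tolerance = 0.3)
})

test_that("validation confounder targets are met on average", {
  # zero confounder effects: score and CRP are independent
  cfg0 <- gag_sim_config(crp_tau = 0, hdl_tau = 0)
  v0 <- generate_validation_cohort(cfg0, seed = 1, n_controls = 150, n_cases = 150)
  bs0 <- bayes_score(v0)
  crp0 <- v0$cohort$crp_mg_dl[match(names(bs0), v0$cohort$subject_id)]
  expect_lt(abs(stats::cor(bs0, crp0, method = "kendall")), 0.1)
  # default targets (tau 0.29 CRP, -0.16 HDL) recovered on average over seeds
  res <- vapply(1:20, function(s) {
    v <- generate_validation_cohort(seed = s)
    bs <- bayes_score(v)
    idx <- match(names(bs), v$cohort$subject_id)
    c(stats::cor(bs, v$cohort$crp_mg_dl[idx], method = "kendall"),
      stats::cor(bs, v$cohort$hdl_mmol_l[idx], method = "kendall"))
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - 0.29), 0.08)
  expect_lt(abs(mean(res[2, ]) - (-0.16)), 0.08)
  expect_error(gag_sim_config(crp_tau = 1.2), "tau")
})

test_that("low-CRP/high-HDL subgroup removes cancer-like control outliers", {
  # the inflammation/metabolic-syndrome trim lowers the upper tail of the
  # control score distribution (and hence the 95%-specificity cutoff); raw
  # variance is dominated by the heavy LOD-driven left tail, so the cutoff
  # location is the stable expression of the planted confounder structure
  res <- vapply(1:5, function(s) {
    v <- generate_validation_cohort(seed = 200 + s)
    bs <- bayes_score(v)
    meta <- v$cohort[match(names(bs), v$cohort$subject_id), ]
    ctrl <- meta$diagnosis == "healthy"
    sub <- ctrl & meta$crp_mg_dl < 4 & meta$hdl_mmol_l > 1
    c(full = unname(stats::quantile(bs[ctrl], 0.95)),
      sub = unname(stats::quantile(bs[sub], 0.95)),
      removed_high = mean(bs[ctrl & !sub] > stats::median(bs[ctrl])))
  }, numeric(3))
  expect_lt(mean(res["sub", ]), mean(res["full", ]))
  # the trimmed-away controls are predominantly cancer-like scorers
  expect_gt(mean(res["removed_high", ]), 0.5)
})

test_that("survival generator plants the requested hazard structure", {
  # null: HR = 1 gives no systematic log-rank signal
  withr::with_seed(11, {
    p_null <- vapply(1:10, function(s) {
      high <- stats::runif(300) < 0.5
      sv <- generate_survival(high, hr_low_vs_high = 1, seed = s)
      logrank_test(sv$os_months, sv$os_event, high)$p
    }, numeric(1))
    expect_lte(mean(p_null < 0.05), 0.3)
  })
  # planted HR 0.5, n = 400, ~50% events: Cox estimate lands in [0.35, 0.70]
  withr::with_seed(12, {
    est <- vapply(1:20, function(s) {
      high <- stats::runif(400) < 0.5
      sv <- generate_survival(high, hr_low_vs_high = 0.5, seed = 50 + s)
      cf <- suppressWarnings(cox_fit(sv$os_months, sv$os_event,
                                     data.frame(low = as.integer(!high)),
                                     spline_age = FALSE))
      cf$coefficients$hr[1]
    }, numeric(1))
    expect_gte(mean(est >= 0.35 & est <= 0.70), 0.9)
  })
  # complete censoring: zero events, downstream fits refuse
  high <- rep(c(TRUE, FALSE), 50)
  sv0 <- generate_survival(high, seed = 1, event_frac = 0)
  expect_equal(sum(sv0$os_event), 0L)
  expect_error(cox_fit(sv0$os_months, sv0$os_event,
                       data.frame(low = as.integer(!high)), spline_age = FALSE),
               "no events")
})

test_that("mouse generator is reproducible and dropout removes cage urine", {
  a <- generate_mouse(seed = 3)
  b <- generate_mouse(seed = 3)
  expect_identical(a$table, b$table)
  expect_equal(a$truth$pct_change$plasma[4], 148)
  expect_equal(a$truth$pct_change$urine[4], 116)
  # dropout: mouse 3 (cage 2) dies before metastasis
  d <- generate_mouse(seed = 3, dropout = list(mouse = 3, from = "metastasis"))
  tab <- cage_filter(d$table)
  expect_false(any(tab$fluid == "urine" & tab$unit_id == "cage02" &
                     tab$timepoint == "metastasis"))
  expect_true(any(tab$fluid == "urine" & tab$unit_id == "cage02" &
                    tab$timepoint == "postop"))
  # plasma rows of the dead mouse are gone too, but other plasma rows remain
  expect_false(any(tab$fluid == "plasma" & tab$unit_id == "mouse03" &
                     tab$timepoint == "metastasis"))
  expect_equal(sum(tab$fluid == "plasma" & tab$timepoint == "metastasis"), 19L)
})
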