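# Feature calculus: the 17 -> 39 GAGome expansion, detectability filtering,
# standardization and outlier screening.

test_that("derived features follow the charge/fraction/ratio definitions", {
  # unsulfated-only: charge must be 0 and the 0S fraction 100%
  f <- compute_features(panel_with(cs_0s = 2))
  expect_equal(f[["total_cs"]], 2)
  expect_equal(f[["frac_cs_0s"]], 100)
  expect_equal(f[["charge_cs"]], 0)
  expect_equal(f[["ratio_4s_0s"]], 0)
  # hand arithmetic: 0S = 4S = 1 -> fractions 50/50, charge 0.5, ratio 1
  f <- compute_features(panel_with(cs_0s = 1, cs_4s = 1))
  expect_equal(f[["total_cs"]], 2)
  expect_equal(f[["frac_cs_0s"]], 50)
  expect_equal(f[["frac_cs_4s"]], 50)
  expect_equal(f[["charge_cs"]], 0.5)
  expect_equal(f[["ratio_4s_0s"]], 1)
  # maximal sulfation: TriS only gives the charge bound 3
  f <- compute_features(panel_with(cs_tris = 5))
  expect_equal(f[["charge_cs"]], 3)
  # zero denominator: ratio undefined, not infinite
  f <- compute_features(panel_with(cs_4s = 1))
  expect_true(is.na(f[["ratio_4s_0s"]]))
  expect_length(f, 39L)
})

test_that("panel validation rejects bad inputs", {
  expect_error(compute_features(panel_with(cs_0s = -1)), "negative")
  bad <- c(panel_with(cs_0s = 1), unknown = 2)
  expect_error(compute_features(bad), "unknown")
  expect_error(compute_features(panel_with(cs_0s = 1)[-1]), "missing")
})

test_that("feature calculus invariants hold on random panels", {
  withr::with_seed(99, {
    for (i in 1:20) {
      x <- stats::setNames(stats::rexp(17, 2), gag_conc_features)
      f <- compute_features(x)
      expect_length(f, 39L)
      # scale invariance of compositional features
      cc <- stats::runif(1, 0.1, 10)
      f2 <- compute_features(x * cc)
      comp <- c("charge_cs", "charge_hs", "ratio_4s_0s", "ratio_6s_0s",
                paste0("frac_cs_", c("0s", "4s", "tris")),
                paste0("frac_hs_", c("0s", "ns")))
      expect_equal(f2[comp], f[comp], tolerance = 1e-12)
      # fractions renormalize to 100
      expect_equal(sum(f[paste0("frac_cs_", c("0s","2s","6s","4s","2s6s","2s4s","4s6s","tris"))]),
                   100, tolerance = 1e-9)
      expect_equal(sum(f[paste0("frac_hs_", c("0s","2s","6s","ns","ns6s","ns2s","2s6s","tris"))]),
                   100, tolerance = 1e-9)
      expect_true(f[["charge_cs"]] >= 0 && f[["charge_cs"]] <= 3)
      expect_true(f[["charge_hs"]] >= 0 && f[["charge_hs"]] <= 3)
    }
  })
  # charge is zero iff all sulfated species are zero
  f <- compute_features(panel_with(cs_0s = 3, hs_0s = 1, ha = 2))
  expect_equal(f[["charge_cs"]], 0)
  f <- compute_features(panel_with(cs_0s = 3, cs_2s = 1e-6))
  expect_gt(f[["charge_cs"]], 0)
})

test_that("detectability uses the per-fluid median rule", {
  mk <- function(vals) {
    df <- as.data.frame(matrix(0.01, length(vals), 17,
                               dimnames = list(NULL, gag_conc_features)))
    df$cs_0s <- vals
    df$fluid <- "plasma"
    add_features(df)
  }
  expect_false(detectability_filter(mk(rep(0.05, 5)))$fluids$plasma$mask[["cs_0s"]])
  # median of {0.05, 0.15, 0.25} = 0.15 > 0.1
  expect_true(detectability_filter(mk(c(0.05, 0.15, 0.25)))$fluids$plasma$mask[["cs_0s"]])
  expect_error(detectability_filter(mk(0.05)[0, ]), "empty")
})

test_that("development-default cohort yields the 6 plasma + 17 urine sets", {
  fx <- dev_cohort()
  pl <- fx$detect$fluids$plasma$detectable
  ur <- fx$detect$fluids$urine$detectable
  expect_length(pl, 6L)
  expect_setequal(pl, c("cs_0s", "cs_4s", "total_cs", "ratio_4s_0s",
                        "frac_cs_0s", "frac_cs_4s"))
  expect_length(ur, 17L)
  expect_setequal(ur, c("cs_0s", "cs_6s", "cs_4s", "cs_2s6s", "hs_0s", "hs_ns",
                        "total_cs", "total_hs", "charge_cs",
                        "ratio_4s_0s", "ratio_6s_0s",
                        "frac_cs_0s", "frac_cs_6s", "frac_cs_4s", "frac_cs_2s6s",
                        "frac_hs_0s", "frac_hs_ns"))
  expect_length(gag_features, 39L)
})

test_that("standardization is exact, reusable and guards zero variance", {
  s <- fit_standardizer(data.frame(x = c(1, 2, 3)), "x")
  expect_equal(predict(s, data.frame(x = c(1, 2, 3)))$x,
               c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  # constant shift leaves z-scores unchanged
  s2 <- fit_standardizer(data.frame(x = c(1, 2, 3) + 10), "x")
  expect_equal(predict(s2, data.frame(x = c(11, 12, 13)))$x,
               predict(s, data.frame(x = c(1, 2, 3)))$x)
  # stored transform reproduces training z-scores
  fx <- dev_cohort()
  pl <- fx$cohort[fx$cohort$fluid == "plasma", ]
  st <- fit_standardizer(pl, c("cs_0s", "cs_4s"))
  z1 <- predict(st, pl)$cs_0s
  z2 <- predict(st, pl)$cs_0s
  expect_identical(z1, z2)
  expect_equal(mean(z1), 0, tolerance = 1e-12)
  expect_error(fit_standardizer(data.frame(x = rep(1, 5)), "x"), "zero-variance.*x")
})

test_that("outlier screen flags gross deviations and spares tight cohorts", {
  # bounded noise: median +/- 5*MAD can never be exceeded
  withr::with_seed(3, {
    n <- 40
    df <- as.data.frame(matrix(stats::runif(n * 17, 0.9, 1.1), n, 17,
                               dimnames = list(NULL, gag_conc_features)))
    df$fluid <- rep(c("plasma", "urine"), each = n / 2)
    df <- add_features(df)
    sc <- outlier_screen(df, detectability_filter(df))
    expect_equal(sum(sc$flag), 0L)
    # a 100x total CS sample is flagged in step 1
    df2 <- df
    df2[1, gag_conc_features] <- df2[1, gag_conc_features] * 100
    df2 <- add_features(df2)
    sc2 <- outlier_screen(df2, detectability_filter(df2))
    expect_true(sc2$flag[1])
    expect_true(any(sc2$details$step == 1))
  })
  expect_error(outlier_screen(data.frame(fluid = rep("plasma", 5))), ">= 10")
})

test_that("planted 10-SD contamination is caught at >= 95%", {
  fx <- dev_cohort()
  coh <- fx$cohort
  withr::with_seed(8, {
    pl_idx <- which(coh$fluid == "plasma")
    bad <- sample(pl_idx, round(0.02 * length(pl_idx)))
    coh$cs_0s[bad] <- coh$cs_0s[bad] + 10 * stats::sd(coh$cs_0s[pl_idx])
    coh <- add_features(coh)
    sc <- outlier_screen(coh, detectability_filter(coh))
    expect_gte(mean(sc$flag[bad]), 0.95)
  })
})
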