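# MCED score machinery: reference model, projection, selection, size rule,
# cutoffs, pruning, serialization.

test_that("reference model calibration behaves like Bayesian logistic regression", {
  # independent response: credible intervals cover zero for >= 90% of features
  dat <- logit_data(n = 400, p = 10, beta = numeric(0), seed = 4)
  y <- withr::with_seed(5, stats::rbinom(400, 1, 0.5))
  fit <- fit_reference(dat$X, y, chains = 2, draws = 400, seed = 6)
  qs <- apply(fit$draws[, -1], 2, stats::quantile, probs = c(0.025, 0.975))
  cover <- mean(qs[1, ] < 0 & qs[2, ] > 0)
  expect_gte(cover, 0.9)
  # a strong true effect is detected
  dat2 <- logit_data(n = 600, p = 5, beta = 2, seed = 7)
  fit2 <- fit_reference(dat2$X, dat2$y, chains = 2, draws = 400, seed = 8)
  q1 <- stats::quantile(fit2$draws[, "f1"], c(0.025, 0.975))
  expect_gt(q1[1], 0)
  expect_error(bayes_logreg(dat2$X, rep(1, 600)), "both classes")
  expect_error(bayes_logreg(cbind(dat2$X, NA), dat2$y), "missing")
})

test_that("duplicating the data shrinks posterior SDs by about sqrt(2)", {
  dat <- logit_data(n = 300, p = 3, beta = 1, seed = 9)
  f1 <- fit_reference(dat$X, dat$y, chains = 2, draws = 500, seed = 10)
  f2 <- fit_reference(rbind(dat$X, dat$X), c(dat$y, dat$y),
                      chains = 2, draws = 500, seed = 11)
  ratio <- apply(f1$draws, 2, stats::sd) / apply(f2$draws, 2, stats::sd)
  expect_equal(unname(ratio), rep(sqrt(2), 4), tolerance = 0.2)
})

test_that("projection identities hold", {
  dat <- logit_data(n = 250, p = 4, beta = c(1.5, -1), seed = 12)
  fit <- fit_reference(dat$X, dat$y, chains = 2, draws = 250, seed = 13)
  # full-set projection reproduces the reference linear predictor per draw
  proj <- project_submodel(fit, colnames(dat$X), ndraws = 200)
  idx <- unique(round(seq(1, nrow(fit$draws), length.out = 200)))
  Xd <- cbind(1, dat$X)
  expect_lt(max(abs(tcrossprod(proj, Xd) - tcrossprod(fit$draws[idx, ], Xd))),
            1e-6)
  # empty subset: intercept-only KL minimizer is logit of the mean probability
  p0 <- project_submodel(fit, character(0), ndraws = 200)
  p_mean <- rowMeans(stats::plogis(tcrossprod(fit$draws[idx, ], Xd)))
  expect_equal(stats::plogis(p0[, 1]), p_mean, tolerance = 1e-10)
  expect_error(project_submodel(fit, "nope"), "not in reference")
})

test_that("single-binary-feature projection matches the two-cell closed form", {
  withr::with_seed(14, {
    x <- stats::rbinom(200, 1, 0.4)
    p_soft <- stats::runif(200, 0.1, 0.9)
  })
  Xd <- cbind(1, x)
  beta <- gagmced:::proj_logit(Xd, p_soft)
  q0 <- mean(p_soft[x == 0]); q1 <- mean(p_soft[x == 1])
  expect_equal(unname(beta),
               c(stats::qlogis(q0), stats::qlogis(q1) - stats::qlogis(q0)),
               tolerance = 1e-7)
})

test_that("one-SE size rule follows its definition", {
  path <- data.frame(size = 1:3,
                     elpd_diff = c(-10, -3, -0.5),
                     diff_se = c(2, 2, 1))
  expect_equal(choose_size(path), 3)
  path$elpd_diff[1] <- -1.5  # first size already within one SE
  expect_equal(choose_size(path), 1)
  path$elpd_diff <- c(-10, -9, -8)
  expect_warning(sz <- choose_size(path), "cap")
  expect_equal(sz, 3)
})

test_that("forward selection respects the cap and finds planted features", {
  dat <- logit_data(n = 300, p = 6, beta = c(1.5, 1.5), seed = 15)
  fit <- fit_reference(dat$X, dat$y, chains = 2, draws = 200, seed = 16)
  path <- forward_select(fit, cap = 1, K = 5, nclusters = 5, seed = 17)
  expect_equal(max(path$size), 1)  # path length 1 plus the intercept-only row
  expect_equal(nrow(path), 2L)
  path3 <- forward_select(fit, cap = 3, K = 5, nclusters = 5, seed = 18)
  expect_true(all(c("f1", "f2") %in% path3$feature[path3$size %in% 1:3]))
  expect_error(forward_select(fit, cap = 0), "cap")
})

test_that("cutoffs anchor the requested specificity", {
  cut <- set_cutoffs(1:100, 0.95)
  expect_gt(cut[[1]], 95); expect_lt(cut[[1]], 96)
  expect_equal(sum(1:100 > cut[[1]]), 5L)
  # all controls equal: cutoff above that value, specificity 100%
  cut <- set_cutoffs(rep(2, 50), 0.95)
  expect_gt(cut[[1]], 2)
  expect_equal(attr(cut, "achieved_specificity")[[1]], 1)
  # specificity 1: cutoff above the maximum
  cut <- set_cutoffs(c(1, 5, 3), 1.0)
  expect_gt(cut[[1]], 5)
  # monotone: 99% cutoff at or above the 95% one
  cs <- withr::with_seed(19, stats::rnorm(500))
  both <- set_cutoffs(cs, c(0.95, 0.99))
  expect_gte(both[["spec99"]], both[["spec95"]])
})

test_that("pruning keeps only concentration features", {
  cand <- c("plasma_cs_0s", "plasma_frac_cs_0s", "urine_charge_cs",
            "urine_ratio_4s_0s", "urine_hs_ns", "urine_total_hs")
  pruned <- prune_to_independent(cand)
  expect_setequal(pruned, c("plasma_cs_0s", "urine_hs_ns", "urine_total_hs"))
  expect_error(prune_to_independent(c("frac_cs_0s", "charge_cs")), "no concentration")
})

test_that("built scores are monotone in positively weighted features", {
  dat <- logit_data(n = 300, p = 4, beta = c(1.5), seed = 20)
  model <- suppressWarnings(
    build_score(dat$X, dat$y, cap = 2, K = 5, nclusters = 5,
                chains = 2, draws = 200, ndraws = 100, seed = 21))
  expect_true("f1" %in% model$features)
  nd <- as.data.frame(dat$X[1:5, , drop = FALSE])
  s1 <- predict(model, nd)
  nd$f1 <- nd$f1 + 1
  s2 <- predict(model, nd)
  expect_true(all(s2 > s1))
  # probabilities and classes are consistent transforms of the score
  expect_equal(predict(model, nd, type = "prob"), stats::plogis(s2))
  expect_equal(predict(model, nd, type = "class"),
               as.integer(s2 > model$cutoffs[["spec95"]]))
  # display capping affects plots only
  expect_equal(display_scores(model, c(-10, 0, 10)), c(-6, 0, 6))
})

test_that("model serialization round-trips bit-identical scores", {
  dat <- logit_data(n = 250, p = 4, beta = c(1.2), seed = 22)
  model <- suppressWarnings(
    build_score(dat$X, dat$y, cap = 2, K = 5, nclusters = 5,
                chains = 2, draws = 150, ndraws = 80, seed = 23))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  model2 <- read_model(path)
  nd <- as.data.frame(dat$X)
  expect_identical(predict(model, nd), predict(model2, nd))
  # version mismatch is an explicit error
  obj <- jsonlite::read_json(path)
  obj$format_version <- 99
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(path), "version mismatch")
  # truncated file: parse error, no partial model
  writeLines(substr(paste(readLines(path), collapse = ""), 1, 50), path)
  expect_error(read_model(path))
})
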