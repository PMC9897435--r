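# Synthetic cohort generators. The generative model mirrors the structure the
# analysis assumes: per-feature skew-normal concentrations with cancer-type
# fixed effects (in SD units), batch random effects, optional type x batch
# variance multipliers, truncation at zero and limit-of-detection censoring,
# stage labels with a weak dependence on the realised GAGome deviation,
# confounder (CRP/HDL-C) shifts, Weibull survival linked to score group, and
# 4-timepoint mouse plasma/urine trajectories.

default_cancer_types <- c("BC", "BCa", "CLL", "CST", "CRC", "DG", "NHL", "EC",
                          "HN", "NSCLC", "OV", "PCa", "RCC", "GNET")

# Baseline skew-normal parameters per fluid: target medians chosen so that the
# detectability pattern of a development-style cohort is 6 plasma and 17 urine
# features (plasma: only 0S and 4S CS above the 0.1 ug/mL LOD; urine: 0S, 4S,
# 6S, 2S6S CS plus 0S and NS HS).
default_baselines <- function() {
  plasma_med <- c(cs_0s = 2.5, cs_2s = 0.02, cs_6s = 0.04, cs_4s = 0.60,
                  cs_2s6s = 0.02, cs_2s4s = 0.01, cs_4s6s = 0.01, cs_tris = 0.01,
                  hs_0s = 0.04, hs_2s = 0.01, hs_6s = 0.02, hs_ns = 0.03,
                  hs_ns6s = 0.01, hs_ns2s = 0.01, hs_2s6s = 0.01, hs_tris = 0.01,
                  ha = 0.05)
  urine_med <- c(cs_0s = 1.8, cs_2s = 0.03, cs_6s = 0.50, cs_4s = 0.90,
                 cs_2s6s = 0.30, cs_2s4s = 0.02, cs_4s6s = 0.03, cs_tris = 0.01,
                 hs_0s = 0.70, hs_2s = 0.02, hs_6s = 0.05, hs_ns = 0.30,
                 hs_ns6s = 0.03, hs_ns2s = 0.02, hs_2s6s = 0.02, hs_tris = 0.01,
                 ha = 0.08)
  mk <- function(med) {
    data.frame(feature = names(med),
               median = unname(med),
               omega = unname(ifelse(med > 0.1, 0.35 * med, 0.5 * med)),
               alpha = 4)
  }
  list(plasma = mk(plasma_med), urine = mk(urine_med))
}

# Cancer-type effect template (SD units): a universal 0S CS increase in both
# fluids, a plasma 4S CS decrease in CRC/NHL (lowering plasma CS charge), and
# a urine 2S6S CS increase in PCa.
default_effects <- function(types = default_cancer_types) {
  mk <- function() {
    m <- matrix(0, length(types), length(gag_conc_features),
                dimnames = list(types, gag_conc_features))
    m
  }
  plasma <- mk(); urine <- mk()
  plasma[, "cs_0s"] <- 1.0
  urine[, "cs_0s"] <- 1.0
  plasma[intersect(c("CRC", "NHL"), types), "cs_4s"] <- -0.8
  urine[intersect("PCa", types), "cs_2s6s"] <- 0.8
  list(plasma = plasma, urine = urine)
}

zero_effects <- function(types = default_cancer_types) {
  e <- default_effects(types)
  e$plasma[] <- 0; e$urine[] <- 0
  e
}

#' Synthetic cohort generator configuration
#'
#' Collects the generative model: arm sizes, cancer types, per-feature
#' skew-normal baselines (location/scale/slant per fluid), cancer-type effect
#' matrices in SD units, batch structure, LOD, stage-assignment behaviour,
#' confounder targets and survival parameters. The defaults describe a
#' development-style cohort at desk scale (about 500 subjects) whose
#' detectability pattern is 6 plasma and 17 urine features.
#'
#' @param n_healthy Healthy subjects.
#' @param n_per_type Cancer patients per cancer type.
#' @param cancer_types Character vector of type labels (max 14).
#' @param fluids Fluids generated per subject.
#' @param baselines Per-fluid data.frame (feature, median, omega, alpha).
#' @param effects Per-fluid type x feature matrix of location shifts, SD units.
#' @param n_batches Number of experimental batches.
#' @param batch_sd SD of the batch random intercept (SD units of the feature).
#' @param var_mult Optional type x batch matrix of scale multipliers.
#' @param lod Limit of detection, ug/mL; draws below are recorded as 0.
#' @param stage_dependence Slope of the stage latent on the realised 0S CS
#'   deviation (weak by default, matching a weak score-stage dependence).
#' @param stage_probs Marginal probabilities of S1/LG, S2, S3, S4/HG, unspecified.
#' @param crp_tau,hdl_tau Target Kendall correlations between the cancer score
#'   and CRP / HDL-C in validation-style cohorts.
#' @param survival List: `hr_low_vs_high`, Weibull `shape`, `median_high`
#'   (months), `event_frac`.
#' @return List of class `gag_sim_config`.
#' @export
gag_sim_config <- function(n_healthy = 250,
                           n_per_type = 18,
                           cancer_types = default_cancer_types,
                           fluids = c("plasma", "urine"),
                           baselines = default_baselines(),
                           effects = default_effects(cancer_types),
                           n_batches = 3,
                           batch_sd = 0.15,
                           var_mult = NULL,
                           lod = 0.1,
                           stage_dependence = 0.3,
                           stage_probs = c(0.34, 0.10, 0.11, 0.43, 0.02),
                           crp_tau = 0.29,
                           hdl_tau = -0.16,
                           survival = list(hr_low_vs_high = 0.61, shape = 1.2,
                                           median_high = 18, event_frac = 0.5)) {
  if (length(cancer_types) > 14) stop("at most 14 cancer types", call. = FALSE)
  for (fl in fluids) {
    bad <- setdiff(rownames(effects[[fl]]), cancer_types)
    if (length(bad)) stop("effect matrix has unknown types: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    badf <- setdiff(colnames(effects[[fl]]), gag_conc_features)
    if (length(badf)) stop("unknown feature name in effect matrix: ",
                           paste(badf, collapse = ", "), call. = FALSE)
    if (any(baselines[[fl]]$omega <= 0)) stop("scales must be > 0", call. = FALSE)
  }
  if (abs(sum(stage_probs) - 1) > 1e-8) stop("stage_probs must sum to 1", call. = FALSE)
  if (abs(crp_tau) >= 1 || abs(hdl_tau) >= 1) {
    stop("target |tau| must be < 1", call. = FALSE)
  }
  structure(list(n_healthy = n_healthy, n_per_type = n_per_type,
                 cancer_types = cancer_types, fluids = fluids,
                 baselines = baselines, effects = effects,
                 n_batches = n_batches, batch_sd = batch_sd,
                 var_mult = var_mult, lod = lod,
                 stage_dependence = stage_dependence,
                 stage_probs = stage_probs,
                 crp_tau = crp_tau, hdl_tau = hdl_tau,
                 survival = survival),
            class = "gag_sim_config")
}

# Draw the 17 concentrations for one fluid.
# type: character vector per subject ("healthy" or a cancer type)
# batch: integer vector; conf_shift: n x 17 matrix of extra SD-unit shifts.
sim_fluid_conc <- function(config, fluid, type, batch, conf_shift = NULL) {
  bl <- config$baselines[[fluid]]
  eff <- config$effects[[fluid]]
  n <- length(type)
  u <- stats::rnorm(config$n_batches, 0, config$batch_sd)  # batch intercepts, SD units
  out <- matrix(0, n, length(gag_conc_features),
                dimnames = list(NULL, gag_conc_features))
  for (j in seq_along(gag_conc_features)) {
    f <- gag_conc_features[j]
    row <- bl[bl$feature == f, ]
    mom <- sn_moments(row$alpha)
    xi <- row$median - row$omega * sn_m0(row$alpha)
    s <- row$omega * mom$sd  # marginal SD of the baseline feature
    beta <- numeric(n)
    is_ca <- type != "healthy"
    beta[is_ca] <- eff[type[is_ca], f]
    beta[is.na(beta)] <- 0
    vm <- rep(1, n)
    if (!is.null(config$var_mult)) {
      idx <- cbind(match(type, rownames(config$var_mult)), batch)
      vm_raw <- config$var_mult[idx]
      vm[!is.na(vm_raw)] <- vm_raw[!is.na(vm_raw)]
    }
    shift <- if (is.null(conf_shift)) 0 else conf_shift[, f]
    x <- xi + row$omega * sqrt(vm) * rsn(n, 0, 1, row$alpha) +
      s * (beta + u[batch] + shift)
    x[x < config$lod] <- 0  # truncation at zero + below-LOD recorded as 0
    out[, j] <- x
  }
  attr(out, "batch_effects") <- u
  out
}

sim_stage <- function(z_dev, config) {
  n <- length(z_dev)
  p <- config$stage_probs
  latent <- config$stage_dependence * z_dev + stats::rlogis(n)
  # first carve out the 'unspecified' fraction at random
  unspec <- stats::runif(n) < p[5]
  p4 <- p[1:4] / sum(p[1:4])
  th <- stats::quantile(latent, probs = cumsum(p4)[1:3], na.rm = TRUE)
  stage <- cut(latent, breaks = c(-Inf, th, Inf),
               labels = c("S1/LG", "S2", "S3", "S4/HG"))
  stage <- as.character(stage)
  stage[unspec] <- "unspecified"
  stage
}

#' Generate a development-style synthetic cohort
#'
#' Draws healthy and cancer subjects with plasma and/or urine disaccharide
#' panels from the configured skew-normal model. Only the 17 raw
#' concentrations are generated; derived features must be computed with
#' [compute_features()] (or [prepare_cohort()]). Identical (config, seed)
#' pairs regenerate identical tables.
#'
#' @param config A [gag_sim_config()].
#' @param seed Integer seed.
#' @return List of class `gag_synthetic` with elements `cohort` (one row per
#'   subject x fluid, CSV schema columns + 17 concentrations) and `truth`
#'   (effect matrices, batch effects, baselines, config).
#' @export
generate_development_cohort <- function(config = gag_sim_config(), seed = 1) {
  with_seed(seed, {
    types <- c(rep("healthy", config$n_healthy),
               rep(config$cancer_types, each = config$n_per_type))
    n <- length(types)
    ord <- sample.int(n)
    types <- types[ord]
    subject <- sprintf("subj%04d", seq_len(n))
    batch <- sample.int(config$n_batches, n, replace = TRUE)
    age <- round(ifelse(types == "healthy", stats::runif(n, 25, 78),
                        stats::runif(n, 35, 88)))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    rows <- list(); batch_eff <- list()
    for (fl in config$fluids) {
      conc <- sim_fluid_conc(config, fl, types, batch)
      batch_eff[[fl]] <- attr(conc, "batch_effects")
      df <- data.frame(sample_id = paste0(subject, "_", fl),
                       subject_id = subject, fluid = fl,
                       batch = paste0("batch", batch),
                       diagnosis = ifelse(types == "healthy", "healthy", "cancer"),
                       cancer_type = ifelse(types == "healthy", "", types),
                       stage_group = "", age = age, sex = sex,
                       os_months = NA_real_, os_event = NA_integer_,
                       crp_mg_dl = NA_real_, hdl_mmol_l = NA_real_,
                       stringsAsFactors = FALSE)
      rows[[fl]] <- cbind(df, as.data.frame(conc))
    }
    # stage labels: weak ordinal dependence on the realised 0S CS deviation
    fl1 <- config$fluids[1]
    bl1 <- config$baselines[[fl1]]
    r0 <- bl1[bl1$feature == "cs_0s", ]
    s0 <- r0$omega * sn_moments(r0$alpha)$sd
    z_dev <- (rows[[fl1]][["cs_0s"]] - r0$median) / s0
    stage <- sim_stage(z_dev, config)
    for (fl in config$fluids) {
      rows[[fl]]$stage_group <- ifelse(types == "healthy", "", stage)
    }
    cohort <- do.call(rbind, rows)
    rownames(cohort) <- NULL
    truth <- list(config = config, effects = config$effects,
                  batch_effects = batch_eff,
                  informative = lapply(config$effects, function(m) {
                    colnames(m)[colSums(m != 0) > 0]
                  }),
                  seed = seed)
    structure(list(cohort = cohort, truth = truth), class = "gag_synthetic")
  })
}

#' @export
print.gag_synthetic <- function(x, ...) {
  cat("Synthetic GAGome cohort:", nrow(x$cohort), "rows,",
      length(unique(x$cohort$subject_id)), "subjects\n")
  invisible(x)
}

# Kendall tau target -> per-feature confounder loading. For a score that sums
# k equally informative standardized features, loading g per feature gives
# score-confounder correlation rho = sqrt(k) g / sqrt(1 + k g^2); tau relates
# to rho by tau = (2/pi) asin(rho) under bivariate normality. The 1.25
# inflation compensates for what the normal approximation ignores (cancer-type
# mixture, skewness, LOD truncation, the extra informative features) and was
# calibrated once by simulation against the oracle score at n = 281.
tau_to_loading <- function(tau, k, calibration = 1.25) {
  rho <- sin(pi * tau / 2)
  calibration * sign(rho) * sqrt(rho^2 / (1 - rho^2) / k)
}

#' Generate a validation-style synthetic cohort with confounders
#'
#' Adds CRP (log-normal, mg/dL) and HDL-C (normal, mmol/L) covariates whose
#' standardized values shift the universally informative 0S CS features, so
#' that the cancer score correlates with CRP (target Kendall tau
#' `config$crp_tau`, default 0.29) and anti-correlates with HDL-C (default
#' -0.16). Case mix and arm sizes default to a validation-study layout.
#'
#' @param config A [gag_sim_config()]; `crp_tau`/`hdl_tau` set the targets.
#' @param seed Integer seed.
#' @param n_controls,n_cases Arm sizes.
#' @param case_types Cancer types (recycled over cases).
#' @return `gag_synthetic` list; the cohort carries `crp_mg_dl`, `hdl_mmol_l`.
#' @export
generate_validation_cohort <- function(config = gag_sim_config(), seed = 1,
                                       n_controls = 110, n_cases = 171,
                                       case_types = c("BC", "CRC", "CST",
                                                      "NSCLC", "PCa", "RCC")) {
  case_types <- intersect(case_types, config$cancer_types)
  with_seed(seed, {
    types <- c(rep("healthy", n_controls),
               rep_len(rep(case_types, length.out = n_cases), n_cases))
    n <- length(types)
    ord <- sample.int(n); types <- types[ord]
    subject <- sprintf("vsubj%04d", seq_len(n))
    batch <- sample.int(config$n_batches, n, replace = TRUE)
    crp <- stats::rlnorm(n, meanlog = log(1.4), sdlog = 0.8)
    hdl <- pmax(0.5, stats::rnorm(n, 1.4, 0.25))
    z_crp <- (log(crp) - log(1.4)) / 0.8
    z_hdl <- (hdl - 1.4) / 0.25
    conf_features <- c("cs_0s")  # universal informative feature, both fluids
    k <- length(conf_features) * length(config$fluids)
    g_crp <- tau_to_loading(config$crp_tau, k)
    g_hdl <- tau_to_loading(config$hdl_tau, k)
    shift <- matrix(0, n, length(gag_conc_features),
                    dimnames = list(NULL, gag_conc_features))
    shift[, conf_features] <- g_crp * z_crp + g_hdl * z_hdl
    age <- round(stats::runif(n, 30, 82))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    rows <- list(); batch_eff <- list()
    for (fl in config$fluids) {
      conc <- sim_fluid_conc(config, fl, types, batch, conf_shift = shift)
      batch_eff[[fl]] <- attr(conc, "batch_effects")
      df <- data.frame(sample_id = paste0(subject, "_", fl),
                       subject_id = subject, fluid = fl,
                       batch = paste0("batch", batch),
                       diagnosis = ifelse(types == "healthy", "healthy", "cancer"),
                       cancer_type = ifelse(types == "healthy", "", types),
                       stage_group = "", age = age, sex = sex,
                       os_months = NA_real_, os_event = NA_integer_,
                       crp_mg_dl = crp, hdl_mmol_l = hdl,
                       stringsAsFactors = FALSE)
      rows[[fl]] <- cbind(df, as.data.frame(conc))
    }
    fl1 <- config$fluids[1]
    bl1 <- config$baselines[[fl1]]
    r0 <- bl1[bl1$feature == "cs_0s", ]
    s0 <- r0$omega * sn_moments(r0$alpha)$sd
    z_dev <- (rows[[fl1]][["cs_0s"]] - r0$median) / s0
    stage <- sim_stage(z_dev, config)
    for (fl in config$fluids) {
      rows[[fl]]$stage_group <- ifelse(types == "healthy", "", stage)
    }
    cohort <- do.call(rbind, rows); rownames(cohort) <- NULL
    truth <- list(config = config, effects = config$effects,
                  batch_effects = batch_eff,
                  conf_loading = list(crp = g_crp, hdl = g_hdl,
                                      features = conf_features),
                  seed = seed)
    structure(list(cohort = cohort, truth = truth), class = "gag_synthetic")
  })
}

#' Oracle (generative Bayes) cancer score for a synthetic cohort
#'
#' The log likelihood ratio of cancer vs healthy computed from the generator's
#' own skew-normal parameters (mixture over the cancer types present, known
#' batch effects), evaluated on the informative features. This is the
#' theoretically optimal score for the generated data and serves as the
#' oracle that fitted MCED scores are compared against.
#'
#' @param synth A `gag_synthetic` object.
#' @param fluids Fluids to use (default: all generated).
#' @return Named numeric vector of oracle scores, one per subject.
#' @export
bayes_score <- function(synth, fluids = NULL) {
  cohort <- synth$cohort; truth <- synth$truth
  config <- truth$config
  fluids <- fluids %||% config$fluids
  types <- config$cancer_types
  subj <- unique(cohort$subject_id)
  score <- stats::setNames(numeric(length(subj)), subj)
  for (fl in fluids) {
    sub <- cohort[cohort$fluid == fl, , drop = FALSE]
    sub <- sub[match(subj, sub$subject_id), , drop = FALSE]
    bl <- config$baselines[[fl]]
    eff <- config$effects[[fl]]
    u <- truth$batch_effects[[fl]]
    b_idx <- as.integer(sub("batch", "", sub$batch))
    info <- colnames(eff)[colSums(eff != 0) > 0]
    if (!length(info)) next
    # type-mixture weights proportional to generated case mix
    w <- rep(1 / length(types), length(types))
    ll1 <- matrix(0, nrow(sub), length(types))
    ll0 <- numeric(nrow(sub))
    for (f in info) {
      row <- bl[bl$feature == f, ]
      mom <- sn_moments(row$alpha)
      xi <- row$median - row$omega * sn_m0(row$alpha)
      s <- row$omega * mom$sd
      x <- sub[[f]]
      base_loc <- xi + s * u[b_idx]
      ll0 <- ll0 + dsn(x, base_loc, row$omega, row$alpha, log = TRUE)
      for (ti in seq_along(types)) {
        ll1[, ti] <- ll1[, ti] +
          dsn(x, base_loc + s * eff[types[ti], f], row$omega, row$alpha, log = TRUE)
      }
    }
    m <- apply(ll1, 1, max)
    lmix <- m + log(as.vector(exp(ll1 - m) %*% w))
    score <- score + (lmix - ll0)
  }
  score
}

#' Attach Weibull survival times linked to score group
#'
#' Draws overall-survival times from a proportional-hazards Weibull model in
#' which the low-score (undetected) group has hazard ratio `hr_low_vs_high`
#' (default 0.61) relative to the high-score group, with uniform censoring
#' calibrated to a target event fraction.
#'
#' @param high Logical vector: score above the 95%-specificity cutoff.
#' @param hr_low_vs_high Planted hazard ratio, low vs high.
#' @param seed Integer seed.
#' @param shape Weibull shape.
#' @param median_high Median survival of the high group, months.
#' @param event_frac Target fraction of observed events; 0 censors everything.
#' @return Data.frame `os_months`, `os_event` plus attribute `truth`.
#' @export
generate_survival <- function(high, hr_low_vs_high = 0.61, seed = 1,
                              shape = 1.2, median_high = 18, event_frac = 0.5) {
  n <- length(high)
  with_seed(seed, {
    b_high <- median_high / log(2)^(1 / shape)
    lhr <- log(hr_low_vs_high)
    eta <- ifelse(high, 0, lhr)
    t_true <- b_high * (-log(stats::runif(n)) / exp(eta))^(1 / shape)
    u_c <- stats::runif(n)
    if (event_frac <= 0) {
      times <- u_c * median_high * 2
      events <- integer(n)
    } else {
      ev_frac <- function(cmax) mean(t_true <= u_c * cmax)
      lo <- 1e-6; hi <- max(t_true) * 100
      for (i in 1:60) {
        mid <- sqrt(lo * hi)
        if (ev_frac(mid) < event_frac) lo <- mid else hi <- mid
      }
      cmax <- sqrt(lo * hi)
      cens <- u_c * cmax
      events <- as.integer(t_true <= cens)
      times <- pmin(t_true, cens)
    }
    out <- data.frame(os_months = times, os_event = events)
    attr(out, "truth") <- list(hr_low_vs_high = hr_low_vs_high, shape = shape,
                               median_high = median_high)
    out
  })
}

#' Generate a longitudinal mouse experiment
#'
#' Emulates a renal tumour progression experiment: per-mouse plasma panels and
#' per-cage pooled urine panels at four timepoints (baseline, localized
#' growth, post-operative resection, metastasis), with random mouse/cage
#' intercepts and a planted multiplicative trend on one feature (default
#' 0S CS, +148% in plasma and +116% in urine at metastasis vs baseline).
#'
#' @param n_mice,n_cages Number of mice and metabolic cages (2 mice/cage).
#' @param seed Integer seed.
#' @param trend List: `feature`, `plasma_mult`, `urine_mult` (length-4
#'   multipliers, baseline first).
#' @param dropout Optional list(mouse = index, from = timepoint name): the
#'   mouse is removed from that timepoint on; its cage's urine rows from then
#'   on are flagged `alive_pair = FALSE`.
#' @return List of class `gag_mouse_synthetic`: `table` (long format:
#'   unit_id, timepoint, fluid, alive_pair, 17 concentrations) and `truth`
#'   (planted percent changes).
#' @export
generate_mouse <- function(n_mice = 20, n_cages = 10, seed = 1,
                           trend = list(feature = "cs_0s",
                                        plasma_mult = c(1, 1.45, 1.85, 2.48),
                                        urine_mult = c(1, 1.35, 1.70, 2.16)),
                           dropout = NULL) {
  timepoints <- c("baseline", "localized", "postop", "metastasis")
  bl <- default_baselines()
  with_seed(seed, {
    mk_rows <- function(units, fluid, mult_named, sd_frac_b = 0.12, sd_frac_e = 0.14) {
      base <- stats::setNames(bl[[fluid]]$median, bl[[fluid]]$feature)
      b_unit <- stats::rnorm(length(units), 0, sd_frac_b) # relative intercepts
      out <- list()
      for (ti in seq_along(timepoints)) {
        m <- matrix(0, length(units), length(gag_conc_features),
                    dimnames = list(NULL, gag_conc_features))
        for (j in seq_along(gag_conc_features)) {
          f <- gag_conc_features[j]
          mult <- if (f == trend$feature) mult_named[ti] else 1
          mu <- base[[f]] * mult
          m[, j] <- pmax(0, mu + base[[f]] * b_unit +
                           stats::rnorm(length(units), 0, sd_frac_e * base[[f]]))
        }
        out[[ti]] <- cbind(
          data.frame(unit_id = units, timepoint = timepoints[ti], fluid = fluid,
                     alive_pair = TRUE, stringsAsFactors = FALSE),
          as.data.frame(m))
      }
      do.call(rbind, out)
    }
    mice <- sprintf("mouse%02d", seq_len(n_mice))
    cages <- sprintf("cage%02d", seq_len(n_cages))
    plasma <- mk_rows(mice, "plasma", trend$plasma_mult)
    urine <- mk_rows(cages, "urine", trend$urine_mult)
    if (!is.null(dropout)) {
      from_idx <- match(dropout$from, timepoints)
      gone_tp <- timepoints[seq(from_idx, length(timepoints))]
      m_id <- mice[dropout$mouse]
      plasma <- plasma[!(plasma$unit_id == m_id & plasma$timepoint %in% gone_tp), ]
      cage_of <- cages[ceiling(dropout$mouse / 2)]
      urine$alive_pair[urine$unit_id == cage_of & urine$timepoint %in% gone_tp] <- FALSE
    }
    tab <- rbind(plasma, urine)
    rownames(tab) <- NULL
    truth <- list(feature = trend$feature,
                  pct_change = list(
                    plasma = 100 * (trend$plasma_mult - 1),
                    urine = 100 * (trend$urine_mult - 1)),
                  timepoints = timepoints, seed = seed)
    structure(list(table = tab, truth = truth), class = "gag_mouse_synthetic")
  })
}
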