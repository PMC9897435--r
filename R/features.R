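# GAGome feature calculus: the 17 measured disaccharide concentrations and the
# 22 calculated features (totals, charges, ratios, mass fractions), plus
# detectability filtering, standardization and outlier screening.

#' @name gag_species
#' @title Disaccharide species and feature names
#' @description Naming constants for the free-GAGome panel: eight chondroitin
#'   sulfate (CS) species, eight heparan sulfate (HS) species and hyaluronic
#'   acid (HA), plus the derived-feature names making up the 39-feature GAGome.
NULL

cs_species <- c("0s", "2s", "6s", "4s", "2s6s", "2s4s", "4s6s", "tris")
hs_species <- c("0s", "2s", "6s", "ns", "ns6s", "ns2s", "2s6s", "tris")

#' @rdname gag_species
#' @export
gag_conc_features <- c(paste0("cs_", cs_species), paste0("hs_", hs_species), "ha")

# Sulfo-group counts: the weight of each species in the charge calculation.
sulfo_weights_cs <- c("0s" = 0, "2s" = 1, "6s" = 1, "4s" = 1,
                      "2s6s" = 2, "2s4s" = 2, "4s6s" = 2, "tris" = 3)
sulfo_weights_hs <- c("0s" = 0, "2s" = 1, "6s" = 1, "ns" = 1,
                      "ns6s" = 2, "ns2s" = 2, "2s6s" = 2, "tris" = 3)

#' @rdname gag_species
#' @export
gag_features <- c(
  gag_conc_features,
  "total_cs", "total_hs", "charge_cs", "charge_hs",
  "ratio_4s_0s", "ratio_6s_0s",
  paste0("frac_cs_", cs_species), paste0("frac_hs_", hs_species)
)

#' Sulfo-group weights for the 17 concentration features
#'
#' @return Named integer vector (0-3) over the 17 concentration features;
#'   HA carries no sulfation and has weight 0.
#' @export
sulfo_weights <- function() {
  w <- c(stats::setNames(sulfo_weights_cs, paste0("cs_", cs_species)),
         stats::setNames(sulfo_weights_hs, paste0("hs_", hs_species)),
         ha = 0)
  w
}

validate_panel <- function(conc) {
  missing <- setdiff(gag_conc_features, names(conc))
  if (length(missing)) {
    stop("missing disaccharide species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(conc), gag_conc_features)
  if (length(extra)) {
    stop("unknown disaccharide species: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  bad <- names(conc)[!is.na(unlist(conc)) & unlist(conc) < 0]
  if (length(bad)) {
    stop("negative concentration for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Compute the 39-feature GAGome from a disaccharide panel
#'
#' Expands the 17 measured disaccharide concentrations (ug/mL) into the full
#' GAGome: class totals (total CS, total HS), CS/HS charge (the fraction-
#' weighted mean sulfo-group count, dimensionless in \[0, 3\]), the 4S/0S and
#' 6S/0S CS ratios, and the 16 mass fractions (% w/w of the class total).
#' Below-LOD values must be encoded as 0 before calling. Ratios with a zero
#' denominator are returned as `NA` (undefined, not infinite); fractions are 0
#' when the class total is 0.
#'
#' @param panel Named numeric vector, one-row data.frame, or data.frame of
#'   samples with the 17 concentration columns (`cs_0s` ... `ha`).
#' @return For a single sample, a named numeric vector of the 39 features; for
#'   a data.frame, a data.frame with one row per input row.
#' @examples
#' x <- setNames(numeric(17), gag_conc_features)
#' x["cs_0s"] <- 1; x["cs_4s"] <- 1
#' f <- compute_features(x)
#' f[c("total_cs", "charge_cs", "ratio_4s_0s")]  # 2, 0.5, 1
#' @export
compute_features <- function(panel) {
  if (is.data.frame(panel) && nrow(panel) > 1) {
    out <- t(vapply(seq_len(nrow(panel)),
                    function(i) compute_features(panel[i, , drop = FALSE]),
                    numeric(length(gag_features))))
    return(as.data.frame(out))
  }
  if (is.data.frame(panel)) {
    panel <- unlist(panel[1, intersect(names(panel), gag_conc_features), drop = TRUE])
  }
  validate_panel(panel)  # full input: catches unknown species keys too
  conc <- panel[gag_conc_features]
  conc <- unlist(conc)
  cs <- stats::setNames(conc[paste0("cs_", cs_species)], cs_species)
  hs <- stats::setNames(conc[paste0("hs_", hs_species)], hs_species)
  total_cs <- sum(cs)
  total_hs <- sum(hs)
  frac_cs <- if (total_cs > 0) 100 * cs / total_cs else cs * 0
  frac_hs <- if (total_hs > 0) 100 * hs / total_hs else hs * 0
  charge_cs <- sum(sulfo_weights_cs * frac_cs / 100)
  charge_hs <- sum(sulfo_weights_hs * frac_hs / 100)
  ratio_4s_0s <- if (!is.na(cs[["0s"]]) && cs[["0s"]] > 0) cs[["4s"]] / cs[["0s"]] else NA_real_
  ratio_6s_0s <- if (!is.na(cs[["0s"]]) && cs[["0s"]] > 0) cs[["6s"]] / cs[["0s"]] else NA_real_
  out <- c(conc, total_cs = total_cs, total_hs = total_hs,
           charge_cs = charge_cs, charge_hs = charge_hs,
           ratio_4s_0s = ratio_4s_0s, ratio_6s_0s = ratio_6s_0s,
           stats::setNames(frac_cs, paste0("frac_cs_", cs_species)),
           stats::setNames(frac_hs, paste0("frac_hs_", hs_species)))
  stats::setNames(as.numeric(out), gag_features)
}

#' Append the 22 calculated features to a cohort table
#'
#' Cohort-level counterpart of [compute_features()]: recomputes the derived
#' feature columns (totals, charges, ratios, fractions) from the 17
#' concentration columns, leaving metadata untouched.
#'
#' @param cohort Data.frame with the 17 concentration columns.
#' @return The cohort with all 39 feature columns.
#' @export
add_features <- function(cohort) {
  feats <- compute_features(cohort[, gag_conc_features, drop = FALSE])
  derived <- setdiff(gag_features, gag_conc_features)
  cohort[derived] <- feats[derived]
  cohort
}

#' Per-fluid detectability filter
#'
#' A concentration feature is detectable in a fluid if its median concentration
#' across all samples of that fluid exceeds `threshold` (default 0.1 ug/mL, the
#' assay limit of detection). Calculated features are retained only when their
#' constituents are detectable: class totals need at least one detectable
#' member concentration; a mass fraction needs its own species (and hence the
#' class total) detectable; a ratio needs both numerator and denominator
#' detectable; a class charge needs at least two detectable sulfated species of
#' that class (with a single charged species the charge is a rescaling of one
#' fraction and carries no independent information).
#'
#' @param cohort Cohort data.frame with a `fluid` column and the 39 feature
#'   columns (see [compute_features()]).
#' @param threshold Detectability threshold in ug/mL.
#' @return Object of class `gag_detectability`: per fluid, the named logical
#'   mask over the 39 features and the vector of detectable feature names.
#' @export
detectability_filter <- function(cohort, threshold = 0.1) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  fluids <- unique(as.character(cohort$fluid))
  res <- lapply(fluids, function(fl) {
    sub <- cohort[cohort$fluid == fl, , drop = FALSE]
    med <- vapply(gag_conc_features,
                  function(f) stats::median(sub[[f]], na.rm = TRUE), numeric(1))
    det_conc <- med > threshold
    mask <- stats::setNames(logical(length(gag_features)), gag_features)
    mask[gag_conc_features] <- det_conc
    cs_det <- det_conc[paste0("cs_", cs_species)]
    hs_det <- det_conc[paste0("hs_", hs_species)]
    mask["total_cs"] <- any(cs_det)
    mask["total_hs"] <- any(hs_det)
    mask[paste0("frac_cs_", cs_species)] <- cs_det & any(cs_det)
    mask[paste0("frac_hs_", hs_species)] <- hs_det & any(hs_det)
    mask["ratio_4s_0s"] <- det_conc[["cs_4s"]] && det_conc[["cs_0s"]]
    mask["ratio_6s_0s"] <- det_conc[["cs_6s"]] && det_conc[["cs_0s"]]
    mask["charge_cs"] <- sum(cs_det[sulfo_weights_cs > 0]) >= 2
    mask["charge_hs"] <- sum(hs_det[sulfo_weights_hs > 0]) >= 2
    list(mask = mask, detectable = names(mask)[mask], medians = med)
  })
  names(res) <- fluids
  structure(list(fluids = res, threshold = threshold),
            class = "gag_detectability")
}

#' @export
print.gag_detectability <- function(x, ...) {
  cat("GAGome detectability (median > ", x$threshold, " ug/mL)\n", sep = "")
  for (fl in names(x$fluids)) {
    d <- x$fluids[[fl]]$detectable
    cat(sprintf("  %s: %d detectable features\n    %s\n", fl, length(d),
                paste(d, collapse = ", ")))
  }
  invisible(x)
}

#' Fit a standardization transform
#'
#' Centers and scales each feature to overall mean 0 and SD 1 (population SD
#' convention, dividing by n). The returned transform can be re-applied to new
#' data, e.g. to score validation samples on the development scale.
#'
#' @param cohort Data.frame holding the feature columns.
#' @param features Character vector of features to standardize.
#' @return Object of class `gag_standardizer` (means, SDs, feature names).
#' @export
fit_standardizer <- function(cohort, features) {
  missing <- setdiff(features, names(cohort))
  if (length(missing)) {
    stop("features not in cohort: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  mu <- vapply(features, function(f) mean(cohort[[f]], na.rm = TRUE), numeric(1))
  sd <- vapply(features, function(f) pop_sd(cohort[[f]]), numeric(1))
  zero <- features[sd == 0 | is.na(sd)]
  if (length(zero)) {
    stop("zero-variance feature(s): ", paste(zero, collapse = ", "), call. = FALSE)
  }
  structure(list(features = features, mean = mu, sd = sd),
            class = "gag_standardizer")
}

#' Apply a standardization transform
#'
#' @param object A `gag_standardizer` from [fit_standardizer()].
#' @param newdata Data.frame holding the transform's feature columns.
#' @param ... Unused.
#' @return `newdata` with the transform's features replaced by z-scores.
#' @export
predict.gag_standardizer <- function(object, newdata, ...) {
  for (f in object$features) {
    newdata[[f]] <- (newdata[[f]] - object$mean[[f]]) / object$sd[[f]]
  }
  newdata
}

#' @export
print.gag_standardizer <- function(x, ...) {
  cat("GAGome standardizer:", length(x$features), "features\n")
  invisible(x)
}

#' Two-step robust outlier screen
#'
#' Flags, per fluid, samples whose total CS concentration (step 1) or any
#' detectable feature (step 2) lies outside median +/- `k_mad` * MAD. This is a
#' documented stand-in for the assay's supplementary two-step procedure. When
#' the MAD of a feature is zero the screen falls back to an IQR-based robust
#' SD (IQR/1.349) with a warning.
#'
#' @param cohort Cohort data.frame with `fluid` and feature columns.
#' @param detect A `gag_detectability` object (or NULL to compute one).
#' @param k_mad Multiplier for the robust deviation (default 5).
#' @return Object of class `gag_outliers`: logical `flag` per row plus a
#'   detail table with the step and feature triggering each flag.
#' @export
outlier_screen <- function(cohort, detect = NULL, k_mad = 5) {
  tab <- table(cohort$fluid)
  if (any(tab < 10)) {
    stop("outlier screen needs >= 10 samples per fluid", call. = FALSE)
  }
  if (is.null(detect)) detect <- detectability_filter(cohort)
  flag <- logical(nrow(cohort))
  details <- list()
  robust_bounds <- function(x) {
    med <- stats::median(x, na.rm = TRUE)
    dev <- stats::mad(x, na.rm = TRUE)
    if (!is.finite(dev) || dev == 0) {
      warning("MAD is zero; falling back to IQR rule", call. = FALSE)
      dev <- stats::IQR(x, na.rm = TRUE) / 1.349
    }
    c(med - k_mad * dev, med + k_mad * dev)
  }
  for (fl in names(detect$fluids)) {
    idx <- which(cohort$fluid == fl)
    sub <- cohort[idx, , drop = FALSE]
    b <- robust_bounds(sub$total_cs)
    out1 <- sub$total_cs < b[1] | sub$total_cs > b[2]
    flag[idx[which(out1)]] <- TRUE
    if (any(out1, na.rm = TRUE)) {
      details[[length(details) + 1]] <- data.frame(
        row = idx[which(out1)], fluid = fl, step = 1L, feature = "total_cs")
    }
    for (f in setdiff(detect$fluids[[fl]]$detectable, "total_cs")) {
      b <- robust_bounds(sub[[f]])
      out2 <- sub[[f]] < b[1] | sub[[f]] > b[2]
      if (any(out2, na.rm = TRUE)) {
        flag[idx[which(out2)]] <- TRUE
        details[[length(details) + 1]] <- data.frame(
          row = idx[which(out2)], fluid = fl, step = 2L, feature = f)
      }
    }
  }
  structure(list(flag = flag,
                 details = if (length(details)) do.call(rbind, details)
                           else data.frame(row = integer(), fluid = character(),
                                           step = integer(), feature = character()),
                 rule = sprintf("median +/- %g*MAD (IQR fallback), step 1 total CS, step 2 detectable features", k_mad),
                 k_mad = k_mad),
            class = "gag_outliers")
}

#' @export
print.gag_outliers <- function(x, ...) {
  cat("GAGome outlier screen:", sum(x$flag), "of", length(x$flag),
      "samples flagged\n  rule:", x$rule, "\n")
  invisible(x)
}
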