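# Readers/writers for cohort tables and model artifacts, plus the design
# helpers that turn a long cohort table into the standardized feature matrix
# a score is built on. Text formats only: CSV/TSV with provenance comment
# headers, JSON for models and configs.

cohort_meta_cols <- c("sample_id", "subject_id", "fluid", "batch", "diagnosis",
                      "cancer_type", "stage_group", "age", "sex",
                      "os_months", "os_event", "crp_mg_dl", "hdl_mmol_l")

MODEL_FORMAT_VERSION <- 1L

#' Read a cohort CSV
#'
#' Expects the package's cohort schema: the 13 metadata columns followed by
#' the 17 disaccharide concentration columns (ug/mL). Provenance comment
#' lines starting with `#` are skipped. Malformed numeric cells, negative
#' concentrations and duplicate sample ids are reported with row numbers.
#'
#' @param path CSV path.
#' @return Cohort data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty cohort file: ", path, call. = FALSE)
  missing <- setdiff(c(cohort_meta_cols, gag_conc_features), names(df))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "),
                        call. = FALSE)
  for (f in gag_conc_features) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    bad <- which(is.na(v) & !is.na(df[[f]]) & df[[f]] != "")
    if (length(bad)) stop(sprintf("malformed numeric in column %s, row(s) %s",
                                  f, paste(bad, collapse = ", ")), call. = FALSE)
    neg <- which(v < 0)
    if (length(neg)) stop(sprintf("negative concentration in column %s, row(s) %s",
                                  f, paste(neg, collapse = ", ")), call. = FALSE)
    df[[f]] <- v
  }
  message(sprintf("read cohort: %d rows, %d columns", nrow(df), ncol(df)))
  df
}

#' Write a cohort CSV with provenance header
#'
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @param seed,config Recorded in the provenance header.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path, seed = NULL, config = NULL) {
  write_table_prov(cohort[, c(cohort_meta_cols,
                              intersect(gag_features, names(cohort)))],
                   path, sep = ",", seed = seed, config = config)
}

#' Build a standardized design matrix for score construction
#'
#' Selects the detectable features of the requested fluid(s), drops a class
#' charge when only one sulfated species of that class is detectable (the
#' charge would duplicate a single fraction), standardizes on the given
#' cohort and returns the candidate matrix. For `fluid = "combined"` the
#' plasma and urine features of subjects with both fluids are joined with
#' `plasma_`/`urine_` prefixes.
#'
#' @param cohort Cohort data.frame with computed features (see
#'   [compute_features()]).
#' @param detect A `gag_detectability` object (computed if NULL).
#' @param fluid `"plasma"`, `"urine"` or `"combined"`.
#' @param standardizer Optional pre-fitted `gag_standardizer` to re-apply
#'   (e.g. development transform on validation data).
#' @return List: `X` (standardized matrix), `y` (1 = cancer), `meta`
#'   (subject-level metadata), `standardizer`, `features`.
#' @export
make_design <- function(cohort, detect = NULL, fluid = c("combined", "plasma", "urine"),
                        standardizer = NULL) {
  fluid <- match.arg(fluid)
  if (is.null(detect)) detect <- detectability_filter(cohort)
  fluids <- if (fluid == "combined") c("plasma", "urine") else fluid
  wide <- NULL
  feats <- character(0)
  for (fl in fluids) {
    det_f <- detect$fluids[[fl]]
    if (is.null(det_f)) stop("fluid not in cohort: ", fl, call. = FALSE)
    f_det <- det_f$detectable
    # drop a charge backed by a single detectable sulfated species
    for (cls in c("cs", "hs")) {
      ch <- paste0("charge_", cls)
      sp <- paste0(cls, "_", if (cls == "cs") cs_species else hs_species)
      w <- if (cls == "cs") sulfo_weights_cs else sulfo_weights_hs
      n_charged <- sum(det_f$mask[sp[w > 0]])
      if (ch %in% f_det && n_charged < 2) f_det <- setdiff(f_det, ch)
    }
    sub <- cohort[cohort$fluid == fl, , drop = FALSE]
    pre <- if (fluid == "combined") paste0(fl, "_") else ""
    tab <- sub[, c("subject_id", f_det), drop = FALSE]
    names(tab) <- c("subject_id", paste0(pre, f_det))
    meta_f <- sub[, intersect(cohort_meta_cols, names(sub)), drop = FALSE]
    if (is.null(wide)) {
      wide <- cbind(meta_f[, setdiff(names(meta_f), "sample_id"), drop = FALSE],
                    tab[, -1, drop = FALSE])
      wide$subject_id <- sub$subject_id
    } else {
      wide <- merge(wide, tab, by = "subject_id")
    }
    feats <- c(feats, paste0(pre, f_det))
  }
  if (nrow(wide) == 0) stop("no subjects with all requested fluids", call. = FALSE)
  if (is.null(standardizer)) {
    standardizer <- fit_standardizer(wide, feats)
  }
  std <- predict(standardizer, wide)
  keep <- stats::complete.cases(std[, feats, drop = FALSE])
  if (any(!keep)) {
    warning(sum(!keep), " subjects dropped for missing feature values", call. = FALSE)
  }
  std <- std[keep, , drop = FALSE]
  list(X = as.matrix(std[, feats, drop = FALSE]),
       y = as.integer(std$diagnosis == "cancer"),
       meta = std[, setdiff(names(std), feats), drop = FALSE],
       standardizer = standardizer, features = feats, fluid = fluid)
}

# doubles as shortest-exact decimal strings so the JSON round trip is
# bit-identical (plain numeric JSON loses the last ulp)
num_exact <- function(x) {
  d <- dim(x)
  out <- sprintf("%.17g", x)
  if (!is.null(d)) dim(out) <- d else names(out) <- names(x)
  out
}

#' Serialize an MCED model to JSON
#'
#' Numeric fields are written as full-precision decimal strings so that a
#' saved and reloaded model scores bit-identically.
#'
#' @param model An `mced_model`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_model <- function(model, path) {
  obj <- list(
    format_version = MODEL_FORMAT_VERSION,
    package_version = model$version,
    fluid = model$fluid,
    features = model$features,
    projected_draws = num_exact(unclass(model$projected_draws)),
    cutoffs = as.list(num_exact(model$cutoffs)),
    achieved_specificity = as.list(attr(model$cutoffs, "achieved_specificity")),
    prior = model$prior,
    seed = model$seed,
    size = model$size,
    display_cap = model$display_cap,
    standardization = if (!is.null(model$standardizer)) {
      list(features = model$standardizer$features,
           mean = as.list(num_exact(model$standardizer$mean)),
           sd = as.list(num_exact(model$standardizer$sd)))
    }
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an MCED model from JSON
#'
#' @param path Model JSON path.
#' @return An `mced_model` whose predictions are bit-identical to the saved
#'   model's.
#' @export
read_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse model file: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(obj$format_version) || obj$format_version != MODEL_FORMAT_VERSION) {
    stop("model format version mismatch: expected ", MODEL_FORMAT_VERSION,
         ", found ", obj$format_version %||% "none", call. = FALSE)
  }
  pd <- as.matrix(obj$projected_draws)
  storage.mode(pd) <- "double"
  colnames(pd) <- c("(Intercept)", obj$features)
  cutoffs <- vapply(obj$cutoffs, as.numeric, numeric(1))
  attr(cutoffs, "achieved_specificity") <- unlist(obj$achieved_specificity)
  std <- NULL
  if (!is.null(obj$standardization)) {
    std <- structure(list(features = obj$standardization$features,
                          mean = vapply(obj$standardization$mean, as.numeric, numeric(1)),
                          sd = vapply(obj$standardization$sd, as.numeric, numeric(1))),
                     class = "gag_standardizer")
  }
  structure(list(features = obj$features, projected_draws = pd,
                 path = NULL, size = obj$size, cutoffs = cutoffs,
                 prior = obj$prior, fluid = obj$fluid, seed = obj$seed,
                 standardizer = std,
                 reference_summary = NULL,
                 display_cap = unlist(obj$display_cap),
                 version = obj$package_version),
            class = "mced_model")
}

#' Read/write a pipeline configuration (JSON)
#'
#' Configurations are JSON objects with a fixed key set; unknown keys are
#' rejected.
#'
#' @param path JSON path.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("fluid", "prior_df", "prior_scale", "specificity", "bootstrap_B",
             "seed", "ci_method", "detect_threshold", "rope", "ess_min",
             "rhat_max", "prevalence", "cap", "verbose")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg
}
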