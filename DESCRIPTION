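Package: gagmced
Title: Free Glycosaminoglycan Profiles for Multi-Cancer Early Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse free glycosaminoglycan (GAG) disaccharide profiles
    ("GAGomes") in plasma and urine as metabolic biomarkers for multi-cancer early
    detection (MCED). Turns 17-disaccharide concentration panels into the 39-feature
    GAGome with detectability filtering and outlier screening; screens per-feature
    cancer-type deviations from healthy baseline with a Bayesian skew-normal mixed
    model and region-of-practical-equivalence (ROPE) decisions; builds sparse MCED
    scores by projection-predictive forward selection on a Bayesian logistic
    reference model; evaluates discrimination (AUC, sensitivity at fixed
    specificity, PPV/NPV) with bootstrap optimism correction; stratifies overall
    survival by score; and estimates longitudinal GAGome trends in mouse
    tumour-progression experiments. Includes a synthetic-cohort generator with the
    statistical structure the analysis assumes, for ground-truth recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
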