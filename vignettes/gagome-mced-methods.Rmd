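---
title: "Methods: free-GAGome scores for multi-cancer early detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-GAGome scores for multi-cancer early detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the tunable parameters with defaults and units, what the
synthetic-data generator emulates (and what it does not, hence what a green
test does and does not establish), the numerical choices, and known
limitations. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The measurement and the feature calculus

A free-GAGome panel reports semi-absolute concentrations (µg/mL) of 17
disaccharides: eight chondroitin sulfate (CS) species, eight heparan sulfate
(HS) species, and hyaluronic acid (HA). `compute_features()` expands these to
39 features per fluid: the 17 concentrations, class totals, 16 mass
fractions (% of class total), two CS ratios (4S/0S, 6S/0S), and the CS and
HS *charge* — the mass-fraction-weighted mean sulfo-group count, a
dimensionless summary in [0, 3].

**Charge on fractions, not concentrations.** The charge could be defined on
raw concentrations or on fractions; we compute it on mass fractions. The
quantity is conventionally annotated as unitless and sits alongside the
compositional features; defining it on fractions makes it scale-invariant
(multiplying the whole panel by c > 0 leaves it unchanged), which is the
behaviour a "composition summary" should have. This is a package design
choice; the alternative definition differs only by a factor of the class
total.

**Below-LOD handling.** Values below the 0.1 µg/mL limit of detection are
recorded as 0 and enter sums and fractions as 0. Concentrations are
semi-absolute and undetectable features are dropped anyway, so any
imputation scheme (LOD/2, censored likelihood) would only affect features
that never reach downstream analysis. Ratios with a zero denominator are
missing (`NA`), never infinite, and ratio features are excluded from the
per-feature Bayesian screen, where near-zero denominators make the
likelihood ill-behaved.

**Detectability.** A concentration feature is detectable in a fluid if its
median across samples exceeds the threshold (default 0.1 µg/mL,
configurable). We use the median deliberately: the mean is dragged over the
threshold by a handful of high samples even when the majority of the cohort
is censored at the LOD. Calculated features are kept only when their
constituents are detectable, operationalised as: totals need at least one
detectable member; a fraction needs its own species detectable; a ratio
needs numerator and denominator; a class charge needs **at least two**
detectable sulfated species — with a single charged species the charge is a
deterministic rescaling of one fraction and carries no independent
information (this is what removes the plasma CS charge when 4S CS is the
only detectable charged plasma species). On development-style synthetic data
this yields 6 detectable plasma and 17 urine features.

**Outlier screen.** Two robust steps per fluid: total CS outside
median ± 5·MAD, then any detectable feature outside median ± 5·MAD. When the
MAD degenerates to zero the screen falls back to IQR/1.349 with a warning.
The exact two-step rule used with the original assay is not public; this
replacement is documented in the screen's output (`rule` field) and its k is
configurable.

## 2. Per-feature Bayesian screening (ROPE)

Each standardized feature is modelled as skew-normal,
`z ~ SN(ξ_g + u_b, ω_gb, α)`, with diagnosis group g fixed, batch b random
(`u_b ~ N(0, σ_u)`), shared slant α, and the group × batch variance
interaction multiplicative on the scale: `log ω_gb = λ_g + κ_b` with
`κ_b ~ N(0, σ_κ)`. Priors: Normal(0, w) on group locations with w ∈
{2.5, 5, 10} (default 5; `prior_sensitivity()` refits under the other two
widths), Gamma(1, 2) on SD hyperparameters, Normal(0, 5) on α.

A cancer type's deviation from healthy is summarised by the difference of
group-median draws (the skew-normal median `ξ + ω·m₀(α)`), and called
**credible** when the 95% CrI excludes 0 *and* at most 5% of the posterior
falls inside the region of practical equivalence ±0.2 standardized units —
a band consistent with the assay's 15–25% measurement CV, inside which a
shift is practically indistinguishable from measurement noise. We default to
medians rather than means because the response is skewed; both are exposed
on the fitted object.

**Sampler.** Adaptive random-walk Metropolis on the *centered*
parametrization (group mean, group log-SD, slant): the direct (ξ, ω, α)
parametrization has a strong likelihood ridge between location and slant
that cripples any random-walk sampler. Batch effects are sum-to-zero
centered inside the likelihood so the group means stay identified.
Covariance adaptation runs only during warmup (so kept draws target the
exact posterior). Defaults: 4 chains × 1000 kept draws after 600 warmup.

**Convergence.** The configured thresholds are deliberately strict
(ESS > 5000, R-hat < 1.001). A desk-scale random-walk sampler will usually
*not* reach them for the absolute group medians — the fits are flagged
`converged = FALSE` and the diagnostics are attached rather than hidden.
The ROPE decision depends only on the *difference* draws, which mix an
order of magnitude better (the slow direction is the common location), and
the decision operating characteristics are what the test suite checks:
false-credible rate ≤ 7% on null features and ≥ 80% detection of 0.5 SD
shifts at n = 200/group.

## 3. MCED score construction

The reference model is Bayesian logistic regression of cancer vs healthy on
all standardized detectable candidates, with heavy-tailed t(df = 7,
location 0, scale 2.5) priors on intercept and coefficients. Sampling uses
independence Metropolis with a multivariate-t proposal centred at the
posterior mode with Laplace covariance (inflated 1.3×): for these
near-Gaussian posteriors acceptance is high and draws are close to
independent, and the scheme remains asymptotically exact. Defaults mirror
4 chains × 500 kept draws. A df = 3 prior appears as the default of
`bootstrap_validate()`; both dfs are configurable, and we kept the two
defaults distinct deliberately rather than silently harmonising them.

**Projection.** For draw s with fitted probabilities p_s, the submodel
coefficients minimise Σ_i KL(Bernoulli(p_s(x_i)) ‖ Bernoulli(q_θ(x_i))) — a
logistic fit with p_s as soft labels, solved by damped Newton with warm
starts. Projecting onto the full candidate set reproduces the reference
predictions to machine precision (tested at 1e−6); the empty projection is
the closed form logit(mean p_s).

**Selection.** Greedy forward search; at each step the candidate maximising
cross-validated projected elpd is added. The reference elpd is estimated by
truncated importance-sampling LOO (weights capped at √S × mean); submodel
elpd by K-fold (default K = 10) re-projection using clustered draws
(default 10 k-means clusters) — an approximation to full LOO forward
selection that bounds the inner-fit count; the reference posterior is not
refit per fold. Elpd ties are broken toward the feature with the larger
absolute posterior-mean reference coefficient, making the path deterministic
given the seed. The chosen size is the smallest whose elpd difference to
the reference is within one standard error of zero (SE = √n × SD of
pointwise differences); if none qualifies, the cap is used with a warning.

**The score.** 400 projected draws of the selected submodel; the score of a
sample is the mean projected linear predictor — the log-odds of any-type
cancer. Averaging linear predictors (not inverse-logit probabilities) keeps
the score an honest log-odds and is monotone-equivalent for ranking either
way. Display capping to (−6, 6) affects plots only, never classification.
Cutoffs: the smallest threshold achieving at least the target specificity on
controls, ties broken upward (the returned cutoff is the midpoint to the
next distinct control score). The pruned variant
(`prune_to_independent()`) restricts candidates to semi-absolute
concentration features before re-running selection, trading a little
discrimination for robustness to compositional re-normalisation artifacts.

## 4. Evaluation

AUC uses the rank statistic with tie correction (exact against exhaustive
pair counting) and a DeLong-style asymptotic CI; a bootstrap CI was
considered and not needed at these n. Sensitivity at fixed specificity uses
the control-anchored cutoff and a binomial CI — Wald by default (matching
the convention of the headline numbers this package is tested against),
Clopper–Pearson optionally; the report names the method. Subgroup
sensitivities always reuse the cutoff fixed on **all** controls. PPV/NPV
are the closed-form screening identities at a stated prevalence (default
1%). The scaled Brier score is 1 − Brier/Brier_null with the null forecast
equal to the case fraction. Bootstrap validation repeats the *entire*
construction (reference fit, capped selection with the one-SE rule,
projection, scoring) per resample and reports optimism under both
conventions — bootstrap-vs-original and bootstrap-vs-assessment
(out-of-bag) — because the literature is not consistent about which is
meant. Caps follow size = min(one-SE size, cases/10, fluid cap) with fluid
caps 51 (plasma), 22 (urine), 18 (combined).

## 5. Survival analysis

Cox proportional-hazards fits go through the `survival` package (Efron ties
by default — the common default of the tooling this analysis style uses;
Breslow available, and used in tests where duplicated data make every time
tied). Age enters as a scaled 3-knot restricted cubic spline with knots at
the 0.1/0.5/0.9 quantiles. Kaplan–Meier stratification dichotomizes at the
95%-specificity cutoff *taken as given* — never re-derived on subsets — and
reports the low-vs-high hazard ratio and log-rank p. Median follow-up uses
reverse Kaplan–Meier. Proportional hazards are checked by the Schoenfeld
residual test with the KM time transform (the identity transform is more
sensitive to censoring patterns); the package treats the conventional
"odds ratio" phrasing of Cox output as hazard ratios throughout. Internal
validation bootstraps Somers' Dxy and reports the optimism and the relative
correction (< 20% conventionally acceptable). The
maximally-selected-rank-statistics alternative cutoff is deliberately not
implemented (a sensitivity analysis in the source material); reports note it
as such.

## 6. Longitudinal mouse analysis

Pooled cage urine is used only while both mice in the cage are alive
(`cage_filter()`); plasma is per-mouse and never cage-filtered. PCA runs on
scaled features with 95% confidence ellipses from a bivariate t fitted to
the first two PCs per timepoint; the ellipse df is n_points − 2 (minimum 3),
a choice the source does not pin down. Per-feature trends use a Gaussian
mixed model on the standardized feature (timepoint fixed, unit random) with
conjugate Gibbs sampling; timepoint-mean draws are back-transformed to the
raw concentration scale before computing percent change vs baseline, because
percent change on a standardized scale is not interpretable and credible
intervals in percent units imply a raw-scale denominator. Draws with a
non-positive baseline level make the percent change undefined and are
reported missing rather than clamped.

## 7. The synthetic generator: what it emulates and what it does not

`gag_sim_config()` states the generative world once; its defaults are the
conditions the analysis assumes, and they are not tuned to test outcomes.

* **Marginals.** Each concentration is skew-normal (slant α = 4, scale
  ω = 0.35 × median for detectable features, 0.5 × median otherwise),
  truncated at zero and floored to 0 below the 0.1 µg/mL LOD. Baseline
  medians are set so that a development-style cohort reproduces the
  6-plasma/17-urine detectability pattern with comfortable margins
  (detectable medians ≥ 3× threshold, undetectable ≤ 0.5×).
* **Effects.** Three template effects in SD units: a universal +1.0 SD
  0S CS increase in both fluids (every cancer type), a −0.8 SD plasma 4S CS
  shift in CRC/NHL (lowering plasma CS charge), and a +0.8 SD urine 2S6S CS
  increase in PCa. The 14 type labels do not carry 14 biologically distinct
  signatures — only these three templates.
* **Structure.** Batch random intercepts (SD 0.15), optional type × batch
  scale multipliers, stage labels with a weak ordinal dependence
  (slope 0.3) of stage on the realised 0S CS deviation, ~2% unspecified
  stages. Arm sizes default to 250 healthy + 14 × 18 cancer (desk scale).
* **Confounders.** Validation-style cohorts draw CRP (log-normal) and HDL-C
  (normal) and shift the universal informative feature by standardized
  confounder values; the loading comes from the normal-copula mapping of
  the target Kendall τ (defaults 0.29 for CRP, −0.16 for HDL-C) times a
  1.25 inflation calibrated once by simulation against the oracle score —
  the analytic mapping ignores the type mixture, skewness and LOD
  truncation.
* **Survival and mice.** Weibull times (shape 1.2, median 18 months in the
  high-score group) with hazard ratio 0.61 for low vs high and uniform
  censoring bisected to a target event fraction (default 50%); mouse
  trajectories plant multiplicative 0S CS trends reaching +148% (plasma)
  and +116% (urine) at metastasis over four timepoints, with unit random
  intercepts at 12% and residual noise at 14% of the baseline level.

A green recovery test therefore establishes that the pipeline recovers known
truth *under this stated world* — skew-normal marginals, additive SD-unit
effects, exchangeable batches — not that it is robust to matrix effects,
assay drift, non-monotone confounding, informative censoring, or cancer-type
signatures richer than the three templates. The generative Bayes oracle
(`bayes_score()`) evaluates the true likelihood ratio on the informative
features ignoring the (rare) LOD flooring there, so it is a near-exact,
slightly optimistic bound.

One generator property deserves note: the oracle score's control
distribution has a heavy left tail (LOD-floored panels give strongly
negative log-likelihood ratios), so trimming high-CRP/low-HDL controls —
which removes mostly *cancer-like* scorers — lowers the upper quantiles of
the control scores (the specificity cutoffs) without necessarily lowering
the raw variance. The confounder-subgroup test asserts the cutoff-location
property, which is the clinically meaningful one.

## 8. Numerical choices and degenerate inputs

* Standardization uses the population SD (divide by n); transforms are
  stored and re-applied to new data, never refit.
* All samplers seed through a single integer; derived child seeds stay below
  2³¹. Identical (config, seed) pairs regenerate identical cohorts.
* `set_cutoffs` on all-equal controls returns a cutoff just above the common
  value (specificity 100%); specificity 1.0 returns a cutoff above the
  maximum control score.
* Wald intervals at boundary sensitivities (0 or 1) are degenerate and
  flagged with a warning rather than silently truncated.
* One-class bootstrap resamples are redrawn; out-of-bag sets need ≥ 10
  samples and both classes.
* Model JSON stores doubles as 17-significant-digit decimal strings so a
  saved model scores bit-identically after reload; a format-version field
  guards against silently reading incompatible files.
* Constant features error in the standardizer (naming the feature); single
  batches degrade the mixed model to no random effect with a warning; zero
  events, single survival strata, single units and single timepoints all
  error with specific messages.

## 9. Known limitations

* The random-walk sampler's ESS for absolute group medians is far below the
  strict configured thresholds at desk scale; decisions ride on the
  better-mixing difference draws, and the `converged` flag is honest about
  the rest. A gradient-based sampler would remove this caveat.
* Forward selection approximates LOO with K-fold re-projection around a
  single reference fit; with very small n or very strong candidate
  correlation the path can differ from full cross-validated selection.
* The generator's three effect templates cannot exercise cancer-type
  classification (out of scope here) and make "per-type" sensitivities
  largely exchangeable beyond the planted contrasts.
* Real-data headline metrics from the motivating study (development AUCs,
  per-type sensitivities, validation AUC) are not reproducible because those
  cohorts are not public; they enter only as generator anchors and worked
  examples on printed arithmetic.
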