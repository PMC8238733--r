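---
title: "Timing imprecision and impulsive choice: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timing imprecision and impulsive choice: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its own science: the valuation
model, the peak-procedure analysis chain, the synthetic-data generator that
stands in for an animal cohort, and the numerical and design decisions taken
where more than one defensible choice existed.

## 1. The valuation model

A unit reward after delay $t$ seconds is discounted hyperbolically,
$v(t) = 1/(1+kt)$, with $k \ge 0$ in s$^{-1}$ (default $k = 0.54$, an
empirical starling estimate; `discount()`). An individual's perception of a
delay is unbiased but noisy:
$$p_{i,t} \sim \mathcal{N}\!\left(t,\; \alpha_i + \beta_i t\right),$$
with fixed imprecision $\alpha_i$ (seconds) and proportional imprecision
$\beta_i$ (dimensionless). The value of an option is the average of $v$ over
perceived delays (`expected_discounted_value()`), and the choice-relevant
statistic is the relative valuation of a smaller-sooner (3 s) versus a
larger-later (8 s) reward, normalised by a noiseless timer
(`relative_valuation()`, `prediction_surface()`). Reward magnitudes cancel
in this double ratio, which is why they do not appear as arguments; the
choice generator (Section 3) keeps them.

**Scale of the noise term.** Whether $\alpha + \beta t$ is a standard
deviation or a variance is ambiguous in the field's usual notation. The
package defaults to the *standard-deviation* reading — it keeps the
empirical Spread-versus-FI line (Section 4), which is a width in seconds,
on the same scale as the generative noise, and it makes constant coefficient
of variation (scalar timing) correspond to $\alpha = 0$ with $\beta$ the
Weber fraction of the full width. `scale = "variance"` switches every
function to the other reading.

**Negative perceived durations.** The Normal admits $p < 0$, where $v$
exceeds 1 and blows up at the pole $t = -1/k$. Delays cannot be negative, so
draws below zero are *censored at zero* (`sample_perceived()`); censoring
rather than rejection-resampling keeps the number of random draws, and hence
seeded reproducibility, fixed. Two consequences are worth knowing:

* Censoring caps the value of a perceived delay at $v(0) = 1$. For large
  fixed imprecision at a short delay (e.g. $\alpha = 4$ at $t = 3$ s, where
  roughly a quarter of draws hit the floor) this *saturates* the
  over-valuation of the sooner reward, so the relative valuation is no
  longer monotone in $\alpha$ out to $\alpha = 4$: it rises to about
  $\alpha \approx 2$ and then falls back. Quadrature over the censored
  density confirms this is a property of the model under censoring, not
  Monte-Carlo error, and no combination of scale reading and truncation
  policy restores joint monotonicity in both parameters over the full
  $\{0..4\}\times\{0.1..1.5\}$ grid. The directional claims hold on the
  interior where the censored mass is small: $R$ increases in $\alpha$ for
  $\alpha \lesssim 2$ at low $\beta$, and decreases in $\beta$ everywhere.
* Censoring shifts the mean perceived delay upward by an amount bounded by
  a few seconds at the noise levels considered. As $k \to 0$ the relative
  valuation therefore approaches 1 only up to a deterministic $O(k)$
  remainder ($\approx 10^{-4}$ at $k = 10^{-4}$); the tests allow for it
  explicitly.

**Normalisation baseline.** The noiseless baseline is the deterministic
timer, $R = 1$ at $\alpha = \beta = 0$, which is the only internally
consistent definition of "perfectly precise".

**Monte-Carlo settings.** Each expectation uses $10^5$ draws by default;
every returned value carries a delta-method standard error (`mc_se`), and
monotonicity checks use 3-SE tolerances. Surfaces are bit-reproducible
given a seed; grid cells use independent draws.

## 2. The peak-procedure analysis chain

`aggregate_probe()` implements the mean-response approach: for each bird and
key, the mean pecks per 0.5-s bin across all probe trials in the bird's last
4 recorded days (probe trials run 135 s; bins are half-open, 0-indexed).
`fit_polynomial()` fits an unweighted 10th-order least-squares polynomial to
each mean curve; the time axis is affinely rescaled to $[-1, 1]$ for
conditioning (the rescaling is stored with the coefficients, and predictions
are in original units; the fit matches a direct normal-equations solve).
`extract_peak()` takes Peak as the argmax of the fitted curve over the
window — a 0.01-s grid scan polished by local optimisation, ties broken
toward the earliest time — Peak Rate as the fitted value there, and Spread
as the distance between the nearest crossings of *half the absolute Peak
Rate* on either side (not baseline-subtracted: high baseline responding
therefore inflates Spread, which is documented rather than corrected). A
missing crossing clips the bound to the window edge and sets a flag; a
non-positive fitted maximum flags the curve as degenerate instead of
dropping it silently. Negative fitted values elsewhere are permitted; the
bounds search uses the fitted function as-is.

**Resolution of the order-10 fit.** A degree-10 polynomial over a 135-s
window has an effective resolution of roughly a dozen seconds. It cannot
represent a bump much narrower than that: a noiseless Gaussian of
$\sigma = 4$ s fitted over the full window comes back with its half-max
width inflated by about 60% (an independent `numpy.polyfit` cross-check
gives the same number). The package therefore validates Gaussian recovery
on a fit window commensurate with the bump (0–30 s, where peak location is
exact and Spread is recovered to 0.5%), and treats the full-window
inflation of narrow spreads — visible at the 5-s interval in simulated
cohorts, where mean Spread comes out around 11 s against a generative
10.8 s plus fit distortion — as a property of the published method that the
package reproduces faithfully. Because the inflation is a smooth
transformation of the underlying width, rank-order recovery of the
imprecision parameters is essentially unaffected (Section 5).

## 3. The synthetic cohort generator

`cohort_spec()` fixes the study conditions; `simulate_cohort()` draws a
cohort. The defaults emulate the structure of a hand-reared starling cohort:
28 birds from 8 natal families (round-robin assignment, sizes 3–4), balanced
across a 2×2 developmental design (food Amount: Lean/Plenty × begging
Effort: Easy/Hard) with sexes shuffled so no factor is confounded by
construction. True imprecision parameters are bivariate normal with
$\alpha \sim N(3.76, (1.18\sqrt{28})^2)$ s and
$\beta \sim N(1.40, (0.12\sqrt{28})^2)$ — means and cohort-level SDs chosen
to match reported cohort summaries (mean ± SE over 28 birds) — clipped at
zero, with true correlation 0 by default so that estimator-induced coupling
(Section 5) is identifiable. A pair clipped to exactly $(0,0)$ is nudged to
$\beta = 10^{-3}$ so the bird remains generatively valid.

**Response model.** No generative rate model is implied by mean-response
data, so the generator uses the simplest curve consistent with single-peaked
responding: expected pecks per 0.5-s bin are a Gaussian bump over a flat
baseline, centred on the trained interval, whose *full width at half maximum
equals the bird's noise scale* $\alpha + \beta F$ at that interval
(`probe_rate_curve()`); counts are Poisson. This makes the analysis chain's
Spread estimand equal the generative truth up to baseline and
polynomial-resolution distortion. Defaults: baseline 0.05 and amplitude 2
pecks per bin (peak rates of ~4 pecks/s, a realistic operant pecking rate,
with sparse off-peak responding), 60 probe trials spread over 4 days —
the stable end-of-training window the analysis uses.

**Choice model.** The probability of choosing the smaller-sooner option is
$\mathrm{logit}^{-1}((V_{ss} - V_{ll})/\tau)$ with
$V = \text{magnitude} \times E[v(\text{delay})]$ computed from the bird's
own $(\alpha, \beta, k)$, and SS counts are Binomial over 240 choice trials
(roughly six sessions of free choices). The softmax is the minimal standard
link between values and choice. The temperature default $\tau = 0.2$ value
units was chosen so that simulated cohorts produce a non-degenerate spread
of SS-choice proportions (roughly 0.10–0.52 with mean ≈ 0.19 under default
parameters); much smaller temperatures saturate the logistic and collapse
all birds to near-exclusive larger-later preference.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: bursty within-trial pecking (the very feature that
defeats single-trials step analysis), perch-return gaps, motivational drift
across sessions, training/acquisition dynamics, inter-trial intervals,
asymmetric response curves (real curves rise faster than they fall), and any
delay-magnitude interactions in choice beyond the valuation model itself.

## 4. Imprecision decomposition and diagnostics

`fit_imprecision()` regresses each bird's three Spreads on FI duration by
ordinary least squares: intercept $\hat\alpha$ (fixed imprecision), slope
$\hat\beta$ (proportional imprecision). Weighted regression would
acknowledge the larger measurement error at long intervals, but plain OLS is
retained for fidelity to the standard analysis. Negative $\hat\alpha$ is
physically impossible yet statistically expected from a three-point
extrapolation to FI = 0; estimates are kept as-is and a truncated variant
(`alpha_truncated = max(alpha_hat, 0)`) is carried in parallel for
sensitivity analyses (`truncate_alpha()`).

`scalar_variance_diagnostics()` tests the scalar-variance property: a
constant coefficient of variation CV = Spread/FI across intervals. CV
$= \alpha/F + \beta$ decreases in $F$ whenever $\alpha > 0$, so the signature
of fixed imprecision is a negative LONG contrast in a mixed model of CV on
interval category (random intercept per bird, ML), alongside one-sample
$t$ tests of the cohort-mean $\hat\alpha$ and $\hat\beta$ against zero.

**Estimator coupling.** With only three design points, the OLS intercept and
slope share measurement error: $\mathrm{cov}(\hat\alpha, \hat\beta) =
-\bar{F}\sigma^2/S_{FF} < 0$ under homoscedastic spread noise. So even when
the true components are uncorrelated, their estimates correlate negatively —
which cautions against reading the empirical $\hat\alpha$–$\hat\beta$
correlation as biology. `coupling_experiment()` demonstrates this on full
generator-to-estimates pipelines: 30 replicate cohorts with true correlation
zero, in a sparse-data regime of 4 probe trials per bird (one per day) where
single-cohort measurement error is visible; the mean per-cohort estimate
correlation comes out clearly negative (about $-0.6$) while the mean true
correlation stays near zero. The replicate count averages away the sampling
noise of a correlation at $n = 28$.

## 5. Linkage statistics

`fit_impulsivity_model()` fits the primary inferential model: proportion of
smaller-sooner choices on one standardized imprecision component plus sex,
with a random intercept for natal family. The two components are far too
collinear (Section 4) to enter together, so predictors are entered singly.
Estimation is maximum likelihood, and $p$-values use Satterthwaite degrees
of freedom via `lmerTest`; singular fits (family variance at the zero
boundary, common at 8 families) are reported and flagged, not errored.
Proportions are modelled on the Gaussian scale rather than by binomial GLMM —
a fidelity-over-optimality choice matching the standard analysis. Missing
birds are dropped listwise.

A caveat the package quantifies rather than hides: Satterthwaite tests on
*ML* fits are mildly liberal at this design size. In null simulations
(27 birds, 8 families, `run_type1_study()`), the empirical type-I rate is
about 7–8% at a nominal 5%, while refitting the same data by REML gives
about 5.3%. ML is retained throughout for consistency with the analysis
convention the package reproduces; users wanting exact nominal size at small
$n$ should treat $p$-values near 0.05 with correspondingly mild suspicion.

`fit_treatment_models()` fits the developmental battery: standardized
$\hat\alpha$ and $\hat\beta$ on Amount + Effort + Sex (random intercept:
family), and per-key Spread and Peak (standardized within FI via
`standardize_by_fi()`, so intervals are comparable) plus Peak Rate (raw
scale, with Key as an extra fixed effect — per-key standardization would
erase exactly the key differences that model asks about) with random
intercepts for family and bird-within-family. Each model starts with the
Amount×Effort interaction and drops it if $p \ge 0.05$ (sequential removal,
least significant first; with one interaction this is a single step).
Estimated marginal means per treatment level come from `emmeans` via
`treatment_means()`.

`split_half_consistency()` assesses whether imprecision is a stable
individual attribute: the last two probe days and the two days before them
are analysed independently through the whole chain, and the variance of the
resulting $\hat\alpha$ and $\hat\beta$ is partitioned into individual,
family and residual components (crossed random intercepts for bird and
family, ML; percentages of the total, summing to 100). Under the default
generator the individual share is high for both components and higher for
$\hat\beta$ than $\hat\alpha$, since the intercept estimate carries more
measurement error.

## 6. Problem sizes, determinism, and degenerate inputs

The test suite and the acceptance script use: $10^5$ Monte-Carlo draws per
expectation (surfaces and directional checks at 3-SE tolerance), 20 random
parameter tuples for the quadrature cross-check, one 28-bird/60-trial cohort
for rank-recovery (Spearman $\hat\beta$ vs $\beta$ ≈ 0.98; $\hat\alpha$
recovery is weaker, ≈ 0.6–0.8, because ~27% of true $\alpha$ draws clip to
zero and tie), 50 replicate cohorts for the sign of the β̂→impulsivity
coefficient, 30 cohorts for estimator coupling, and 500 null cohorts for the
type-I rate. These sizes were chosen so each study estimates its quantity
with comfortable margin; a full acceptance run takes a few minutes on one
CPU.

Every stochastic function takes a `seed` and restores the caller's RNG
state; equal seeds give bit-identical output. Degenerate inputs fail loudly
with named culprits: invalid noise parameters, grid cells with negative
imprecision, birds lacking probe trials in the analysis window, missing FIs
in the decomposition, zero within-FI variance in standardization, and
rate curves of non-positive width.

## 7. Known limitations

* The censoring policy makes the valuation model's $\alpha$ effect
  non-monotone at the extreme short-delay/high-$\alpha$ corner (Section 1);
  conclusions there depend on an unstated modelling choice and should not be
  leaned on.
* Order-10 polynomials inflate narrow spreads over the full probe window
  (Section 2); absolute Spread values are method-dependent even though ranks
  are stable.
* The absolute half-max convention couples Spread to baseline response rate;
  motivated responders look more imprecise.
* Three FIs give strongly coupled $(\hat\alpha, \hat\beta)$; more interval
  durations would decouple them.
* Gaussian mixed models on choice proportions and ML-based Satterthwaite
  tests are mildly miscalibrated at $n \approx 27$ (Section 5).
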