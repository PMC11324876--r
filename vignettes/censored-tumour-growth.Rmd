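---
title: "Censored tumour-growth inference: models, likelihood and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored tumour-growth inference: models, likelihood and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censgrowth)
```

## The problem

Longitudinal tumour-volume experiments in mice are measured by callipers:
very small tumours cannot be measured at all, and animals are euthanised for
ethical reasons once the tumour exceeds a threshold (typically 1.5 cm³).
Both ends of a growth study are therefore *censored* — at early times only
the largest tumours are recorded, at late times only the slowest-growing
animals remain. Discarding these unmeasurable points biases any fitted
growth model: the curve is pulled up where only large tumours were
measurable and down where only small ones were, which in turn distorts the
initial volume, the carrying capacity, and every extrapolation beyond the
measured window.

censgrowth implements a Bayesian estimation pipeline that keeps the
censored observations in the likelihood, together with the diagnostics
needed to judge what the data can and cannot constrain: profile
log-likelihood curves, local sensitivities, marginal posterior summaries
and solution-curve envelopes. Because the motivating experimental dataset
is external, the package ships a synthetic-cohort generator that emulates
its structure, so every stage is testable end to end without a download.

## Growth models

Five nested ordinary-differential-equation models are supported, each with
a closed-form solution evaluated by `growth_curve()`:

| name   | dC/dt | parameters |
|--------|---------------------------------------------------|------------|
| Rich   | μ/min(α,1) · C [1 − (C/κ)^α]                      | C₀, μ, κ, α |
| Logis  | μ C (1 − C/κ)                                     | C₀, μ, κ |
| Gomp   | −μ C ln(C/κ)                                      | C₀, μ, κ |
| ExpCap | C(t) = min(C₀ e^{μt}, κ)                          | C₀, μ, κ |
| Exp    | μ C                                               | C₀, μ |

`C` is volume in mm³, `μ` a rate in 1/day, `κ` the carrying capacity in
mm³ and `α` a dimensionless shape. The generalised logistic (Richards)
family uses the coefficient μ/min(α, 1), which keeps the interpretation of
μ stable on both sides of the logistic point α = 1; the price is a
discontinuity in the best-fit μ exactly at α = 1, and we know of no
smoother replacement with the same property, so min(α, 1) is used as is.
Richards with α = 1 *is* the logistic model (same code path, exact
equality); α → 0 approaches Gompertz and α → ∞ approaches the capped
exponential, which is implemented directly as the algebraic min of the two
closed forms rather than as an ODE. μ = 0 is allowed and gives a constant
curve.

Numerically, all curves are evaluated in log space. For the Richards form
the term (κ/C₀)^α is never formed directly: with
L = α log(κ/C₀), the solution is assembled from `log1p`/`expm1`
identities on L, so shapes anywhere in α ∈ [10⁻⁵, 10⁵] — which the prior
bounds demand — neither overflow nor lose precision, including curves
started above capacity (κ < C₀).

```{r}
growth_curve("Gomp", c(C0 = 100, kappa = 1000, mu = 0.1), log(2) / 0.1)
```

## Likelihood

Measurement error on tumour volume is multiplicative: the spread of
replicate volumes grows with the volume, and log10 volumes are
symmetrically scattered with a roughly constant standard deviation. The
likelihood is therefore Gaussian in log10 residuals, unnormalised:

  ln L_measured = − SSR / (2 σ_C²),

where SSR sums squared log10 residuals over all *measured* records and
σ_C is one fixed scale for all animals and times. `estimate_sigma_c()`
computes it the way the convention defines it: the sample standard
deviation (n − 1 denominator) of log10 volumes at each design time with at
least two measurements, averaged over those times. σ_C is held fixed
during inference — it is estimated up front or supplied, never sampled.

Censored records enter through the normal tail probabilities. If the model
predicts volume C at a design time, the probability that an observation
falls below the lower limit of detection (LLD) is
Φ(log10(LLD/C)/σ_C) — the erf form of the Gaussian integral — and
symmetrically above the upper limit (ULD). Each design time t_k with U_k
unmeasurable records contributes U_k · ln[P_LLD + P_ULD]. Two deliberate
consequences:

* the likelihood does not use *which* limit a censored record violated —
  every unmeasurable point contributes the same two-sided term (the cohort
  retains the side for the generator and diagnostics only);
* U_k counts every censored slot, including the post-euthanasia times of
  an animal that dropped out earlier. In the emulated 10-mouse design this
  bookkeeping yields 130 slots = 92 measured + 38 censored, of which 12 are
  below-LLD at 5–7 dpi and 26 above.

With no censored records the censored likelihood reduces *exactly* to the
measured one. The ULD is known (1500 mm³, the euthanasia threshold); the
LLD is treated as an inferred parameter, bounded above by the smallest
measured volume in the cohort (capped at 19 mm³) — a volume that was
measured at least once is at least sometimes measurable. Its posterior
typically piles up against that bound, and `posterior_summary()` warns
when a marginal does so.

## Priors and the sampled posterior

Two reference priors are provided per parameter: linear-uniform
(density ∝ 1) and log-uniform (density ∝ 1/p), both with bounds,
defaulting to C₀ ∈ [0, ∞) mm³, μ ∈ [0, ∞) /d, κ ∈ [0, 10⁶] mm³,
α ∈ (10⁻⁵, 10⁵), LLD ∈ [0, 19] mm³. Several of these leave the posterior
un-normalisable; the sampler explores it anyway (the data confines it in
practice) and the summaries warn at bounds. The map
β = 1/(1 + 1/α) to [0, 1] is provided for users who prefer a bounded
linear-uniform exploration of the shape parameter.

All positivity-constrained parameters are sampled as log10 values. The
sampler's target density therefore includes the Jacobian Σ ln p, which
makes a log-uniform prior exactly flat in the sampled coordinate, and a
linear-uniform prior an exponentially increasing density in log10 — a
property the tests verify by prior-only sampling. The stored
`log_posterior` column, however, is the Bayes-theorem posterior on the
parameter scale (likelihood × prior, Jacobian stripped), so that
`map_estimate()` under a flat prior returns the maximum-likelihood sample.
Reported modes, intervals and MAP coordinates are all in log10 units;
linear-scale values are a presentation transform.

## The ensemble sampler

`run_ensemble()` implements the affine-invariant "stretch move": walkers
split into two half-ensembles updated alternately; a walker proposes along
the line through a partner from the other half with a scale z drawn from
the density ∝ 1/√z on [1/a, a] (a = 2), accepted with probability
min(1, z^{d−1} e^{ΔlnP}). Affine invariance is exact: a linear
reparameterisation of the target with the same seed yields the identical
acceptance sequence, which the tests assert. Non-finite proposals are
rejected, never raised. Initial positions are scattered log-normally
around a rough SSR-minimised set (`ssr_minimise()`, a Nelder-Mead pre-fit
whose only contract is not to worsen its start).

The full budgets are 300 chains × 10,000 stored steps after a 10,000-step
burn-in for posterior runs (3,000,000 stored sets) and 40 chains for
profile runs. Desk-scale analyses and the test suite use reduced budgets
(16–40 chains, a few hundred steps), which the `sampler_config()` object
makes explicit; the vectorised likelihood evaluates all walkers of a
half-ensemble in one matrix operation, so even the full Gaussian-target
budget runs in seconds. Convergence is monitored by the integrated
autocorrelation time (`autocorrelation_time()`, windowed Sokal estimator,
window constant 5), which flags chains shorter than 50 τ rather than
failing silently.

## Identifiability diagnostics

`profile_curve()` fixes one parameter on a grid and maximises the
likelihood over the rest, following the sampling procedure — keep the
single best set from a short MCMC exploration — plus a deterministic
polish (Brent in one nuisance dimension, Nelder-Mead otherwise), on by
default, because a finite random search only approximates the maximum.
Grid points warm-start their neighbours. Logarithmic grids are the natural
choice for positivity-bound parameters; endpoints are the user's.
A flat profile is the operational signature of practical
non-identifiability.

`local_sensitivity()` computes the central difference of log10 C with
respect to the log10 of each parameter, with relative perturbation
f = 10⁻⁸, about a supplied (typically best-fit) set. For the exponential
model the analytic values are 1 (for C₀) and μt (for μ), which the tests
use as oracles; for bounded models the capacity sensitivity starts at 0
and grows with time while the C₀ sensitivity is largest at the earliest
design time.

## Posterior summaries

`hpd_contiguous()` reports the narrowest *contiguous* span containing 95%
of the marginal samples — an exact sample property (sorted-window
enumeration), not a density estimate. Contiguous intervals can be
misleadingly wide when a marginal is multimodal, so a flag is raised
whenever the lightly smoothed 100-bin histogram shows two or more local
maxima above 10% of the global one (both thresholds configurable).
`marginal_mode()` uses the same fixed 100-bin histogram (first-bin
tie-break), recorded in its output. `solution_envelope()` resamples 1000
stored sets with replacement and reports pointwise central 68/95% curve
quantiles per time; pointwise bands approximate, but are not exactly,
whole-curve coverage.

## The synthetic cohort generator

`generate_cohort()` emulates the motivating study design:
10 subjects, design times {5, 6, 7, 11, 12, 13, 14, 15, 18, 19, 20, 21, 22}
days post-injection, σ_C = 0.16, ULD = 1500 mm³ with euthanasia dropout,
LLD = 19 mm³. Volumes are the model curve times 10^N(0, σ_C); censoring is
applied to the *noisy* volume, because measurability in the lab is a
property of the observed size. Under the default euthanasia rule a subject
whose noisy volume exceeds the ULD is censored above at every later design
time; the `independent` rule censors each time on its own and exists to
match the likelihood's independence assumption exactly — the right mode
for coverage calibration, where it achieves nominal coverage while
euthanasia dropout (a deliberate model violation, as in a real study)
does not. Per-subject parameter heterogeneity is available
(`per_subject_variation`, log10 sd applied to all active parameters) but
defaults to 0: the emulated study folds inter-animal variability into
σ_C.

The default truth `default_truth()` is Gompertz with C₀ = 0.1 mm³,
μ = 0.125 /d, κ = 4000 mm³, chosen once so that the noiseless curve
reproduces the study's censoring pattern: ~14 mm³ at 5 dpi (≈2/10
measurable), ~27 mm³ at 6 dpi (≈8/10), crossing 1500 mm³ between 19 and
20 dpi so subjects drop out progressively over the last days.
`study_design_cohort()` separately reconstructs the printed
measurable-count schedule (2, 8, 8, 10, 10, 10, 10, 10, 9, 7, 5, 2, 1) as a
status-only replica for bookkeeping checks.

What passing tests on these cohorts do *not* show: real calliper data has
serially correlated per-animal deviations (each mouse tracks its own
curve), possible heteroscedastic noise, and a soft, probabilistic
measurability threshold rather than a sharp LLD. The generator reproduces
none of these by default, so recovery results here are a necessary, not
sufficient, check for real data.

## The censoring bias, and a caveat about C₀

Fitting synthetic both-end-censored cohorts with and without the censored
likelihood reproduces the qualitative bias that motivates the machinery:
the exclusion fit is higher at 5–7 dpi, lower at late times, and its
carrying capacity is biased low, in every replicate. One subtlety is worth
recording. For the *generating* Gompertz family the bias on the C₀
parameter itself can invert: the exclusion fit's low κ forces a high μ,
and the extrapolation to t = 0 — five days before the first design time —
dives below the inclusion fit's, even though the exclusion *curve* is
higher at every early design time. For the capped-exponential fit, whose
intercept is anchored by the early data without that μ–κ coupling, the
parameter-level direction (C₀ biased high, κ biased low under exclusion)
holds and is what the acceptance checks assert by sign test over 30
replicates. The lesson mirrors the package's broader point: parameter
biases are statements about curves plus parameterisations, not curves
alone.

## Numerical and design choices, collected

* Richards evaluated via `log1p`/`expm1` identities (no overflow at
  α = 10±5); ExpCap as an algebraic min; Logis runs through the Richards
  path with α = 1 so their equivalence is exact.
* Likelihood arithmetic in natural logs, unnormalised; P_LLD + P_ULD
  underflowing to 0 returns −∞, never NaN.
* Sample sd uses n − 1; design times with fewer than two measured values
  are skipped when estimating σ_C.
* MAP ties break to the first (chain, step); HPD window ties to the lowest
  start; mode ties to the first bin.
* One integer seed drives every random draw (sub-seeds derived by a
  32-bit-safe linear map), so cohorts, fits and envelopes are reproducible
  bit for bit.
* Fits drop the LLD parameter when the cohort has no censored records (it
  is unidentifiable there and the likelihood is LLD-free), which makes
  "censoring on, nothing censored" identical to "censoring off" under one
  seed.
* Test-suite problem sizes: 16–40 walkers, 150–800 stored steps, 6–30
  replicate cohorts — the package's choice of desk-scale defaults; the
  full budgets remain available through `sampler_config()`.

## Known limitations

* The euthanasia dropout rule violates the independence assumption of the
  censored likelihood; parameter estimates under it carry a model
  mis-specification bias (μ low, κ high in the Gompertz experiments
  above). This mirrors the real experimental situation and is the package's
  default precisely because of that; use `dropout = "independent"` for
  statistically calibrated simulations.
* Contiguous credible intervals are reported deliberately, with a
  multimodality flag, rather than disjoint highest-density regions.
* No per-time or per-subject noise scales; one σ_C for all points.
* No treatment terms, dynamic carrying capacities, or stochastic growth;
  the five deterministic curves only.
* No AIC/BIC model selection: several default priors leave the posterior
  improper and artificially bounded, which would compromise such
  comparisons.
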