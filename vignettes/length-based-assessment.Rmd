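---
title: "Length-based stock assessment with lenstock: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Length-based stock assessment with lenstock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lenstock)
```

## The problem

Data-limited river fisheries are typically assessed from individual fish
records — group label, sex, otolith age, body length (mm), body weight (g) —
with no catch-effort series and no absolute abundance. `lenstock` implements
the classical length-based assessment chain for such data: allometry and
growth fitting, derived life-history ages, mortality decomposition,
Beverton–Holt per-recruit analysis and capture-length advice. This vignette
explains each model, its assumptions, the tunable parameters, and the design
choices made where standard practice leaves the details open.

## Growth models

**Length–weight allometry.** W = a·L^b is fitted, by default, as ordinary
least squares of log10(W) on log10(L). The log-scale fit is the standard in
this literature, is robust to the strong heteroscedasticity of raw weights,
and yields the usual t-test of the isometry hypothesis b = 3 from the slope's
standard error (significance level `isometry_alpha`, default 0.05). A direct
nonlinear fit on the raw scale (`method = "nls"`) is available; it weights
large fish more heavily and typically shifts b by a small amount. Sexes are
pooled within a group: per-group single relationships are fitted, with
`ancova_slopes()` available to test whether groups can share one.

**Von Bertalanffy growth.** L_t = L∞(1 − e^(−k(t−t₀))) is fitted to
individual length-at-age records (an age-class-means option exists via
`use_means`; individuals are the default because they use all data and match
reported sample sizes). The optimiser is Levenberg–Marquardt
(`minpack.lm::nlsLM`) from five fixed starting points — initial L∞ at 1.05×
the largest observed fish and k spanning 0.1–0.4/yr — because the L∞–k ridge
of the VBGF least-squares surface can trap single-start optimisers. The best
residual sum of squares wins; near-ties are broken by the smallest |t₀|.
Ages are integer annulus counts used as-is, with no fractional-year
correction; the systematic effect of flooring continuous ages is absorbed
almost entirely by t₀ (the mean curve over floored ages is itself a VBGF
with the same L∞ and k), which is why recovery tests check L∞ and k but not
t₀ under noise. t₀ is freely estimated, bounded above by the youngest
observed age.

A note on one deliberate choice: the sanity condition "L∞ should exceed the
largest observed fish" is reported as a flag (`linf_exceeds_lmax`), not
imposed as an optimisation constraint. Under multiplicative length noise the
largest *observed* length routinely exceeds the true asymptote, and
constraining L∞ above it would bias the fit upward precisely when the data
are noisy.

**Derived quantities.** The weight growth curve is never refitted:
W∞ = a·L∞^b exactly, with k, t₀, b carried over. The inflection-point age
t_i = ln(b)/k + t₀ (where dW/dt peaks; defined only for b > 1), the critical
age t_c = [k·t₀ − ln M + ln(bk + M)]/k (where an unfished cohort's biomass
peaks), and φ′ = log₁₀k + 2·log₁₀L∞ are closed forms. φ′ is computed with
L∞ in **millimetres**; the cm convention would shift every value by exactly
−2, so the unit is stated wherever φ′ is reported.

## Mortality

**Total mortality** uses the Beverton–Holt mean-length estimator
Z = k(L∞ − L̄)/(L̄ − L_c). Its derivation assumes an equilibrium population
(constant recruitment), VBGF growth, knife-edge capture at L_c and constant
Z above the age at first capture; under exactly those assumptions it is
exact in expectation, which the simulation tests exploit. L̄ is computed
over fish at or above L_c only, as the derivation requires.

**Length at first capture.** When not supplied, L_c defaults to the 5th
percentile of retained lengths (transparent, configurable via `prob`); a
logistic-retention estimator fitted to the ascending limb of the
length-frequency distribution is offered as an option (`method =
"logistic"`, returning the 50%-retention length). Both are rough; a
configured L_c from gear knowledge is always preferable.

**Natural mortality** uses Pauly's empirical regression. The default
variant (`base10_cm`) evaluates it in base-10 logarithms with L∞ converted
to centimetres — the standard published form, and the only reading that
yields plausible M values (≈ 0.31–0.37/yr for these growth parameters at
water temperatures near 11–13 °C). The same coefficients evaluated as
natural logarithms with L∞ in mm (`natural_log_printed`, a form that
circulates in the literature) give markedly different values and are kept
only behind an explicit flag; the variant used is always recorded in the
output. F = Z − M and E = F/Z follow; a negative F is reported with a
warning, never clamped, because it signals inconsistent inputs.

**Reliability screens.** e^(−k) < 1 (growth-equation reliability),
M/k ∈ [1, 2.5] (credible natural mortality) and the position of Z/k
relative to 3 (natural- vs fishing-dominated mortality) are reported as
flags alongside the ratios.

## Per-recruit analysis

The relative yield per recruit is
Y′/R = E·U^(M/k)·[1 − 3U/(1+m) + 3U²/(1+2m) − U³/(1+3m)], with
U = 1 − L_c/L∞ and m = k/Z. Sweeping E uses the substitution Z = M/(1−E),
the standard reading that makes Y′/R a function of E alone. The bracket's
coefficients (1, −3, 3, −1) encode cubic allometry, so the relative curves
assume b = 3; with the b of these populations within 0.07 of 3 the
approximation is conventional. B′/R = (Y′/R)/F is implemented through the
algebraically equivalent form (1/k)·U^(M/k)·Σ Ωₙ Uⁿ/(M/k/(1−E) + n), which
is finite at E = 0 and equals the analytic limit there — needed because
E-0.5 is defined relative to B′/R(0). Both closed forms are verified in the
tests against an independent age-structured numerical integration of the
survival-weighted yield integral (recruitment at t₀, mortality M below the
capture age and Z above, cubic weight growth), to 0.1% over a grid of
(E, L_c/L∞, M/k).

**Reference points.** E-max is located by a grid scan (step `E_step`,
default 0.001) followed by golden-section refinement (tolerance 1e-5); a
non-unimodal scan triggers a warning and falls back to the global grid
argmax. E-0.1 solves dY′/dE = 0.1 × dY′/dE|₀ via central differences (step
1e-5) and root bracketing — the marginal-yield reading of the "one-tenth"
criterion. E-0.5 solves B′/R(E) = ½·B′/R(0) to 1e-6. All three are
grid-resolution independent below step 0.005 (tested).

**Isopleths and the shape of the yield surface.** `isopleth_grid()`
evaluates Y′/R over (E, L_c), bounded by default at L_c/L∞ ∈ [0.1, 0.6].
For fixed E the yield is unimodal in L_c with a ridge that moves toward
larger capture lengths as E grows; it is *not* monotone in L_c all the way
to the 0.6 bound at every exploitation rate. At the exploitation rates of
the three overexploited tributaries (E ≈ 0.52–0.78) raising L_c toward
0.6·L∞ raises Y′/R substantially, whereas at E ≈ 0.31 (Duoxiong Zangbo) the
ridge sits near L_c/L∞ ≈ 0.39 and the 0.6 target costs a little yield —
the management case there rests on precaution, not on yield gain. The tests
encode the unimodal-ridge properties rather than a blanket monotonicity.

**Advice.** The recommended minimum catchable length is the mean of three
indices — the capture length at the L_c/L∞ = 0.6 yield target, the length
at t_i, and the length at t_c — rounded to whole millimetres (matching the
reporting precision of such advice). For the published Duoxiong Zangbo
parameters this reproduces 257 mm exactly; the other tributaries come out
within 1–3 mm of the published recommendations, a discrepancy attributable
to unknown intermediate rounding in the original calculation and documented
rather than forced.

## The synthetic population generator

`simulate_population()` draws from exactly the generative model the
estimators assume: equilibrium age structure (truncated exponential with
rate Z on [recruitment age, max age], inverse-CDF sampling), VBGF mean
lengths with multiplicative normal noise (CV `length_cv`, clamped at ±3σ to
preserve positivity), allometric weights with mean-one lognormal noise (CV
`weight_cv`), Bernoulli sex assignment, and knife-edge or logistic gear
selectivity applied by `simulate_catch()`. Continuous ages are floored to
integer annulus counts for the reported `age` column and retained in
`age_true` for oracle computations. A single integer seed drives one
generator stream, so identical configurations reproduce records exactly.

What it deliberately does **not** emulate: seasonal growth oscillation,
density dependence, recruitment variability, multi-gear selectivity
mixtures, ageing error, or spatial structure. Passing recovery tests on
these simulations therefore demonstrates internal consistency of the
estimator chain under its own assumptions — not robustness to the
violations real river data will contain.

Default study-like conditions used in the tests: asymptotic length 400 mm,
k = 0.16/yr, t₀ = −0.5 yr, cubic allometry with a = 2×10⁻⁵, length CV 8%,
weight CV 10%, maximum age 20–60 yr depending on the mortality rate, and
sample sizes of 3000 (growth recovery), 5×10⁴ (pipeline recovery, 10 seeds)
and 10⁶ (mean-length estimator bias, 20 replicates) — large enough for the
stated tolerances (L∞ within 3%, k within 10%, Z bias under 2%, E within
0.05) yet well inside a single-CPU test run.

## Group comparison

`ancova_slopes()` realises the ANCOVA as the standard nested-model F test:
full interaction `y ~ x*group` against common slope `y ~ x + group`, with
exact degrees of freedom. Length–weight comparisons run on the log10–log10
scale (slopes are the allometry exponents); age relationships run on the
identity scale, the simplest reading for length- or weight-at-age
comparisons. The statistic is invariant to affine rescaling of the
covariate, agrees with a longhand residual-sum-of-squares computation to
1e-10, holds its nominal type-I error (checked over 1000 null replicates),
and has high power for exponent differences of ±0.1 at n = 500 per group.

## Interfaces and reporting

`run_full_assessment()` orchestrates the chain per group and supports a
parameters-injected mode so published parameter tables can be pushed through
the downstream analysis without raw records; any stage failure aborts with
the stage and group name. When no capture length is configured or derivable
from data, the per-recruit curves use L∞/4 — representative of the small
capture sizes of unregulated gillnet fisheries — and this default is
reported alongside the curves. Machine outputs (CSV/JSON via
`write_assessment()`) carry full precision; printed tables round to the
conventional 2 decimals for ages and φ′, 3 for rates, whole mm for lengths.
The manifest records the package version, seed and an MD5 hash of the
configuration, so every table regenerates identically from config + seed.
The package's interface is its functions; there is no shell entry point
beyond the small acceptance script, because the intended users work in R.

## Known limitations

- Pauly's M is an empirical cross-species regression; its error is easily
  ±30% for any single stock, and everything downstream of M (F, E, t_c,
  E-max) inherits that uncertainty. No uncertainty intervals are produced.
- The mean-length Z estimator is sensitive to L_c misspecification and to
  the equilibrium assumption; trends in recruitment bias it.
- The relative per-recruit model is knife-edge and equilibrium; it yields
  relative, not absolute, quantities.
- Only the VBGF is implemented; alternative growth models (Gompertz,
  logistic) are out of scope.
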