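---
title: "Methods: rate-domain analysis of choice reaction times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rate-domain analysis of choice reaction times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratedomain)
```

## The model

`ratedomain` treats *rate* — the reciprocal of reaction time, in s⁻¹ — as
the fundamental behavioural variable of a two-alternative choice task. The
working hypothesis is that rate on each trial is a draw from a Normal
distribution, left-truncated at the smallest observable rate
`a` (the reciprocal of the trial time-out, `1/60 ≈ 0.0167` s⁻¹ for a 60 s
time-out):

$$f(x;\mu,\sigma,a) \;=\; \frac{\varphi\!\left[(x-\mu)/\sigma\right]}
  {\sigma\,\bigl(1-\Phi\!\left[(a-\mu)/\sigma\right]\bigr)},\qquad x \ge a .$$

In the time domain this is the reciprocal truncated Normal (`rectrN`),
easily distinguished from the inverse Gaussian that a drift-diffusion
(stochastic rise-to-threshold) account predicts: `recIG` rates stay
positively skewed, `trN` rates do not. The package provides closed-form
densities, seeded samplers, the generic reciprocal change of variables
`g(x) = f(1/x)/x²`, and the two-boundary first-passage sine series of the
pure diffusion model for comparison.

Three further layers sit on top of the marginal model:

1. **Sequential dependency.** Rates are serially dependent. A stationary
   autoregressive model $r_n = \sum_{j=1}^m a_j r_{n-j} + u_n$ with iid
   Normal input $u_n$ captures it; the equivalent moving-average form
   $r_n = \sum_i b_i u_{n-i}$ (via z-transform partial fractions) exposes
   the steady-state gains — mean gain $\sum_i b_i = 1/(1-\sum_j a_j)$, SD
   gain $\sqrt{\sum_i b_i^2}$ — the start-of-block step response, and the
   stationary density as the convolution of scaled copies of the input
   density.
2. **Laterality history.** The previous four side transitions, coded
   binary repeat/alternate (earliest most significant), modulate rate in
   easy conditions.
3. **Optimal timing.** Expected gain for a response at time $t$ is
   $\hat G(t) = (U^+ + U^-)\,p(t) - U^-$ with concave accuracy $p(t)$;
   maximising the expected *rate* of gain $\hat G(t)/(t+T_{ND})$ gives
   $(t^*+T_{ND})\,\hat G'(t^*) = \hat G(t^*)$. Accuracy is parameterised by
   a time-acceleration scale $\hat\varepsilon$ with
   $p_{\hat\varepsilon}(t) = p(\hat\varepsilon t)$, default
   $p(t) = \tfrac12 + \tfrac12(1 - e^{-\hat\varepsilon t})$ for two
   alternatives.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| truncation bound `a` | 1/60 ≈ 0.0167 | s⁻¹ | reciprocal of the 60 s time-out; fixed, not fitted |
| anticipation bound | 0.15 | s | RTs strictly below are guesses (rate > 6.67 s⁻¹); excluded |
| dither | U(−0.5, 0.5) | ms | undoes millisecond quantisation before the reciprocal |
| CV threshold | 0.4 | — | blocks with ML CV ≥ 0.4 are "truncated" (bound within 2.5 SD of the mean); boundary assigned to the truncated side |
| AR order | 6 (fit), 3 (reference) | lags | order-6 fits show only the first three weights significant |
| AR weights | {0.222, 0.104, 0.076} | — | reference estimates; mean gain 1.67, SD gain 1.05 |
| PACF lags / skip | 20 / 10 | trials | transient dies out in under 10 trials; skipped before steady-state analysis |
| `U⁺, U⁻` | 1, 5 | utility | worked payoff case; `t_min = ln 3`, `t* ≈ 2.289` at `ε̂ = 1`, `T_ND = 0` |
| ε̂ grid (power law) | 50 log-spaced on [0.01, 1] | scale | grid for the `t*(ε̂)` regression; reported with every fit |

## What the synthetic generator emulates — and what it does not

`generate_experiment()` reproduces the *statistical design* the analysis
assumes: 24 subjects × 4 blocks × 200 trials; each subject receives the
four condition blocks (AE, AD, UE, UD) in one of the 24 possible orders;
rates follow the AR(3) process started from zero history (so the first ~10
trials show the transient); latent rates below `a` are *censored* to the
bound and recorded as 60 s time-outs (censoring, not rejection — that is
what an experiment observes); reaction times are quantised to the nearest
millisecond; sides are Bernoulli(1/2); error flags are Bernoulli with rates
0.01 (easy) and 0.24 (difficult); and easy-condition rates receive small
additive offsets keyed by the repeat/alternate code (+0.08 s⁻¹ for pure
repetition/alternation, −0.08 s⁻¹ for run-breaking histories RRRA, AAAR,
ARRA), applied at the observation level rather than fed back into the AR
recursion.

Input means (`mu_u`; 1.85/2.00 easy, 0.40/0.50 difficult, SD 0.30
throughout) were chosen once so that stationary rates land where a typical
subject's do — easy blocks near 3 s⁻¹ (RTs ≈ 300 ms, CV ≈ 0.1, cleanly
untruncated) and difficult blocks near 0.7–0.85 s⁻¹ (RTs of a second or
more, CV straddling 0.4, occasional time-outs) — giving both truncation
classes in every run.

The generator does **not** model luminance psychophysics, foreperiod
effects, fatigue or inter-block rests, error-specific RT processes (error
trials share the rate process; only the correct flag differs), or
between-block parameter drift. Passing tests therefore demonstrate that
the pipeline recovers the structure it assumes, at realistic scale and
noise — not that real data contain no further structure.

## Numerical choices

- **Truncated-Normal MLE**: Nelder–Mead simplex over `(μ, log σ)` (so
  σ > 0 is structural and μ may go negative, which deep truncation can
  legitimately produce), initialised at sample moments, relative tolerance
  1e−8, at most 10⁴ evaluations; survival normaliser computed with
  `pnorm(..., log.p = TRUE)` for stability. Non-convergence is flagged,
  not raised.
- **AR fitting**: conditional Gaussian ML — per-block de-meaned lagged
  regressions stacked across blocks (no lag pair crosses a block
  boundary), solved by least squares; at ~190 usable trials per block the
  difference from exact likelihood is negligible and the estimator is
  transparent. Timed-out trials are dropped; the first 10 trials are
  skipped. Stability of the estimate is checked against the unit circle.
- **AR→MA conversion**: characteristic roots by `polyroot`; residues by
  partial fractions for distinct roots, with conjugate pairs combined and
  residual imaginary parts asserted < 1e−10; (near-)repeated roots fall
  back to the exact recursion `b_i = Σ_j a_j b_{i−j}`. Truncation at the
  first `|b_i| < 1e−10`, cap 10⁴.
- **First-passage series**: summed in increasing `k`, stopping after two
  consecutive terms fall below `tol` × the partial sum (the sine factor
  oscillates, so one small term is not evidence of convergence); densities
  below `t = 1e−6` are returned as 0, where the series converges too
  slowly to be worth the cost.
- **Steady-state convolution**: uniform grid (4096 points per copy),
  FFT-accelerated discrete convolution with trapezoidal end-point
  correction — chosen so that the convolution of densities supported on
  `[0, ∞)` is *exactly* zero at the origin, matching the analytic argument
  that any two-term convolution kills a density step at zero. Copies whose
  scaled support is narrower than ~32 grid steps contribute variance below
  resolution and are applied as exact mean shifts `b_i E[u]`. An output
  mass deviating from 1 by more than 1e−3 raises a resolution error rather
  than silently renormalising a bad grid.
- **Probit diagnostics**: plotting positions `(i − 3/8)/(n + 1/4)` (the
  conventional choice for Normal QQ work); the line is fitted on the
  5–95% band only, where the Normal approximation is claimed. For the
  truncated pool, which retains only positive z-scores, theoretical
  quantiles come from the upper half-Normal, `Φ⁻¹((1+p)/2)` — against
  full-Normal quantiles a correct half-Normal sample would bend by
  construction. The pipeline labels a pool "linear" when the band R²
  reaches 0.999, the figure that separates Normal pools from
  inverse-Gaussian clones (whose band R² sits near 0.997 at study scale).
- **Optimal timing**: `t*` by bracketed root-finding on
  `(t + T_ND) G′(t) − G(t)` starting just above `t_min`, with the upper
  bracket grown geometrically; the solution is verified as a maximum of
  `G(t)/(t + T_ND)` at ±1%. Derivatives are analytic for the exponential
  accuracy form and central differences (`h = 1e−6·t`) otherwise. With
  `T_ND = 0` the optimality condition depends on `t` only through `ε̂t`,
  so `t* = t₁/ε̂` exactly — used as a shortcut in
  `predict_rate_distribution()` and cross-checked against the per-draw
  solver in tests.

## Design choices where the design was open

- **Censoring, not rejection**, for rates below the time-out bound: the
  generator records what an experiment records (a 60 s trial), and the
  preprocessing carries the flag so each analysis can choose (moments and
  fits keep censored trials at the bound; AR fitting drops them).
- **Exclusion order**: anticipatory masking is applied *after* dithering
  (a dither can move a 150 ms reaction time across the bound) with a
  strict `< 0.15 s` rule; sample moments are computed after exclusion.
- **Zero pre-history in `decorrelate()`** by default, matching the
  generator's start-from-rest convention so input recovery is exact from
  trial 1; a `"drop"` option marks the first `m` values `NA` for data
  whose pre-block history is unknown.
- **The repeat/alternate code is strictly 4-bit binary** (0–15). Pure
  alternation AAAA codes to 15; a sequence cannot code to 16 under binary
  weighting, and the hyperbolic-weighted variant is out of scope.
- **Power-law grids**: the exponent `k` of `t* ≈ a ε̂^{−k}` is
  grid-dependent whenever `T_ND > 0`; the default grid is 50 log-spaced
  points on `[0.01, 1]` and is reported with every fit. On this grid
  `k ∈ (0, 1)` for `T_ND ∈ {10, 100, 1000}` but is not monotone in
  `T_ND` — only `k = 1` at `T_ND = 0` is grid-free, and that is the only
  exponent value the package asserts.
- **Pooled AR fitting** across blocks is the default (blocks are
  independent recordings of what the analysis treats as one process);
  per-block fitting is available by passing single blocks.

## Problem sizes used in the test suite

Statistical checks run at the scales that make their tolerances meaningful
while keeping the suite quick: study-scale tables (19,200 trials) for the
probit/clone contrasts; 96 blocks × 200 trials for AR weight recovery
(±0.03); 100 replicates of n = 10⁴ for MLE bias (±0.02); 10⁵ stationary
realisations (60-trial burn-in) for the convolution χ² check; 2 × 10⁴
random walks at Δt = 5 × 10⁻⁴ for the first-passage oracle.

## Known limitations

- The truncated-Normal MLE treats censored (timed-out) observations as
  exact values at the bound rather than contributing censored-likelihood
  mass; with the few per-mille of time-outs the defaults produce, the
  effect is well below sampling noise, but heavily censored designs would
  need a censored likelihood.
- The AR model is fitted to the steady-state portion only; the transient
  is *predicted* (step response) rather than jointly estimated.
- `fit_ar_ml()` assumes a common AR process across pooled blocks, which
  the generator satisfies by construction; heterogeneous real blocks would
  average their dynamics.
- The drift-diffusion module provides densities and conservation checks,
  not likelihood fitting; the extended model with across-trial parameter
  variability is out of scope.
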