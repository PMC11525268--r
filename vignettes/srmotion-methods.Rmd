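---
title: "Modelling stochastic resonance in motion detection across the lifespan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stochastic resonance in motion detection across the lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srmotion)
```

## The scientific problem

Stochastic resonance (SR) is the counter-intuitive phenomenon in which a
moderate amount of noise *improves* the detection of a weak signal in a
nonlinear (thresholded) system. In visual psychophysics it shows up as an
inverted-U curve: plot accuracy against external noise and performance
rises to a maximum at an intermediate noise level before collapsing.

`srmotion` simulates and analyses a two-block motion-detection experiment
built around this phenomenon. Participants view two successive random-dot
kinematograms (RDKs) and report which interval contained coherent
rightward motion (two-interval forced choice, 2IFC). Block 1 estimates
each participant's coherence threshold with a one-up two-down staircase at
a fixed dot numerosity (100 or 400 dots). Block 2 fixes coherence at that
threshold and sweeps the *total number of dots* — the external noise —
across 14 quasi-logarithmic levels from 20 to 2000 (20 trials each, 280
trials). Because ageing is associated with increased internal neural
noise, the package's synthetic cohorts tie internal noise to age, and the
analysis asks how the SR curve changes across the lifespan: does it
flatten, and does its peak move toward lower external noise?

## The observer model

Each stimulus interval is reduced to a scalar evidence draw. For a
stimulus with coherence $c$ and $N$ dots the target interval yields
$X_t \sim \mathcal N(\mu, \sigma^2)$ and the non-target interval
$X_n \sim \mathcal N(0, \sigma^2)$, with

$$\mu = a\,c\,\frac{N}{N + N_s}, \qquad
  \sigma = \sqrt{\sigma_{\text{int}}^2 + b^2 N}.$$

Evidence passes through a hard threshold $T(x) = x\,[x > \theta]$ and the
observer chooses the interval with the larger rectified evidence, guessing
on exact ties; a lapse rate mixes in a fraction of random responses. This
is the minimal classical threshold-SR observer: a sub-threshold signal
($\mu < \theta$) is invisible without noise, an intermediate $\sigma$
lifts signal-plus-noise over the threshold more often in the target
interval than noise alone does in the non-target interval, and excessive
$\sigma$ erases the asymmetry. `p_correct_2ifc()` evaluates the choice
probability exactly — two closed-form terms plus one adaptive quadrature
term (absolute tolerance $10^{-6}$) — and `simulate_trials()` is its
stochastic counterpart.

Parameter defaults (`observer_params()`):

* `theta = 1` fixes the evidence scale; all other parameters are read
  relative to it.
* `gain_a = 5.8` puts the analytic 70.7% coherence thresholds of young
  observers near 16% coherence at 100 dots, in the empirically plausible
  range for this task.
* `n_sat = 0.01` dots: pooling saturates far below the tested numerosity
  range, so the pooled signal is effectively density-independent and the
  density effect is carried entirely by the noise channel. This is the
  regime in which the classical SR machinery, rather than signal pooling,
  shapes the accuracy-vs-numerosity curve.
* `ext_b = 0.04` evidence units per $\sqrt{\text{dot}}$: external noise
  grows as $\sqrt N$, the natural scaling if each dot contributes an
  independent correspondence error. With this value the youngest
  observers' accuracy peaks at roughly 100–150 dots and declines clearly
  by 2000 dots.
* `lapse = 0.02`, a standard psychophysical guard against degenerate fits
  at extreme levels.

Two consequences of this observer are worth stating because they shape
everything downstream. First, at the 70.7% calibration point the signal
needed is always close to the threshold ($\mu \geq 0.92\,\theta$
whatever $\sigma$), so the inverted U measured *at a participant's own
threshold* is intrinsically shallow (a few percentage points). Second,
once $\sigma_{\text{int}}$ exceeds roughly $0.8\,\theta$ the calibrated
signal is supra-threshold and added noise can only hurt: the curve
becomes flat-then-falling with its maximum at the lowest numerosity.
The transition between these regimes is the model's expression of the
age-related leftward peak shift.

## The synthetic cohort

`cohort_config()` draws ages from a normal distribution truncated to
[18, 82] (mean 43.52, SD 19.61) and maps age to internal noise. The
default map is exponential,
$\sigma_{\text{int}}(\text{age}) = 0.12\,e^{0.0462(\text{age}-18)}$,
rising from 0.12 at 18 to about 2.3 at 82, with lognormal
between-participant jitter (SD 0.05 on the log scale; pooling gain
receives one third of that). We chose the exponential form over a linear
one after observing that a linear map compresses the sub-threshold
(interior-peak) regime into the first few years of the age range, leaving
almost no age-by-numerosity structure for the analysis stage to recover;
the exponential map spreads the sub-to-supra transition across the
lifespan. A linear map remains available (`noise_map = "linear"`).

With these defaults the jitter-free ground truth reproduces the target
phenomena: analytic 70.7% thresholds rise from 16% to 37% coherence
(positive age effect at both 100 and 400 dots, with a ~0.02
percentage-point SR dip at the youngest ages that no linear model would
resolve), the youngest observers show a strictly interior accuracy peak,
and `sr_peak()` is non-increasing in age, reaching the lowest numerosity
by midlife.

`generate_dataset()` runs the full pipeline per participant — group
assignment (118:214 probability of the 100-dot staircase group), block 1,
block 2 at the estimated threshold, and the three exclusion rules
(threshold above 75%, fewer than 6 reversals in the last 40 staircase
trials, block-2 accuracy above 90%; boundaries kept, first failing rule
reported). Exclusions are emergent, not forced; a `target_kept` mode
resamples until a requested analysable sample size is reached.

What the generator does *not* emulate: practice effects, response times,
hardware variability of online testing, the recruited cohort's possibly
bimodal age density, and the empirical 400-dot threshold advantage in
younger adults (a pooling phenomenon that the saturated-pooling observer
deliberately excludes). Passing tests therefore demonstrate that the
analysis machinery recovers this generative model's structure, not that
the generative model is a complete account of the human data.

## The staircase

`staircase_step()` implements the one-up two-down rule: coherence starts
at 70%, steps are 10, 5, 3, 2, 1 percentage points (the step advances at
each reversal and the reversal-triggering move already uses the new
size), the run stops at 12 reversals, and the threshold is the mean of
the last 8 reversal values, recorded at the pre-move level. The rule
converges to the 70.7% point ($p^2 = 1/2$). Two bookkeeping decisions the
procedure leaves open are fixed and documented: a first move from the
start records no reversal (there is no prior direction), and coherence is
clamped to [1, 100]%.

The staircase estimate carries meaningful noise: across runs its SD is
1–2 percentage points, which is comparable to the sub-threshold margin
$\theta - \mu$ of young observers. This matters for inference — it is the
main reason the fitted age-by-numerosity interaction on full-pipeline
cohorts is much weaker than the jitter-free ground truth suggests — and
it motivates the design of the recovery experiments below.

## The analysis stage

`fit_threshold_lm()` fits ln(threshold) on scaled age, a sum-to-zero
group contrast and their interaction, with sequential F tests, partial
$\eta^2 = SS_{\text{term}}/(SS_{\text{term}} + SS_{\text{res}})$, and
back-transformed group marginal means at the mean age. It is fit at
participant level, one threshold per participant.

`fit_logistic_glmm()` implements the binomial random-intercept GLMM
directly: trial-level Bernoulli responses (aggregated to binomial counts
per participant and level, which is exact under conditional
independence), a logit link, orthogonal polynomials of log dot numerosity
up to degree 4 (`orthogonal_poly()`, a three-term recurrence whose
coefficients are stored so new values map into the identical basis),
scaled age or a sum-to-zero younger/older contrast (cut at 50, boundary
to "older"), and polynomial-by-age interactions. The marginal likelihood
integrates each participant's random intercept by adaptive Gauss–Hermite
quadrature (15 nodes by default; 1 node gives the Laplace approximation;
nodes are computed by the Golub–Welsch eigendecomposition). The
optimiser is `nlminb` with an analytic score obtained from Fisher's
identity — the posterior-expected complete-data score on the same
quadrature grid — which is exact up to quadrature error and is therefore
only used from 7 nodes up. The variance parameter is profiled on the
log-SD scale with a soft floor, so boundary estimates of zero are
admissible; the coefficient covariance is the inverse observed
information from a central-difference Hessian. Reported log-likelihoods
are Bernoulli-trial log-likelihoods and `n_obs` counts Bernoulli trials,
so `aicc()` operates on the trial scale; the parameter count `K` is the
number of fixed effects plus one variance component (5, 7, 9, 11 for
degrees 1–4).

Model selection (`compare_sr_models()`) ranks the four polynomial
degrees by AICc with Akaike weights. `wald_type3()` tests each term
block by the quadratic form $b^\top V_b^{-1} b$; sum-to-zero coding makes
these Type III tests invariant to factor-level ordering.
`marginal_r2()` is the Nakagawa ratio
$\mathrm{var}(X\hat\beta) / (\mathrm{var}(X\hat\beta) + \hat\sigma_u^2 +
\pi^2/3)$, and `part_r2()` reports the drop in marginal $R^2$ when a term
is removed (main effects are assessed in the interaction-free model, the
interaction against the full model). `peak_location()` takes the argmax
of the population-level predicted curve on a 2001-point log-spaced grid
over [20, 2000] — a dense grid rather than derivative roots, because the
logit link makes the response-scale curve non-polynomial — with ties
resolved toward the smaller level, and is reported as not applicable for
degrees below 2. `simulated_residual_ks()` is a simulation-based
uniformity check: randomized quantile residuals of the observed counts
within their simulated distributions, tested against Uniform(0, 1).

## Recovery experiments and problem sizes

The package ships two reference generators used by the test suite and
the acceptance script.

`simulate_quartic_cohort()` draws a lifespan cohort and simulates
binomial responses from a *known* quartic logit surface: a deep
inverted-U anchor curve for the young, a flat-then-falling curve for the
old, blended linearly in age and projected onto the exact
orthogonal-polynomial design of the realised cohort. Because the truth is
quartic by construction and of the curvature magnitude the constant
stimuli experiment is designed to detect, it supports coefficient-level
recovery checks (at 200 participants x 280 trials, pooled 2-standard-
error coverage across 20 replicates is about 94%) and model-selection
checks (AICc prefers degree 3 or 4 in essentially every replicate at
n = 214).

`simulate_band_cohort()` generates three age bands (18–29, 38–46, 56–64
by default, 100 participants each) whose responses are drawn from the
observer model at each participant's *analytic* coherence threshold, so
the generative accuracy peak is known exactly per participant. Fitted
peaks at the band-centre ages then order left-shifting with age in
essentially every replicate. We use analytic rather than
staircase-estimated coherence here deliberately: this experiment is a
ground-truth recovery check, and staircase noise — which is tested by its
own convergence experiment (1000 runs; the mean threshold maps back to
within 0.03 of the 70.7% point) — would otherwise randomise the ground
truth itself. On full-pipeline default cohorts at the recruited sample
size, the fitted interaction and peak ordering are directionally
consistent but seed-sensitive; this mirrors the shallow calibrated-U
property of the observer discussed above and is documented rather than
hidden.

These problem sizes (20 replicates; 200–300 participants; 1000 staircase
runs; $10^6$-draw Monte-Carlo checks of the quadrature on a 20-point
lattice) were chosen so the whole suite completes comfortably on a single
CPU while leaving each check statistically meaningful.

## Numerical choices and degenerate inputs

* Quadrature tolerances: $10^{-6}$ absolute for the 2IFC probability;
  $10^{-4}$ coherence tolerance for threshold bisection, with an
  explicit `NA` ("unattainable") when even full coherence cannot reach
  the target.
* The staircase raises a diagnostic error if it fails to complete within
  10,000 trials.
* `orthogonal_poly()` refuses fewer distinct values than the requested
  degree; `zscale()` refuses constant input.
* GLMM convergence is declared from the score norm rather than the
  optimiser's return code alone, since quasi-Newton methods routinely
  report "false convergence" at the flat optima of large-n likelihoods;
  non-converged fits are flagged, never silently returned.
* Exact ties in the rectified-max rule (both intervals below threshold)
  are resolved by an unbiased guess; ties in peak grids go to the smaller
  level; the corner case of a dot leaving the aperture diagonally wraps
  on the axis with the larger overshoot.
* Seeds: every stochastic stage takes an explicit seed, and
  `derive_seed()` expands one master seed into independent named
  streams, so adding participants to one block never perturbs another.

## Known limitations

The observer is deliberately minimal: no motion-energy filterbank, no
spatial pooling structure, no response-time model, and a single noise
source per age (gain decline is available as a knob but off by default).
The inverted U it produces at each participant's own 70.7% calibration is
shallower than the published human curves, which limits the attainable
power of interaction tests on fully pipeline-simulated cohorts of
realistic size. The printed quartic prediction equations of the original
analysis are response-scale approximations valid near the covariate
origin; the package keeps link-scale coefficients and response-scale
evaluations (`evaluate_quartic()`) strictly separate.
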