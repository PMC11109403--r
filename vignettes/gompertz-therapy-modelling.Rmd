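---
title: "Macroscopic modelling of tumor growth under radio- and immunotherapy"
author: "gomptx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macroscopic modelling of tumor growth under radio- and immunotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gomptx)
```

## The model

Untreated tumors over the macroscopic size range follow sigmoid growth
laws remarkably well, and among these the Gompertz law has repeatedly
been found to describe preclinical growth curves best. `gomptx` writes
it through the *specific growth rate* — the per-size growth rate
$(1/N)\,dN/dt$:

$$\frac{1}{N}\frac{dN}{dt} = a - k \ln\frac{N}{N_0} = k\ln\frac{N_\infty}{N},$$

with $a$ (day$^{-1}$) the initial exponential rate, $k$ (day$^{-1}$) the
limiting-factor rate and $N_\infty = N_0 e^{a/k}$ the carrying capacity.
In log size $u = \ln N$ the dynamics are *linear*,
$du/dt = a - k(u - u_0)$, which is the organising fact behind the whole
package: all integration happens in $u$ (positivity is automatic and
instantaneous therapy effects become subtractions), and every therapy
term below has a closed form because the homogeneous dynamics propagate
any log-space impulse as $e^{-k(t - t_i)}$.

Three therapy mechanisms sit on top:

* **Immunotherapy** adds $-\gamma I(t)$ to the specific rate. The sign
  of $\gamma$ carries the biology — agonist antibodies ($\gamma < 0$)
  accelerate growth, antagonist ones ($\gamma > 0$) suppress it. For a
  constant drug level the whole effect is a shifted carrying capacity
  $N_\infty e^{-\gamma I_0/k}$; for an exponentially cleared drug
  ($I(t) = I_0 e^{-\rho t}$) the closed form is
  $W(t) = \gamma I_0\,(e^{-\rho t} - e^{-kt})/(k-\rho)$.
* **Radiotherapy** kills instantaneously at each fraction with the
  linear-quadratic surviving fraction $e^{-\alpha d - \beta d^2}$. A
  full fractionated course then has the closed form
  $$\ln N(t) - \ln N(t_0) = \ln\frac{N_\infty}{N(t_0)}\left[1 -
  e^{-k(t-t_0)}\right] - \bar W(t, t_0) - D_{n_f},$$
  where $D_{n_f} = \sum_i (\alpha d_i + \beta d_i^2)\, e^{-k(t - t_i)}$
  is the discounted sum of per-fraction log-kills and $\bar W$ the
  discounted immunotherapy integral. The discounting is not an extra
  assumption: it is forced by the linear log-space dynamics, and the
  package verifies the closed form against a recursive
  grow-then-kill simulation to $10^{-8}$ in $\ln N$. The course
  *regresses* the tumor exactly when the right-hand side is negative
  (`regression_condition()`); near the critical point where the growth
  term balances $D_{n_f}$, an arbitrarily small immunotherapy
  contribution decides the outcome.
* **Synergy (abscopal effect)**: radiotherapy of the primary tumor
  triggers a systemic immune response that attacks an *unirradiated*
  metastasis. Each fraction launches a pulse of amplitude $Y_0$ on the
  metastatic specific rate, switched on `lag` days after the fraction
  and decaying with time constant $\tau$, scaled by a coupling
  $\delta$. After the last pulse onset, if the specific rate has turned
  negative the immune attack is assumed to continue as a frozen
  exponential decline at the end-of-course rate; otherwise the
  perturbed dynamics simply run on until the pulses fade.

## Numerical and interface choices

Decisions that were genuinely open, and how they were settled:

* **Onset delay vs decay time.** The immune response after a fraction
  has both a delay before it acts on the secondary and a typical decay
  once active. These are conceptually distinct, so the synergy type
  carries both `lag` and `tau`, with `lag = tau` as the default when a
  single time scale is all one wants to assume.
* **Pulse shape.** The coupling between dose and immune kill is not
  observable macroscopically; the package uses a per-fraction
  triggered exponential pulse $Y_0 e^{-(t - t_i - \mathrm{lag})/\tau}$,
  the minimal form with the right time scale. `Y0` may be a function
  of the fraction dose for users who want saturation above
  immunogenic doses; the default is dose-independent.
* **Branch thresholds.** The $k \to 0$ (pure exponential) branch
  switches at $|k| < 10^{-9}\,$day$^{-1}$, and the $k = \rho$
  immunotherapy limit at $|k - \rho| < 10^{-9}$, both far below any
  biologically resolvable rate.
* **Event convention.** Trajectory values *at* a fraction time are
  post-kill (right-continuous). Consistently, an observation made on a
  treatment day belongs to the following phase in phase-wise fitting.
* **Frozen post-course rate.** The end-of-course specific rate used for
  the exponential continuation is evaluated one small step
  ($10^{-3}$ day) after the last pulse onset, so the rate already
  includes the fully switched-on immune term.

## The phenomenological fitting layer

The analysis layer deliberately does *not* try to identify
$\gamma, \alpha, \beta, \delta$ from data. Following the macroscopic
philosophy, therapy effects are absorbed into *effective* Gompertz
parameters $(a_{\rm eff}, k_{\rm eff})$ refit per treatment phase:

* `fit_gompertz()` — Levenberg–Marquardt least squares of the closed
  form, on log sizes by default (multiplicative measurement error;
  raw-scale residuals are an option). A deterministic multi-start grid
  over $a$ and $\pm k$ makes the fit robust to either sign of the
  effective parameters. Parameter uncertainties are the
  $\chi^2/\mathrm{dof}$-scaled covariance; goodness is reported as the
  Pearson correlation of observed vs fitted sizes plus the RMS
  relative error.
* $N(t_0)$ is **co-estimated** by default. Anchoring the curve to the
  first *observed* (noisy) size looks natural but measurably biases
  both rates (a ~2% median bias in $\hat a$ and ~5% in $\hat k$ at 5%
  noise with 20 points); co-estimation removes the bias at the cost of
  one more parameter. The fixed anchor remains available
  (`fix_N0 = TRUE`) and is exactly what `fit_phasewise()` uses to keep
  consecutive phases continuous: each later phase starts at the break
  day, at the previous phase's fitted value there.
* The final phase of a course that drives the tumor toward extinction
  is better described by a *linearly time-dependent* rate,
  $a_{\rm eff}(t - t_0) - k_{\rm eff}\ln(N/N(t_0))$ with
  $a_{\rm eff}$ in day$^{-2}$ (`a_linear_time`). Negative
  $(a_{\rm eff}, k_{\rm eff})$ in this form have no finite carrying
  capacity; the fit reports an extinction regime rather than
  $N_\infty^{\rm eff}$.
* `estimate_specific_rate()` gives the model-free view: day-by-day
  finite differences of $\ln N$ (central in the interior, one-sided at
  the ends). A sustained negative trend is the clearest signature of
  therapy response, and is more sensitive than the raw volume curve.

## What the synthetic-data module emulates — and what it does not

`generate_trajectory()`/`generate_study()` produce multi-arm designs
with the structure the fitting layer assumes: exact model dynamics from
the modules above, plus measurement noise. Two packaged designs mirror
the study layouts the method targets: an antibody study
(`design_antibody_like()`: untreated + two agonist + two antagonist
arms, a = 0.049, k = 0.011 day$^{-1}$, observations every 2 days over
days 0–40) and a fractionated-RT/abscopal study
(`design_rt_abscopal_like()`: untreated, 1×8 Gy, 3×8 Gy on days 9–11
with $\alpha = 0.3$ Gy$^{-1}$, $\beta = \alpha/10$, and an unirradiated
metastasis arm, a = 0.054, k = 0.0164 day$^{-1}$, daily observations
over days 0–25).

The default noise is multiplicative lognormal with 5% relative sd — a
realistic scale for caliper or imaging measurements of individual
animals, and the level at which the parameter-recovery experiments are
run (100 replicates per arm; mean $\hat a$ recovers the generating
value within a few percent). What the generator does *not* emulate:
between-animal parameter heterogeneity (every subject in an arm shares
one parameter set), irregular observation schedules, censoring by
humane endpoints, and any microscopic immune dynamics. Passing tests on
these synthetics therefore demonstrate the estimators' correctness and
calibration under the stated error model, not robustness to everything
real data can do.

For the sign-structure experiment (growth → slowed growth → extinction
across phase-wise fits) the replicates use daily sampling over days
0–25 with breaks at days 9 and 15, phases
$(a, k) = (0.135, 0.131) \to (0.04, 0.3) \to$ linear-time
$(-5.06\times10^{-4}, -0.464)$, and 1% noise. Two of these choices
deserve a note. The middle phase's $k$ was chosen so its saturation is
actually expressed inside the 6-day window ($kT \approx 1.8$): with a
weakly curved phase (say $k \approx 0.1$ over 6 daily points) the sign
of $k_{\rm eff}$ is statistically unidentifiable at any plausible
noise — the $\chi^2$-based uncertainty equals the information bound
and $k/\sigma_k \lesssim 1$ — so a sign-recovery experiment there
would measure coin flips, not estimator correctness. And 1% noise is
the group-mean/digitized-curve scatter scale appropriate to phase-wise
fits of averaged series, consistent with (indeed conservative against)
the parameter uncertainties such fits report.

## Problem sizes

The test suite and the recovery experiments use: 200 random parameter
draws for closed-form/integrator equivalence, 100 random schedules for
the fractionated-course identity, 500 random courses for the
regression-condition sign check, 100 replicates per parameter-recovery
experiment, and 100 replicates for the sign-structure experiment —
enough for stable means and proportions at the tolerances quoted, while
keeping a full run in tens of seconds.

## Known limitations

* The instantaneous-kill assumption of the linear-quadratic step is a
  simplification; delayed radiation damage is real (the fibrosarcoma
  curves regress only days after the last fraction) and is represented
  here only phenomenologically, through the time-dependent effective
  parameters and the synergy lag.
* Effective parameters absorb *everything* — they are descriptive, not
  mechanistic, and extrapolating a fitted phase beyond its data is only
  as good as the phase assumption.
* No logistic-law counterpart is provided; the perturbation hook in
  `integrate_growth()` accepts any additive specific-rate term, which
  is the intended extension point.
* Spatially heterogeneous dose distributions, lymphocyte depletion
  under protracted schedules, and immune-escape dynamics are out of
  scope.
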