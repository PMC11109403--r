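# gomptx

Macroscopic modelling of tumor progression under radiotherapy (RT) and
immunotherapy (IT), for preclinical and translational researchers who
analyse longitudinal tumor-size data and want quantitative, low-parameter
descriptions of therapy response — including the abscopal effect, where RT
on a primary tumor drives regression of an unirradiated metastasis through
the immune system.

## The model

Untreated growth follows the Gompertz law, written through the specific
growth rate (the per-size growth rate):

    (1/N) dN/dt = a − k ln(N/N₀) = k ln(N∞/N),      N∞ = N₀ e^{a/k}

Therapy enters three ways:

* **Immunotherapy**: an additive term −γI(t) on the specific rate
  (γ < 0 agonist, γ > 0 antagonist); constant or exponentially decaying
  drug profiles have closed-form solutions (a constant profile just shifts
  the carrying capacity to N∞·e^{−γI₀/k}).
* **Radiotherapy**: instantaneous linear-quadratic kills, surviving
  fraction e^{−αd−βd²} per fraction. A fractionated course has the closed
  form ln N(t) − ln N(t₀) = ln(N∞/N(t₀))[1 − e^{−k(t−t₀)}] − W̄ − D_nf,
  with D_nf the sum of per-fraction log-kills discounted by e^{−k(t−tᵢ)};
  the course regresses the tumor exactly when this expression is negative.
* **Synergy / abscopal effect**: each fraction on the primary triggers an
  immune pulse δ·Y₀·e^{−(t−tᵢ−lag)/τ} on the metastatic specific rate;
  if the rate is negative when the pulses are done, the decline continues
  exponentially at the frozen end-of-course rate.

A phenomenological fitting layer absorbs therapy effects into *effective*
Gompertz parameters refit per treatment phase (nonlinear least squares on
log size, χ²/dof-scaled uncertainties, correlation + RMS relative error),
estimates day-by-day specific growth rates from data, and flags
sign changes of k_eff — the signature of regression toward extinction.
A synthetic-data module generates multi-arm studies (antibody-like and
RT/abscopal-like designs) for end-to-end testing and calibration.

## Worked example

```r
library(gomptx)

gp <- gompertz_params(a = 0.054, k = 0.0164, N0 = 50)   # fibrosarcoma-like
rt <- radiation_schedule(c(9, 10, 11), 8, alpha = 0.3, beta = 0.03)

eff <- combined_log_effect(gp, rt, t0 = 0, t = 15)
eff
#> Combined log effect over [0, 15] days:
#>   growth term 0.718061, W_bar 0, D_nf 11.9408
#>   ln N(t) - ln N(t0) = -11.2227  (N: 50 -> 0.000668368)
regression_condition(eff)$is_regressing
#> [1] TRUE
```

The growth term (0.72 log units of regrowth over 15 days) is swamped by
the discounted RT log-kill D_nf = 11.94 (three 8 Gy fractions at
αd + βd² = 4.32 each), so the course predicts deep regression.

Fitting a noisy synthetic untreated arm recovers the generating
parameters with honest uncertainties:

```r
tr <- generate_trajectory(gp, days = 0:25, noise = noise_model(sd = 0.05), seed = 1)
fit_gompertz(tr)
#> Effective Gompertz fit (26 points, t0 = 0):
#>   a_eff = 0.05817 +/- 0.0059 day^-1
#>   k_eff = 0.0225 +/- 0.0085 day^-1
#>   effective carrying capacity = 658.3
#>   correlation = 0.9893, RMS relative error = 0.04424
```

The abscopal response of an unirradiated metastasis to the same course:

```r
syn <- synergy_params(delta = 1, tau = 5, lag = 3, Y0 = 0.1, t_in = 9)
met <- abscopal_trajectory(gp, syn, rt, t_grid = 0:40)
met$sizes[c(13, 21, 31, 41)]      # days 12, 20, 30, 40
#> [1] 90.039 22.757  3.025  0.402
```

The metastasis grows untreated until the first pulse onset (day 9 + lag
3), then the immune pulses drive its specific rate negative and it
declines toward extinction.

## Command line

A thin CLI wraps the same functions (`inst/cli/gomptx`, or call
`gomptx::run_cli()`):

```sh
gomptx synth --design rt-abscopal --out study.csv --seed 1
gomptx fit   --in study.csv --out fits.csv --phases 9,15 --linear-a-last
gomptx rate  --in study.csv --out rates.csv
gomptx abscopal --config inst/extdata/abscopal-example.yaml --out met.csv
```

Trajectory files are long-format CSV (`subject_id, arm, time_days, size,
unit`); run configs are strict YAML (unknown keys are errors) — see
`inst/extdata/abscopal-example.yaml`.

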