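# Therapy-perturbed dynamics: immunotherapy-modified Gompertz growth,
# linear-quadratic fraction kills, the closed-form fractionated course,
# the regression condition, and the RT-triggered synergy (abscopal) model.

#' Immunotherapy profile
#'
#' Describes the drug/immune level \eqn{I(t)} entering the perturbed
#' specific rate as \eqn{-\gamma I(t)}. Two profiles are supported:
#' constant \eqn{I(t) = I_0} and exponentially decaying
#' \eqn{I(t) = I_0 e^{-\rho t}} (clock starting when the therapy phase
#' starts). The sign of `gamma` carries the biology: a negative `gamma`
#' increases the specific growth rate (agonist), a positive one suppresses
#' it (antagonist).
#'
#' @param gamma Coupling constant, (day x I-unit)^-1; either sign.
#' @param I0 Initial drug/immune level, arbitrary I-units, `>= 0`.
#' @param rho Decay rate, day^-1, `>= 0`; `rho = 0` means constant profile.
#' @param mode `"constant"` or `"exponential"`; defaults to the mode
#'   implied by `rho`. `mode = "constant"` requires `rho = 0`.
#' @return An object of class `immunotherapy_profile`.
#' @export
immunotherapy_profile <- function(gamma, I0, rho = 0,
                                  mode = if (rho == 0) "constant" else "exponential") {
  mode <- match.arg(mode, c("constant", "exponential"))
  stopifnot(is.numeric(gamma), is.numeric(I0), is.numeric(rho),
            is.finite(gamma), is.finite(I0), is.finite(rho))
  if (I0 < 0) stop("I0 must be non-negative")
  if (rho < 0) stop("rho must be non-negative")
  if (mode == "constant" && rho != 0)
    stop("constant mode requires rho = 0")
  structure(list(gamma = gamma, I0 = I0, rho = rho, mode = mode),
            class = "immunotherapy_profile")
}

#' Fractionated radiotherapy schedule
#'
#' Fraction times and doses plus the linear-quadratic radiosensitivity
#' constants. Each fraction kills instantaneously with surviving fraction
#' \eqn{e^{-\alpha d - \beta d^2}}. The radiobiology convention
#' \eqn{\beta \simeq \alpha/10} is common but not enforced.
#'
#' @param times Fraction times, days, strictly increasing.
#' @param doses Doses in Gy, `>= 0`; recycled if scalar.
#' @param alpha Linear coefficient, Gy^-1, `>= 0`.
#' @param beta Quadratic coefficient, Gy^-2, `>= 0`.
#' @return An object of class `radiation_schedule`.
#' @examples
#' radiation_schedule(times = c(9, 10, 11), doses = 8, alpha = 0.3, beta = 0.03)
#' @export
radiation_schedule <- function(times, doses, alpha, beta = alpha / 10) {
  stopifnot(is.numeric(times), is.numeric(doses),
            is.numeric(alpha), is.numeric(beta))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("fraction times must be strictly increasing")
  if (length(doses) == 1L) doses <- rep(doses, length(times))
  if (length(doses) != length(times))
    stop("doses must be scalar or match the number of fraction times")
  if (any(doses < 0)) stop("doses must be non-negative")
  if (alpha < 0 || beta < 0) stop("alpha and beta must be non-negative")
  structure(list(times = as.numeric(times), doses = as.numeric(doses),
                 alpha = alpha, beta = beta),
            class = "radiation_schedule")
}

#' Linear-quadratic surviving fraction
#'
#' Surviving fraction after a single instantaneous dose:
#' \eqn{N_{t^+}/N_{t^-} = e^{-\alpha d - \beta d^2} \in (0, 1]}.
#'
#' @param dose Dose in Gy, `>= 0`.
#' @param alpha Gy^-1. @param beta Gy^-2.
#' @return Surviving fraction(s) in (0, 1].
#' @examples
#' lqm_survival(8, alpha = 0.3, beta = 0.03)
#' @export
lqm_survival <- function(dose, alpha, beta) {
  stopifnot(is.numeric(dose), is.numeric(alpha), is.numeric(beta))
  if (any(dose < 0)) stop("dose must be non-negative")
  exp(-(alpha * dose + beta * dose^2))
}

# per-fraction log-kills alpha*d + beta*d^2
.log_kills <- function(schedule) {
  schedule$alpha * schedule$doses + schedule$beta * schedule$doses^2
}

#' Synergy (abscopal) parameters
#'
#' Parameters of the radiotherapy-triggered immune attack on an
#' unirradiated metastatic site. Each delivered fraction triggers an
#' immune-response pulse of amplitude `Y0` that sets in `lag` days after
#' the fraction and decays exponentially with time constant `tau`; the
#' pulse enters the metastatic specific rate scaled by `delta`. With
#' `delta = 0` or `Y0 = 0` there is no synergy and the metastasis follows
#' untreated Gompertz growth. `Y0` may be a function of the fraction dose
#' (Gy) instead of a constant; the default is dose-independent.
#'
#' @param delta Synergy coupling (dimensionless scaling of the immune kill
#'   rate), `>= 0`.
#' @param tau Immune-response decay time, days, `> 0`.
#' @param lag Delay between a fraction and immune-effect onset, days,
#'   `>= 0`; defaults to `tau` (the onset delay and the decay time are
#'   distinct knobs, equal by default).
#' @param Y0 Triggered immune-response amplitude per fraction (day^-1 once
#'   multiplied by `delta`), `>= 0`, or a function `dose -> amplitude`.
#' @param t_in Radiotherapy start day; must not exceed the first fraction.
#' @return An object of class `synergy_params`.
#' @export
synergy_params <- function(delta, tau, lag = tau, Y0, t_in = 0) {
  stopifnot(is.numeric(delta), is.numeric(tau), is.numeric(lag),
            is.numeric(t_in))
  if (delta < 0) stop("delta must be non-negative")
  if (tau <= 0) stop("tau must be positive")
  if (lag < 0) stop("lag must be non-negative")
  if (is.function(Y0)) {
    y_fun <- Y0
  } else {
    stopifnot(is.numeric(Y0), length(Y0) == 1L)
    if (Y0 < 0) stop("Y0 must be non-negative")
    y_fun <- local({ y <- Y0; function(dose) rep(y, length(dose)) })
  }
  structure(list(delta = delta, tau = tau, lag = lag, Y0 = Y0,
                 y_fun = y_fun, t_in = t_in),
            class = "synergy_params")
}

#' Therapy course
#'
#' Bundles an immunotherapy profile, a radiotherapy schedule and synergy
#' parameters into one treatment description. Any component may be absent.
#'
#' @param it Optional [immunotherapy_profile()].
#' @param rt Optional [radiation_schedule()].
#' @param synergy Optional [synergy_params()] (used for metastatic sites).
#' @return An object of class `therapy_course`.
#' @export
therapy_course <- function(it = NULL, rt = NULL, synergy = NULL) {
  if (!is.null(it)) stopifnot(inherits(it, "immunotherapy_profile"))
  if (!is.null(rt)) stopifnot(inherits(rt, "radiation_schedule"))
  if (!is.null(synergy)) stopifnot(inherits(synergy, "synergy_params"))
  structure(list(it = it, rt = rt, synergy = synergy),
            class = "therapy_course")
}

# cumulative IT log-effect W(dt) = gamma * int_0^dt e^{-k(dt-s)} I(s) ds,
# closed forms for both profiles; |k - rho| < 1e-9 handled by the limit.
.it_w <- function(it, k, dt) {
  if (is.null(it) || it$gamma == 0 || it$I0 == 0) return(rep(0, length(dt)))
  g <- it$gamma * it$I0
  if (it$mode == "constant") {
    g * vapply(dt, function(d) .gk(k, d), numeric(1))
  } else {
    rho <- it$rho
    if (abs(k - rho) < 1e-9) {
      g * dt * exp(-k * dt)
    } else {
      g * (exp(-rho * dt) - exp(-k * dt)) / (k - rho)
    }
  }
}

#' Immunotherapy-perturbed Gompertz trajectory (closed form)
#'
#' Solves \eqn{(1/N) dN/dt = k \ln(N_\infty/N) - \gamma I(t)} in log-size
#' space: \eqn{u(t) = u_0 + a\,(1-e^{-kt})/k - W(t)} with
#' \eqn{W(t) = \gamma \int_0^t e^{-k(t-s)} I(s)\,ds}. For a constant
#' profile \eqn{W(t) = (\gamma I_0/k)(1-e^{-kt})}, i.e. the therapy shifts
#' the carrying capacity to \eqn{N_\infty e^{-\gamma I_0 / k}}; for an
#' exponential profile \eqn{W(t) = \gamma I_0 (e^{-\rho t} - e^{-kt})/(k-\rho)}
#' (the \eqn{k=\rho} limit \eqn{\gamma I_0\, t\, e^{-kt}} is taken below
#' \eqn{|k-\rho| < 10^{-9}}).
#'
#' @param gp A [gompertz_params()] object.
#' @param it An [immunotherapy_profile()].
#' @param t Time(s), days, `>= 0`.
#' @return Size(s) at `t`.
#' @export
it_trajectory <- function(gp, it, t) {
  stopifnot(inherits(gp, "gompertz_params"),
            inherits(it, "immunotherapy_profile"), is.numeric(t))
  if (any(t < 0)) stop("t must be non-negative")
  u <- log(gp$N0) + gp$a * vapply(t, function(ti) .gk(gp$k, ti), numeric(1)) -
    .it_w(it, gp$k, t)
  exp(u)
}

#' Effective carrying capacity under constant immunotherapy
#'
#' For a constant profile the perturbed dynamics saturate at
#' \eqn{N_\infty^{eff} = N_\infty e^{-\gamma I_0 / k}}.
#'
#' @inheritParams it_trajectory
#' @return The shifted asymptotic size (requires `k > 0` and constant mode).
#' @export
effective_carrying_capacity <- function(gp, it) {
  stopifnot(inherits(gp, "gompertz_params"),
            inherits(it, "immunotherapy_profile"))
  if (it$mode != "constant")
    stop("effective carrying capacity is defined for the constant profile")
  if (gp$k <= 0) return(Inf)
  carrying_capacity(gp) * exp(-it$gamma * it$I0 / gp$k)
}

#' Closed-form log-effect decomposition of a combined RT + IT course
#'
#' Decomposes \eqn{\ln N(t) - \ln N(t_0)} for a fractionated course into
#' three terms: the untreated growth term
#' \eqn{\ln(N_\infty/N(t_0))[1 - e^{-k(t-t_0)}]}, the cumulative
#' immunotherapy log-effect \eqn{\bar W}, and the cumulative radiotherapy
#' log-effect \eqn{D_{n_f}}. Because the log-space dynamics are linear,
#' each instantaneous fraction log-kill \eqn{\alpha d_i + \beta d_i^2} is
#' discounted by \eqn{e^{-k(t - t_i)}} at evaluation time, and
#' \eqn{\bar W(t, t_0) = \gamma \int_{t_0}^t e^{-k(t-s)} I(s)\,ds} (drug
#' clock starting at `t0`). The reconstruction
#' \eqn{N(t) = N(t_0)\exp(\mathrm{growth} - \bar W - D_{n_f})} equals the
#' recursive alternate-grow-and-kill construction exactly in log space.
#'
#' `gp$N0` is interpreted as the size at `t0`.
#'
#' @param gp A [gompertz_params()] object (`N0` = size at `t0`).
#' @param schedule Optional [radiation_schedule()]; fraction times must lie
#'   in `[t0, t]`.
#' @param it Optional [immunotherapy_profile()].
#' @param t0 Course start day. @param t Evaluation day, `>= t0`.
#' @return An object of class `combined_log_effect` with fields
#'   `growth_term`, `W_bar`, `D_nf`, `N_t0`, `N_t` and `log_change`.
#' @examples
#' gp <- gompertz_params(0.054, 0.0164, 50)
#' rt <- radiation_schedule(c(9, 10, 11), 8, alpha = 0.3, beta = 0.03)
#' combined_log_effect(gp, rt, t0 = 0, t = 15)
#' @export
combined_log_effect <- function(gp, schedule = NULL, it = NULL, t0 = 0, t) {
  stopifnot(inherits(gp, "gompertz_params"), is.numeric(t0), is.numeric(t),
            length(t) == 1L, length(t0) == 1L)
  if (t < t0) stop("t must be >= t0")
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "radiation_schedule"))
    if (length(schedule$times) &&
        (min(schedule$times) < t0 || max(schedule$times) > t))
      stop("fraction times must lie within [t0, t]")
  }
  if (!is.null(it)) stopifnot(inherits(it, "immunotherapy_profile"))

  growth_term <- gp$a * .gk(gp$k, t - t0)
  W_bar <- .it_w(it, gp$k, t - t0)
  D_nf <- 0
  if (!is.null(schedule) && length(schedule$times)) {
    D_nf <- sum(.log_kills(schedule) * exp(-gp$k * (t - schedule$times)))
  }
  log_change <- growth_term - W_bar - D_nf
  structure(list(growth_term = growth_term, W_bar = W_bar, D_nf = D_nf,
                 t0 = t0, t = t, N_t0 = gp$N0,
                 N_t = gp$N0 * exp(log_change), log_change = log_change),
            class = "combined_log_effect")
}

#' @export
print.combined_log_effect <- function(x, ...) {
  cat(sprintf(paste0("Combined log effect over [%g, %g] days:\n",
                     "  growth term %g, W_bar %g, D_nf %g\n",
                     "  ln N(t) - ln N(t0) = %g  (N: %g -> %g)\n"),
              x$t0, x$t, x$growth_term, x$W_bar, x$D_nf,
              x$log_change, x$N_t0, x$N_t))
  invisible(x)
}

#' Regression (tumor-shrinkage) condition for a therapy course
#'
#' The tumor cell number at the end of the course is below its start value
#' exactly when the log-change margin
#' \eqn{\ln(N_\infty/N(t_0))[1-e^{-k(t-t_0)}] - \bar W - D_{n_f}} is
#' negative. The near-critical flag marks courses where radiotherapy alone
#' almost balances regrowth (\eqn{|\mathrm{growth} - D_{n_f}|} below a
#' caller tolerance), so that a small immunotherapy contribution tips the
#' course into regression.
#'
#' @param effect A [combined_log_effect()].
#' @param near_critical_tol Tolerance, in log units, for the near-critical
#'   flag (default 0.05).
#' @return A list with `is_regressing`, `margin` and `near_critical`.
#' @export
regression_condition <- function(effect, near_critical_tol = 0.05) {
  stopifnot(inherits(effect, "combined_log_effect"),
            near_critical_tol >= 0)
  margin <- effect$growth_term - effect$W_bar - effect$D_nf
  list(is_regressing = margin < 0, margin = margin,
       near_critical = abs(effect$growth_term - effect$D_nf) < near_critical_tol)
}

# synergy kill term on the metastatic specific rate at time t:
# delta * sum_i Y0(d_i) * exp(-(t - t_i - lag)/tau) for t >= t_i + lag
.synergy_rate <- function(syn, schedule) {
  amps <- syn$delta * syn$y_fun(schedule$doses)
  onset <- schedule$times + syn$lag
  tau <- syn$tau
  function(t) {
    vapply(t, function(ti) {
      on <- ti >= onset
      if (!any(on)) return(0)
      -sum(amps[on] * exp(-(ti - onset[on]) / tau))
    }, numeric(1))
  }
}

#' Abscopal trajectory of an unirradiated metastatic site
#'
#' Time evolution of a metastasis whose regression is driven solely by the
#' systemic immune response that radiotherapy of the primary tumor
#' triggers (the direct drug term \eqn{\gamma I(t)} is set to zero). The
#' dynamics are piecewise:
#' \enumerate{
#'   \item before the first fraction's effect onset the site follows
#'     untreated Gompertz growth with its own parameters;
#'   \item during the radiotherapy window the specific rate is
#'     \eqn{k \ln(N_\infty/N) - \delta \sum_i Y_0 e^{-(t - t_i -
#'     \mathrm{lag})/\tau}} (pulses triggered by each fraction), integrated
#'     numerically;
#'   \item after the last fraction's onset, if the specific rate has turned
#'     negative the activated immune system keeps depleting the site
#'     exponentially at that frozen rate,
#'     \eqn{N(t) = N_{end} e^{r_{end}(t - t_{end})}}; otherwise the
#'     perturbed dynamics simply continue until the pulses decay.
#' }
#' The trajectory is continuous everywhere: radiotherapy of the primary
#' applies no instantaneous kill to the metastasis. The frozen rate
#' \eqn{r_{end}} is the model specific rate evaluated one integrator step
#' (`h = 1e-3` day) after the last fraction time plus `lag`.
#'
#' @param gp_met [gompertz_params()] of the (untreated) metastatic site.
#' @param syn [synergy_params()]; `t_in` must not exceed the first
#'   fraction time.
#' @param schedule [radiation_schedule()] delivered to the primary; must
#'   contain at least one fraction when `delta > 0`.
#' @param t_grid Strictly increasing evaluation times, days.
#' @return A [tumor_trajectory()].
#' @examples
#' gp <- gompertz_params(0.054, 0.0164, 50)
#' rt <- radiation_schedule(c(9, 10, 11), 8, alpha = 0.3, beta = 0.03)
#' syn <- synergy_params(delta = 1, tau = 5, lag = 3, Y0 = 0.1, t_in = 9)
#' tr <- abscopal_trajectory(gp, syn, rt, t_grid = 0:40)
#' @export
abscopal_trajectory <- function(gp_met, syn, schedule, t_grid) {
  stopifnot(inherits(gp_met, "gompertz_params"),
            inherits(syn, "synergy_params"),
            inherits(schedule, "radiation_schedule"), is.numeric(t_grid))
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing with at least two points")
  if (!length(schedule$times)) {
    if (syn$delta > 0)
      stop("synergy requires at least one radiotherapy fraction (no dose, no synergy)")
    return(integrate_growth(gp_met, t_grid = t_grid, arm = "metastasis"))
  }
  if (syn$t_in > min(schedule$times))
    stop("t_in must not exceed the first fraction time")

  amps_zero <- syn$delta == 0 ||
    all(syn$y_fun(schedule$doses) == 0)
  if (amps_zero)
    return(integrate_growth(gp_met, t_grid = t_grid, arm = "metastasis"))

  pert <- .synergy_rate(syn, schedule)
  t_end <- max(schedule$times) + syn$lag
  t_max <- t_grid[length(t_grid)]
  if (t_end >= t_max)
    return(integrate_growth(gp_met, perturbation = pert, t_grid = t_grid,
                            arm = "metastasis"))

  h <- 1e-3
  pre_grid <- sort(unique(c(t_grid[t_grid <= t_end], t_end, t_end + h)))
  if (pre_grid[1] > t_grid[1]) pre_grid <- c(t_grid[1], pre_grid)
  pre <- integrate_growth(gp_met, perturbation = pert, t_grid = pre_grid,
                          arm = "metastasis")
  n_pre <- length(pre_grid)
  N_probe <- pre$sizes[n_pre]                     # at t_end + h
  r_end <- specific_rate(gp_met, N_probe) + pert(t_end + h)

  keep <- match(t_grid[t_grid <= t_end], pre_grid)
  out_t <- t_grid
  out_N <- numeric(length(t_grid))
  out_N[t_grid <= t_end] <- pre$sizes[keep]

  later <- t_grid > t_end
  if (r_end < 0) {
    # assumption: the activated immune response keeps an exponential
    # depletion at the end-of-RT specific rate
    N_end <- pre$sizes[match(t_end, pre_grid)]
    out_N[later] <- N_end * exp(r_end * (t_grid[later] - t_end))
  } else {
    N_end <- pre$sizes[match(t_end, pre_grid)]
    gp_cont <- gompertz_params(specific_rate(gp_met, N_end),
                               gp_met$k, N_end, unit = gp_met$unit)
    # continue the perturbed Gompertz dynamics from t_end; re-express the
    # pulse clock relative to t_end
    pert_shift <- function(t) pert(t + t_end)
    cont_grid <- c(0, t_grid[later] - t_end)
    cont <- integrate_growth(gp_cont, perturbation = pert_shift,
                             t_grid = cont_grid)
    out_N[later] <- cont$sizes[-1]
  }
  tumor_trajectory(out_t, out_N, subject_id = "metastasis",
                   arm = "metastasis", unit = gp_met$unit)
}
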