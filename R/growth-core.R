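# Untreated Gompertz dynamics: parameter container, specific rate,
# closed-form solution, and the numerical event integrator that serves as
# the oracle for every closed form in the package.

# (1 - exp(-k*dt))/k, stable for |k| -> 0 (series below the branch threshold)
.gk <- function(k, dt) {
  if (abs(k) < 1e-9) {
    dt - k * dt^2 / 2 + k^2 * dt^3 / 6
  } else {
    -expm1(-k * dt) / k
  }
}

#' Gompertz growth parameters
#'
#' Container for the triple \eqn{(a, k, N_0)} defining Gompertz dynamics:
#' specific growth rate \eqn{a - k \ln(N/N_0)}, carrying capacity
#' \eqn{N_\infty = N_0 e^{a/k}} (finite for \eqn{k > 0}). Untreated tumors
#' have \eqn{a > 0, k > 0}; effective (fitted) parameters may carry either
#' sign, so only `N0 > 0` is enforced here.
#'
#' @param a Exponential growth rate, day^-1.
#' @param k Limiting-factor rate, day^-1. `k = 0` gives pure exponential
#'   growth (handled by an explicit small-`|k|` branch throughout).
#' @param N0 Initial size (cells, mm^3, or mm; the unit is carried as an
#'   opaque label, all sizes are positive reals).
#' @param unit Free-text unit label.
#' @return An object of class `gompertz_params`.
#' @examples
#' gp <- gompertz_params(a = 0.049, k = 0.011, N0 = 100)
#' carrying_capacity(gp)
#' @export
gompertz_params <- function(a, k, N0, unit = "mm^3") {
  stopifnot(is.numeric(a), is.numeric(k), is.numeric(N0),
            length(a) == 1L, length(k) == 1L, length(N0) == 1L,
            is.finite(a), is.finite(k), is.finite(N0))
  if (N0 <= 0) stop("N0 must be positive")
  structure(list(a = a, k = k, N0 = N0, unit = as.character(unit)),
            class = "gompertz_params")
}

#' @export
print.gompertz_params <- function(x, ...) {
  cat(sprintf("Gompertz parameters: a = %g /day, k = %g /day, N0 = %g %s\n",
              x$a, x$k, x$N0, x$unit))
  if (x$k > 0)
    cat(sprintf("  carrying capacity N_inf = %g %s\n",
                carrying_capacity(x), x$unit))
  invisible(x)
}

#' Carrying capacity of a Gompertz model
#'
#' \eqn{N_\infty = N_0 e^{a/k}}; `Inf` when `k <= 0` (no finite saturation).
#'
#' @param gp A [gompertz_params()] object.
#' @return The asymptotic size, in the units of `N0`.
#' @export
carrying_capacity <- function(gp) {
  stopifnot(inherits(gp, "gompertz_params"))
  if (gp$k <= 0) return(Inf)
  gp$N0 * exp(gp$a / gp$k)
}

#' Gompertz specific growth rate
#'
#' The per-size growth rate \eqn{(1/N)\,dN/dt = a - k \ln(N/N_0)},
#' equivalently \eqn{k \ln(N_\infty/N)} for \eqn{k \neq 0}. Negative values
#' indicate regression.
#'
#' @param gp A [gompertz_params()] object.
#' @param N Size(s) at which to evaluate; must be positive.
#' @return Specific rate(s), day^-1.
#' @examples
#' gp <- gompertz_params(0.049, 0.011, 100)
#' specific_rate(gp, 100)              # a at N = N0
#' specific_rate(gp, carrying_capacity(gp))  # 0 at saturation
#' @export
specific_rate <- function(gp, N) {
  stopifnot(inherits(gp, "gompertz_params"), is.numeric(N))
  if (any(!is.finite(N)) || any(N <= 0)) stop("N must be positive and finite")
  gp$a - gp$k * log(N / gp$N0)
}

#' Closed-form Gompertz size
#'
#' \eqn{N(t) = N_0 \exp\{(a/k)(1 - e^{-kt})\}} for \eqn{k \neq 0}; the
#' \eqn{k \to 0} limit \eqn{N_0 e^{at}} is taken explicitly below
#' \eqn{|k| < 10^{-9}} day^-1.
#'
#' @param gp A [gompertz_params()] object.
#' @param t Time(s) in days, `t >= 0`.
#' @return Size(s) at `t`, same units as `N0`.
#' @examples
#' gompertz_size(gompertz_params(0.1, 0.05, 100), c(0, 50, 200))
#' @export
gompertz_size <- function(gp, t) {
  stopifnot(inherits(gp, "gompertz_params"), is.numeric(t))
  if (any(t < 0)) stop("t must be non-negative")
  gp$N0 * exp(gp$a * vapply(t, function(ti) .gk(gp$k, ti), numeric(1)))
}

#' Numerically integrate perturbed Gompertz growth with kill events
#'
#' Integrates \eqn{d(\ln N)/dt = a - k \ln(N/N_0) + p(t)} on a time grid,
#' applying instantaneous log-kills at event times. All dynamics run in
#' log-size space, where the Gompertz law is linear, kills are subtractions
#' and positivity is automatic. This integrator is the independent oracle
#' against which the package's closed forms are checked; relative accuracy
#' against those closed forms is at the 1e-10 tolerance of the adaptive
#' stepper.
#'
#' @param gp A [gompertz_params()] object.
#' @param perturbation Optional function of time (days) returning an
#'   additive term on the specific rate, day^-1. `NULL` means untreated.
#' @param kill_events Optional data frame with columns `time` and
#'   `log_kill`: at each `time`, `log_kill` is subtracted from \eqn{\ln N}.
#'   The reported value AT an event time is post-kill (right-continuous).
#' @param t_grid Strictly increasing evaluation times, days; event times
#'   must lie within its span.
#' @param subject_id,arm,unit Metadata passed to [tumor_trajectory()].
#' @return A [tumor_trajectory()] evaluated at `t_grid`.
#' @examples
#' gp <- gompertz_params(0.054, 0.0164, 50)
#' kills <- data.frame(time = c(9, 10, 11), log_kill = 4.32)
#' tr <- integrate_growth(gp, kill_events = kills, t_grid = 0:25)
#' @export
integrate_growth <- function(gp, perturbation = NULL, kill_events = NULL,
                             t_grid, subject_id = "model", arm = "",
                             unit = gp$unit) {
  stopifnot(inherits(gp, "gompertz_params"), is.numeric(t_grid))
  if (length(t_grid) < 1L || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing")
  if (!is.null(kill_events)) {
    stopifnot(is.data.frame(kill_events),
              all(c("time", "log_kill") %in% names(kill_events)))
    if (nrow(kill_events) &&
        (min(kill_events$time) < t_grid[1] ||
         max(kill_events$time) > t_grid[length(t_grid)]))
      stop("kill event times must lie within the span of t_grid")
  }
  pert <- if (is.null(perturbation)) function(t) 0 else perturbation
  u0 <- log(gp$N0)
  rate <- function(t, u, parms) {
    p <- pert(t)
    if (!all(is.finite(p))) stop("perturbation returned non-finite value")
    list(gp$a - gp$k * (u - u0) + p)
  }

  # collapse simultaneous kills (log-kills add), segment the integration
  ev_t <- numeric(0); ev_d <- numeric(0)
  if (!is.null(kill_events) && nrow(kill_events)) {
    agg <- tapply(kill_events$log_kill, kill_events$time, sum)
    ev_t <- as.numeric(names(agg)); ev_d <- as.numeric(agg)
    o <- order(ev_t); ev_t <- ev_t[o]; ev_d <- ev_d[o]
  }

  out_u <- numeric(length(t_grid))
  seg_start <- t_grid[1]
  u_cur <- u0
  # kills at or before the first grid point apply immediately
  pre <- ev_t <= seg_start
  if (any(pre)) u_cur <- u_cur - sum(ev_d[pre])
  boundaries <- c(ev_t[!pre], t_grid[length(t_grid)])
  kills_left <- c(ev_d[!pre], 0)
  idx_done <- t_grid <= seg_start
  out_u[idx_done] <- u_cur

  for (j in seq_along(boundaries)) {
    seg_end <- boundaries[j]
    if (seg_end > seg_start) {
      inner <- t_grid[t_grid > seg_start & t_grid < seg_end]
      times <- unique(c(seg_start, inner, seg_end))
      sol <- deSolve::ode(y = c(u = u_cur), times = times, func = rate,
                          parms = NULL, method = "lsoda",
                          rtol = 1e-10, atol = 1e-10)
      u_t <- sol[, "u"]
      if (length(inner))
        out_u[match(inner, t_grid)] <- u_t[match(inner, times)]
      u_cur <- u_t[length(u_t)]
    }
    u_cur <- u_cur - kills_left[j]           # post-kill at the boundary
    hit <- which(t_grid == seg_end)
    if (length(hit)) out_u[hit] <- u_cur
    seg_start <- seg_end
  }

  tumor_trajectory(times = t_grid, sizes = exp(out_u),
                   subject_id = subject_id, arm = arm, unit = unit)
}
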