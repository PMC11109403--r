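# Phenomenological analysis layer: effective Gompertz parameter fits per
# treatment phase, day-by-day specific growth rate estimation, and the
# goodness statistics reported alongside the fits.

# predicted log size at times t for parameters th = c(a, k) (and u0 if
# co-estimated), anchored at (t0, u0). With linear_a the specific rate is
# a*(t - t0) - k*ln(N/N(t0)) and a carries day^-2 units:
#   u(t) - u0 = (a/k) * (dt - (1 - e^{-k dt})/k),  -> a dt^2/2 as k -> 0
.gl_log_size <- function(a, k, u0, t, t0, linear_a = FALSE) {
  dt <- t - t0
  g <- vapply(dt, function(d) .gk(k, d), numeric(1))
  if (!linear_a) {
    u0 + a * g
  } else if (abs(k) < 1e-6) {
    u0 + a * dt^2 / 2 - a * k * dt^3 / 6
  } else {
    u0 + (a / k) * (dt - g)
  }
}

.fit_start_grid <- function(times, lsz) {
  # data-driven start: average log-slope; then the fixed deterministic grid
  slope <- if (length(times) > 1L)
    (lsz[length(lsz)] - lsz[1]) / (times[length(times)] - times[1]) else 0.05
  grid <- expand.grid(a = c(0.01, 0.05, 0.1, 0.3),
                      k = c(0.005, -0.005, 0.05, -0.05, 0.3, -0.3))
  rbind(data.frame(a = slope, k = 0.01), grid)
}

# finite-difference Jacobian of a residual function at a point
.num_jacobian <- function(fn, par, eps = 1e-6) {
  r0 <- fn(par)
  J <- matrix(NA_real_, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(1, abs(par[j]))
    pp <- par; pp[j] <- pp[j] + h
    J[, j] <- (fn(pp) - r0) / h
  }
  J
}

#' Goodness-of-fit statistics
#'
#' Pearson correlation between observed and fitted sizes, and the root
#' mean squared relative error \eqn{\sqrt{\mathrm{mean}[((obs -
#' fit)/fit)^2]}}.
#'
#' @param observed,fitted Equal-length size vectors, `fitted > 0`,
#'   length `>= 2`.
#' @return A list with `correlation` (NA with a `degenerate` flag if
#'   either vector has zero variance) and `rms_relative_error`.
#' @export
goodness_stats <- function(observed, fitted) {
  stopifnot(is.numeric(observed), is.numeric(fitted),
            length(observed) == length(fitted), length(observed) >= 2L)
  if (any(fitted <= 0)) stop("fitted sizes must be positive")
  degenerate <- stats::sd(observed) == 0 || stats::sd(fitted) == 0
  r <- if (degenerate) NA_real_ else stats::cor(observed, fitted)
  list(correlation = r,
       rms_relative_error = sqrt(mean(((observed - fitted) / fitted)^2)),
       degenerate = degenerate)
}

#' Fit effective Gompertz parameters to a tumor trajectory
#'
#' Nonlinear least squares of the closed-form Gompertz law for the
#' effective parameters \eqn{(a_{eff}, k_{eff})}, by default on log sizes
#' (a multiplicative measurement-error assumption, under which the model
#' is linear in its log form) with \eqn{N(t_0)} co-estimated alongside
#' them; anchoring \eqn{N(t_0)} to a noisy first observation biases both
#' rate estimates, so the fixed anchor is an option (`fix_N0 = TRUE`,
#' used by [fit_phasewise()] for cross-phase continuity). The optimizer
#' is Levenberg-Marquardt with a deterministic multi-start grid;
#' parameter uncertainties come from the \eqn{\chi^2}/dof-scaled
#' covariance of the best fit.
#'
#' With `a_linear_time = TRUE` the exponential-rate parameter enters as
#' \eqn{a_{eff} (t - t_0)} (units day^-2), the parameterization used for
#' end-of-therapy phases where the specific rate keeps falling linearly;
#' negative \eqn{(a_{eff}, k_{eff})} then describe an extinction regime
#' with no finite carrying capacity.
#'
#' @param traj A [tumor_trajectory()] (or data frame with `time_days` and
#'   `size` columns); at least 4 points.
#' @param init Optional named list/vector with starting `a` and `k`
#'   (prepended to the multi-start grid).
#' @param log_scale Fit on log sizes (default) or on the raw scale.
#' @param fix_N0 Fix \eqn{\ln N(t_0)} to `u0` instead of co-estimating it
#'   (default `FALSE`).
#' @param a_linear_time Use the linearly time-dependent rate
#'   parameterization described above.
#' @param t0 Phase origin, defaulting to the first observation time.
#' @param u0 Optional anchor for \eqn{\ln N(t_0)} (used by
#'   [fit_phasewise()] for continuity across phases); default is the log
#'   of the first observed size.
#' @return An object of class `gl_fit` with elements `a`, `k`, `a_err`,
#'   `k_err`, `t0`, `N_t0`, `a_linear_time`, `correlation`,
#'   `rms_relative_error`, `n_points`, `fitted`, `chisq_dof`,
#'   `degenerate`, `converged`.
#' @examples
#' gp <- gompertz_params(0.1, 0.02, 100)
#' tr <- tumor_trajectory(seq(0, 60, length.out = 20),
#'                        gompertz_size(gp, seq(0, 60, length.out = 20)))
#' fit_gompertz(tr)
#' @export
fit_gompertz <- function(traj, init = NULL, log_scale = TRUE,
                         fix_N0 = FALSE, a_linear_time = FALSE,
                         t0 = NULL, u0 = NULL) {
  if (is.data.frame(traj)) {
    traj <- tumor_trajectory(traj$time_days, traj$size)
  }
  stopifnot(inherits(traj, "tumor_trajectory"))
  times <- traj$times; sizes <- traj$sizes
  if (length(times) < 4L) stop("need at least 4 data points to fit")
  lsz <- log(sizes)
  if (is.null(t0)) t0 <- times[1]
  if (is.null(u0)) u0 <- lsz[1]

  # degenerate series: no dynamics, k unidentifiable
  if (stats::sd(lsz) < 1e-12) {
    return(structure(list(a = 0, k = NA_real_, a_err = NA_real_,
                          k_err = NA_real_, t0 = t0, N_t0 = exp(u0),
                          a_linear_time = a_linear_time,
                          correlation = NA_real_, rms_relative_error = 0,
                          n_points = length(times), fitted = sizes,
                          chisq_dof = 0, degenerate = TRUE,
                          converged = TRUE),
                     class = "gl_fit"))
  }

  resid_fn <- function(par) {
    a <- par[1]; k <- par[2]
    u_fit <- if (fix_N0) u0 else par[3]
    u <- .gl_log_size(a, k, u_fit, times, t0, a_linear_time)
    if (log_scale) lsz - u else sizes - exp(pmin(u, 700))
  }

  starts <- .fit_start_grid(times, lsz)
  if (!is.null(init)) {
    init <- as.list(init)
    starts <- rbind(data.frame(a = init$a, k = init$k), starts)
  }
  best <- NULL; best_ss <- Inf
  for (i in seq_len(nrow(starts))) {
    par0 <- c(starts$a[i], starts$k[i])
    if (!fix_N0) par0 <- c(par0, u0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (is.finite(ss) && ss < best_ss) { best_ss <- ss; best <- fit }
  }
  if (is.null(best))
    stop("Gompertz fit did not converge from any start value")

  par <- best$par
  n <- length(times); p <- length(par)
  dof <- max(n - p, 1L)
  chisq_dof <- best_ss / dof
  J <- .num_jacobian(resid_fn, par)
  covm <- tryCatch(chisq_dof * solve(crossprod(J)),
                   error = function(e) matrix(NA_real_, p, p))
  errs <- sqrt(pmax(diag(covm), 0))

  u_fit <- if (fix_N0) u0 else par[3]
  fitted_sizes <- exp(.gl_log_size(par[1], par[2], u_fit, times, t0,
                                   a_linear_time))
  gs <- goodness_stats(sizes, fitted_sizes)
  structure(list(a = par[1], k = par[2], a_err = errs[1], k_err = errs[2],
                 t0 = t0, N_t0 = exp(u_fit),
                 a_linear_time = a_linear_time,
                 correlation = gs$correlation,
                 rms_relative_error = gs$rms_relative_error,
                 n_points = n, fitted = fitted_sizes,
                 chisq_dof = chisq_dof, degenerate = FALSE,
                 converged = TRUE),
            class = "gl_fit")
}

#' @export
print.gl_fit <- function(x, ...) {
  unit_a <- if (x$a_linear_time) "day^-2" else "day^-1"
  cat(sprintf("Effective Gompertz fit (%d points, t0 = %g):\n",
              x$n_points, x$t0))
  cat(sprintf("  a_eff = %.4g +/- %.2g %s%s\n", x$a, x$a_err, unit_a,
              if (x$a_linear_time) " (linear time dependence)" else ""))
  cat(sprintf("  k_eff = %.4g +/- %.2g day^-1\n", x$k, x$k_err))
  if (isTRUE(x$degenerate)) {
    cat("  degenerate series: k unidentifiable\n")
  } else if (!x$a_linear_time && !is.na(x$k) && x$k > 0 && x$a > 0) {
    cat(sprintf("  effective carrying capacity = %.4g\n",
                x$N_t0 * exp(x$a / x$k)))
  } else if (!is.na(x$k) && (x$k < 0 || x$a < 0)) {
    cat("  extinction regime (negative effective rates, no finite carrying capacity)\n")
  }
  cat(sprintf("  correlation = %.4g, RMS relative error = %.4g\n",
              x$correlation, x$rms_relative_error))
  invisible(x)
}

#' @export
as.data.frame.gl_fit <- function(x, ..., phase = NA_character_) {
  data.frame(phase = phase, a_eff = x$a, a_err = x$a_err,
             k_eff = x$k, k_err = x$k_err,
             corr = x$correlation, rms_rel_err = x$rms_relative_error,
             n_points = x$n_points, a_linear_time = x$a_linear_time,
             stringsAsFactors = FALSE)
}

#' Phase-wise effective-parameter fits
#'
#' Segments a trajectory at caller-supplied phase boundaries (treatment
#' days are known, so no change-point detection) and fits effective
#' Gompertz parameters independently per phase. Each phase after the first
#' is anchored for continuity: its \eqn{N(t_0)} is the preceding phase's
#' fitted curve evaluated at the boundary. Sign changes of the effective
#' parameters across phases are the model's regression indicator — a
#' negative \eqn{k_{eff}} (with the optional linearly time-dependent
#' \eqn{a_{eff}} in the final phase) signals depletion toward extinction.
#'
#' Points with `time >= break[j-1]` and `< break[j]` belong to phase `j`;
#' the last phase includes its right endpoint.
#'
#' @param traj A [tumor_trajectory()].
#' @param phase_breaks Increasing interior boundary days within the
#'   trajectory span; empty for a single-phase fit.
#' @param linear_a_last_phase Use the `a_linear_time` parameterization for
#'   the final phase.
#' @param ... Further arguments passed to [fit_gompertz()].
#' @return An object of class `gl_phase_fits`: a list of `gl_fit` objects
#'   with `phase_labels` and a `k_signs` summary attribute.
#' @export
fit_phasewise <- function(traj, phase_breaks = numeric(0),
                          linear_a_last_phase = FALSE, ...) {
  stopifnot(inherits(traj, "tumor_trajectory"), is.numeric(phase_breaks))
  times <- traj$times
  if (length(phase_breaks)) {
    if (any(diff(phase_breaks) <= 0)) stop("phase_breaks must be increasing")
    if (min(phase_breaks) <= times[1] || max(phase_breaks) >= times[length(times)])
      stop("phase_breaks must lie strictly within the trajectory time span")
  }
  edges <- c(times[1], phase_breaks, times[length(times)])
  n_phase <- length(edges) - 1L
  fits <- vector("list", n_phase)
  labels <- character(n_phase)
  u_anchor <- NULL; t_anchor <- NULL
  for (j in seq_len(n_phase)) {
    last <- j == n_phase
    sel <- times >= edges[j] & (if (last) times <= edges[j + 1] else times < edges[j + 1])
    if (sum(sel) < 3L)
      stop(sprintf("phase %d has %d points; need at least 3", j, sum(sel)))
    ph <- tumor_trajectory(times[sel], traj$sizes[sel],
                           subject_id = traj$subject_id, arm = traj$arm,
                           unit = traj$unit)
    # anchor this phase's N(t0) to the previous phase's fitted curve;
    # the first phase co-estimates its own starting size
    t0_j <- if (j == 1L) ph$times[1] else edges[j]
    u0_j <- if (j == 1L) NULL else u_anchor
    fits[[j]] <- fit_gompertz(ph, t0 = t0_j, u0 = u0_j, fix_N0 = j > 1L,
                              a_linear_time = last && linear_a_last_phase,
                              ...)
    f <- fits[[j]]
    u_next <- .gl_log_size(f$a, f$k, log(f$N_t0), edges[j + 1], f$t0,
                           f$a_linear_time)
    u_anchor <- u_next
    labels[j] <- sprintf("phase%d[%g,%g]", j, edges[j], edges[j + 1])
  }
  k_signs <- vapply(fits, function(f) sign(f$k), numeric(1))
  a_signs <- vapply(fits, function(f) sign(f$a), numeric(1))
  structure(fits, class = "gl_phase_fits", phase_labels = labels,
            k_signs = k_signs, a_signs = a_signs,
            regression_flagged = any(k_signs < 0, na.rm = TRUE))
}

#' @export
print.gl_phase_fits <- function(x, ...) {
  labels <- attr(x, "phase_labels")
  for (j in seq_along(x)) {
    cat("--", labels[j], "--\n")
    print(x[[j]])
  }
  if (isTRUE(attr(x, "regression_flagged")))
    cat("Sign change of k_eff across phases: regression/extinction indicated.\n")
  invisible(x)
}

#' @export
as.data.frame.gl_phase_fits <- function(x, ...) {
  labels <- attr(x, "phase_labels")
  do.call(rbind, lapply(seq_along(x), function(j)
    as.data.frame(x[[j]], phase = labels[j])))
}

#' Day-by-day specific growth rate from data
#'
#' Finite-difference estimate of \eqn{d(\ln N)/dt} on the observation
#' grid: central differences in the interior and one-sided differences at
#' the ends (`method = "central"`), or forward differences throughout with
#' a backward difference at the last point (`method = "forward"`).
#' Negative values flag regression.
#'
#' @param traj A [tumor_trajectory()] with at least 3 points and no
#'   duplicate time stamps.
#' @param method `"central"` (default) or `"forward"`.
#' @return An object of class `specific_rate_series`: a data frame with
#'   columns `time_days` and `rate` (day^-1) and a `method` attribute.
#' @export
estimate_specific_rate <- function(traj, method = c("central", "forward")) {
  method <- match.arg(method)
  stopifnot(inherits(traj, "tumor_trajectory"))
  t <- traj$times; u <- log(traj$sizes); n <- length(t)
  if (n < 3L) stop("need at least 3 points")
  if (anyDuplicated(t)) stop("duplicate time stamps")
  r <- numeric(n)
  if (method == "central") {
    i <- 2:(n - 1)
    r[i] <- (u[i + 1] - u[i - 1]) / (t[i + 1] - t[i - 1])
    r[1] <- (u[2] - u[1]) / (t[2] - t[1])
    r[n] <- (u[n] - u[n - 1]) / (t[n] - t[n - 1])
  } else {
    i <- 1:(n - 1)
    r[i] <- (u[i + 1] - u[i]) / (t[i + 1] - t[i])
    r[n] <- r[n - 1]
  }
  out <- data.frame(time_days = t, rate = r)
  structure(out, class = c("specific_rate_series", "data.frame"),
            method = method)
}

#' Model-based specific growth rate along a fitted curve
#'
#' Specific rate implied by a `gl_fit` at given times:
#' \eqn{a - k \ln(N(t)/N(t_0))}, or
#' \eqn{a (t - t_0) - k \ln(N(t)/N(t_0))} for the linearly time-dependent
#' parameterization.
#'
#' @param fit A `gl_fit` object. @param t Times, days.
#' @return Numeric vector of rates, day^-1.
#' @export
fitted_specific_rate <- function(fit, t) {
  stopifnot(inherits(fit, "gl_fit"))
  u0 <- log(fit$N_t0)
  u <- .gl_log_size(fit$a, fit$k, u0, t, fit$t0, fit$a_linear_time)
  a_t <- if (fit$a_linear_time) fit$a * (t - fit$t0) else fit$a
  a_t - fit$k * (u - u0)
}
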