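# Shared generators for property-style tests.

# random untreated Gompertz parameter draws
draw_gp <- function(n, a_range = c(0.01, 0.2), k_range = c(0.001, 0.2),
                    N0_range = c(1, 100)) {
  lapply(seq_len(n), function(i)
    gompertz_params(a = stats::runif(1, a_range[1], a_range[2]),
                    k = stats::runif(1, k_range[1], k_range[2]),
                    N0 = stats::runif(1, N0_range[1], N0_range[2])))
}

# random fractionated schedule within [t0, t_max]
draw_schedule <- function(t0 = 0, t_max = 30) {
  nf <- sample(1:6, 1)
  times <- sort(stats::runif(nf, t0 + 0.5, t_max - 0.5))
  while (any(diff(times) < 1e-3)) times <- sort(stats::runif(nf, t0 + 0.5, t_max - 0.5))
  radiation_schedule(times, doses = stats::runif(nf, 1, 12),
                     alpha = stats::runif(1, 0.05, 0.5),
                     beta = stats::runif(1, 0.005, 0.05))
}

# recursive kill-and-regrow oracle: alternate closed-form Gompertz
# evolution and instantaneous LQM kills, in log space
recursive_course_logN <- function(gp, schedule, t0, t) {
  u <- log(gp$N0)
  u0_anchor <- log(gp$N0)         # reference level for the specific rate
  kills <- schedule$alpha * schedule$doses + schedule$beta * schedule$doses^2
  # exact propagation of d u/dt = a - k (u - u0_anchor) over dt
  evolve <- function(u, dt) {
    if (abs(gp$k) < 1e-12) return(u + gp$a * dt)
    u0_anchor + (u - u0_anchor) * exp(-gp$k * dt) +
      (gp$a / gp$k) * (1 - exp(-gp$k * dt))
  }
  t_cur <- t0
  for (i in seq_along(schedule$times)) {
    ti <- schedule$times[i]
    if (ti > t) break
    u <- evolve(u, ti - t_cur)
    u <- u - kills[i]
    t_cur <- ti
  }
  evolve(u, t - t_cur)
}

# the three-phase sign-structure study: Gompertz growth, slowed growth,
# then accelerating decay with the linearly time-dependent rate form
gen_three_phase <- function(seed, sd = 0.01,
                            p1 = c(0.135, 0.131), p2 = c(0.04, 0.3),
                            p3 = c(-5.06e-4, -0.464)) {
  gpA <- gompertz_params(p1[1], p1[2], 50)
  sA <- gompertz_size(gpA, 0:8)
  gpB <- gompertz_params(p2[1], p2[2], gompertz_size(gpA, 9))
  sB <- gompertz_size(gpB, (9:14) - 9)
  NC <- gompertz_size(gpB, 6)
  a3 <- p3[1]; k3 <- p3[2]; dt <- 0:10
  uC <- log(NC) + (a3 / k3) * (dt - (1 - exp(-k3 * dt)) / k3)
  set.seed(seed)
  tumor_trajectory(0:25, c(sA, sB, exp(uC)) * exp(stats::rnorm(26, 0, sd)))
}
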