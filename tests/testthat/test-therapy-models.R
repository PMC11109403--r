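test_that("LQM surviving fraction follows exp(-alpha d - beta d^2)", {
  expect_equal(lqm_survival(0, 0.3, 0.03), 1)
  expect_equal(lqm_survival(8, 0.3, 0.03), exp(-4.32))
  expect_equal(lqm_survival(8, 0.3, 0.03), 0.0133, tolerance = 1e-2)
  # the beta = alpha/10 convention is the schedule default
  sched <- radiation_schedule(9, 8, alpha = 0.3)
  expect_equal(sched$beta, 0.03)
  expect_error(lqm_survival(-1, 0.3, 0.03), "non-negative")
})

test_that("IT-perturbed closed form matches the ODE oracle for both profiles", {
  gp <- gompertz_params(0.07, 0.015, 20)
  grid <- seq(0, 90, by = 3)
  # constant profile
  it_c <- immunotherapy_profile(gamma = 0.02, I0 = 1, rho = 0)
  orc <- integrate_growth(gp, perturbation = function(t) rep(-0.02, length(t)),
                          t_grid = grid)
  expect_lt(max(abs(it_trajectory(gp, it_c, grid) - orc$sizes) / orc$sizes), 1e-8)
  # exponential profile
  it_e <- immunotherapy_profile(gamma = 0.05, I0 = 1, rho = 0.2)
  orc2 <- integrate_growth(gp, perturbation = function(t) -0.05 * exp(-0.2 * t),
                           t_grid = grid)
  expect_lt(max(abs(it_trajectory(gp, it_e, grid) - orc2$sizes) / orc2$sizes), 1e-8)
  # k == rho limit branch
  it_l <- immunotherapy_profile(gamma = 0.05, I0 = 1, rho = gp$k)
  orc3 <- integrate_growth(gp, perturbation = function(t) -0.05 * exp(-gp$k * t),
                           t_grid = grid)
  expect_lt(max(abs(it_trajectory(gp, it_l, grid) - orc3$sizes) / orc3$sizes), 1e-7)
})

test_that("constant immunotherapy shifts the carrying capacity by exp(-gamma I0 / k)", {
  gp <- gompertz_params(0.05, 0.01, 10)
  it <- immunotherapy_profile(gamma = 0.02, I0 = 1, rho = 0)
  eff <- effective_carrying_capacity(gp, it)
  expect_equal(eff, carrying_capacity(gp) * exp(-2))
  expect_equal(it_trajectory(gp, it, 3000), eff, tolerance = 1e-8)
})

test_that("immunotherapy limits: zero coupling and instant decay recover untreated growth", {
  gp <- gompertz_params(0.06, 0.02, 5)
  t <- seq(0, 60, by = 5)
  un <- gompertz_size(gp, t)
  it0 <- immunotherapy_profile(gamma = 0, I0 = 1, rho = 0)
  expect_equal(it_trajectory(gp, it0, t), un)
  it_fast <- immunotherapy_profile(gamma = 0.05, I0 = 1, rho = 1e3)
  expect_lt(max(abs(it_trajectory(gp, it_fast, t[-1]) - un[-1]) / un[-1]), 1e-4)
})

test_that("gamma sign carries agonist/antagonist semantics pointwise", {
  gp <- gompertz_params(0.06, 0.02, 5)
  t <- seq(1, 60, by = 1)
  un <- gompertz_size(gp, t)
  ago <- it_trajectory(gp, immunotherapy_profile(-0.02, 1, 0), t)
  ant <- it_trajectory(gp, immunotherapy_profile(0.02, 1, 0), t)
  expect_true(all(ago > un))
  expect_true(all(ant < un))
})

test_that("combined log effect reconstructs the recursive kill-and-regrow course", {
  gp <- gompertz_params(0.054, 0.0164, 50)
  rt <- radiation_schedule(c(9, 10, 11), 8, alpha = 0.3, beta = 0.03)
  eff <- combined_log_effect(gp, rt, t0 = 0, t = 15)
  # discounted sum of per-fraction log-kills (oracle-computed)
  expect_equal(eff$D_nf, sum(4.32 * exp(-0.0164 * (15 - c(9, 10, 11)))),
               tolerance = 1e-12)
  expect_equal(eff$D_nf, 11.94076, tolerance = 1e-6)
  expect_equal(log(eff$N_t), recursive_course_logN(gp, rt, 0, 15),
               tolerance = 1e-10)
  # single fraction evaluated at its own time: D_nf is the undecayed kill
  rt1 <- radiation_schedule(10, 6, alpha = 0.2, beta = 0.02)
  eff1 <- combined_log_effect(gp, rt1, t0 = 0, t = 10)
  expect_equal(eff1$D_nf, 0.2 * 6 + 0.02 * 36)
  # no fractions, no drug: pure growth term
  eff0 <- combined_log_effect(gp, t0 = 0, t = 15)
  expect_equal(eff0$D_nf, 0)
  expect_equal(eff0$W_bar, 0)
  expect_equal(eff0$N_t, gompertz_size(gp, 15), tolerance = 1e-12)
  expect_error(combined_log_effect(gp, rt, t0 = 0, t = 10), "within")
})

test_that("closed-form course equals the recursive oracle over random schedules", {
  set.seed(21)
  for (i in 1:25) {
    gp <- draw_gp(1)[[1]]
    sched <- draw_schedule(0, 30)
    t_eval <- 30
    eff <- combined_log_effect(gp, sched, t0 = 0, t = t_eval)
    expect_lt(abs(log(eff$N_t) - recursive_course_logN(gp, sched, 0, t_eval)), 1e-8)
  }
})

test_that("W_bar closed forms agree with numerical quadrature", {
  gp <- gompertz_params(0.06, 0.03, 10)
  for (it in list(immunotherapy_profile(0.04, 1.5, 0),
                  immunotherapy_profile(0.04, 1.5, 0.12))) {
    t <- 18
    Ifun <- function(s) it$I0 * exp(-it$rho * s)
    quad <- it$gamma * stats::integrate(function(s) exp(-gp$k * (t - s)) * Ifun(s),
                                        0, t, rel.tol = 1e-12)$value
    eff <- combined_log_effect(gp, it = it, t0 = 0, t = t)
    expect_lt(abs(eff$W_bar - quad), 1e-8)
  }
})

test_that("regression condition reads the sign of the log-change margin", {
  gp <- gompertz_params(0.054, 0.0164, 50)
  # no therapy below carrying capacity: growing
  eff0 <- combined_log_effect(gp, t0 = 0, t = 10)
  rc0 <- regression_condition(eff0)
  expect_false(rc0$is_regressing)
  expect_gt(rc0$margin, 0)
  # heavy RT: regressing
  rt <- radiation_schedule(c(9, 10, 11), 8, alpha = 0.3, beta = 0.03)
  rc1 <- regression_condition(combined_log_effect(gp, rt, t0 = 0, t = 15))
  expect_true(rc1$is_regressing)
  # near-critical: growth term ~ D_nf, a small W_bar tips the balance
  eff <- combined_log_effect(gp, t0 = 0, t = 20)
  crit <- eff$growth_term
  eff_c <- eff
  eff_c$D_nf <- crit; eff_c$W_bar <- 0.01
  rc2 <- regression_condition(eff_c)
  expect_true(rc2$is_regressing)
  expect_equal(rc2$margin, -0.01)
  expect_true(rc2$near_critical)
})

test_that("abscopal model reduces to untreated growth without coupling", {
  gp <- gompertz_params(0.054, 0.0164, 50)
  rt <- radiation_schedule(c(9, 10, 11), 8, alpha = 0.3, beta = 0.03)
  grid <- 0:40
  un <- gompertz_size(gp, grid)
  for (syn in list(synergy_params(delta = 0, tau = 5, lag = 3, Y0 = 0.1, t_in = 9),
                   synergy_params(delta = 1, tau = 5, lag = 3, Y0 = 0, t_in = 9))) {
    tr <- abscopal_trajectory(gp, syn, rt, grid)
    expect_lt(max(abs(tr$sizes - un) / un), 1e-8)
  }
  expect_error(abscopal_trajectory(gp, synergy_params(1, 5, 3, 0.1, 9),
                                   radiation_schedule(numeric(0), numeric(0), 0.3),
                                   grid),
               "fraction")
})

test_that("abscopal trajectories are continuous, lag-respecting and ordered in the coupling", {
  gp <- gompertz_params(0.054, 0.0164, 50)
  rt <- radiation_schedule(c(9, 10, 11), 8, alpha = 0.3, beta = 0.03)
  grid <- seq(0, 40, by = 0.5)
  un <- gompertz_size(gp, grid)
  syn_a <- synergy_params(delta = 1, tau = 5, lag = 3, Y0 = 0.05, t_in = 9)
  syn_b <- synergy_params(delta = 1, tau = 5, lag = 3, Y0 = 0.15, t_in = 9)
  tr_a <- abscopal_trajectory(gp, syn_a, rt, grid)
  tr_b <- abscopal_trajectory(gp, syn_b, rt, grid)
  # untreated until the first fraction's effect onset (day 9 + lag 3)
  pre <- grid <= 12
  expect_lt(max(abs(tr_a$sizes[pre] - un[pre]) / un[pre]), 1e-8)
  # stronger coupling, pointwise smaller metastasis afterwards
  expect_true(all(tr_b$sizes[!pre] <= tr_a$sizes[!pre]))
  # no instantaneous kills: largest log step bounded by rate * dt
  expect_lt(max(abs(diff(log(tr_b$sizes)))), 0.5)
})

test_that("final metastatic size is non-increasing in Y0, delta and tau", {
  gp <- gompertz_params(0.054, 0.0164, 50)
  rt <- radiation_schedule(c(9, 10, 11), 8, alpha = 0.3, beta = 0.03)
  grid <- 0:40
  base <- list(delta = 1, tau = 5, lag = 3, Y0 = 0.05, t_in = 9)
  final_size <- function(p) {
    syn <- synergy_params(p$delta, p$tau, p$lag, p$Y0, p$t_in)
    tail(abscopal_trajectory(gp, syn, rt, grid)$sizes, 1)
  }
  for (knob in c("Y0", "delta", "tau")) {
    lo <- base; hi <- base
    hi[[knob]] <- base[[knob]] * 2
    expect_lte(final_size(hi), final_size(lo))
  }
})
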