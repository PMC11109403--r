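# Synthetic trajectories and multi-arm study designs with the statistical
# structure the analysis layer assumes: Gompertz growth plus therapy
# effects, under multiplicative-lognormal or additive-Gaussian
# measurement noise. Packaged fixture designs emulate an antibody
# dose-arm study and a fractionated-RT + abscopal study.

#' Measurement-noise model
#'
#' @param kind `"multiplicative_lognormal"` (sd is the standard deviation
#'   of log sizes, i.e. the relative error) or `"additive_gaussian"`
#'   (sd in size units, for diameter-like data).
#' @param sd Noise magnitude, `>= 0`. The default 5% relative error is a
#'   realistic scale for caliper/imaging tumor measurements.
#' @param seed Optional integer; fixes the noise stream of
#'   [generate_trajectory()] so that the same seed reproduces the same
#'   trajectory bit for bit.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative_lognormal", "additive_gaussian"),
                        sd = 0.05, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(sd), length(sd) == 1L, sd >= 0)
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(kind = kind, sd = sd, seed = seed), class = "noise_model")
}

# deterministic model sizes for one subject under a therapy course
.model_sizes <- function(gp, course, days) {
  if (is.null(course)) return(gompertz_size(gp, days))
  stopifnot(inherits(course, "therapy_course"))
  if (!is.null(course$synergy)) {
    if (is.null(course$rt)) stop("a synergy course requires an rt schedule")
    return(abscopal_trajectory(gp, course$synergy, course$rt, days)$sizes)
  }
  u <- log(gp$N0) + gp$a * vapply(days, function(d) .gk(gp$k, d), numeric(1)) -
    .it_w(course$it, gp$k, days)
  if (!is.null(course$rt) && length(course$rt$times)) {
    kills <- .log_kills(course$rt)
    u <- u - vapply(days, function(d) {
      on <- course$rt$times <= d
      if (!any(on)) 0 else
        sum(kills[on] * exp(-gp$k * (d - course$rt$times[on])))
    }, numeric(1))
  }
  exp(u)
}

#' Generate one noisy synthetic trajectory
#'
#' Evaluates the model implied by the growth parameters and (optional)
#' therapy course at the requested days, then applies measurement noise.
#' Zero-sd noise reproduces the model exactly; the same seed reproduces
#' the same trajectory.
#'
#' @param gp A [gompertz_params()] object.
#' @param course Optional [therapy_course()].
#' @param days Strictly increasing observation days.
#' @param noise A [noise_model()].
#' @param seed Integer seed; defaults to `noise$seed`. `NULL` draws from
#'   the current RNG state.
#' @param subject_id,arm Labels carried into the trajectory.
#' @return A [tumor_trajectory()].
#' @examples
#' gp <- gompertz_params(0.049, 0.011, 100)
#' generate_trajectory(gp, days = seq(0, 40, 2),
#'                     noise = noise_model(sd = 0.05, seed = 1))
#' @export
generate_trajectory <- function(gp, course = NULL, days,
                                noise = noise_model(), seed = noise$seed,
                                subject_id = "s1", arm = "") {
  stopifnot(inherits(gp, "gompertz_params"), is.numeric(days),
            inherits(noise, "noise_model"))
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  sizes <- .model_sizes(gp, course, days)
  if (noise$sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    n <- length(sizes)
    if (noise$kind == "multiplicative_lognormal") {
      sizes <- sizes * exp(stats::rnorm(n, 0, noise$sd))
    } else {
      noisy <- sizes + stats::rnorm(n, 0, noise$sd)
      bad <- noisy <= 0
      if (any(bad)) {
        # floor: additive noise must not produce non-positive sizes
        noisy[bad] <- 1e-6 * sizes[bad]
        message(sprintf("floored %d non-positive noisy size(s)", sum(bad)))
      }
      sizes <- noisy
    }
  }
  tumor_trajectory(days, sizes, subject_id = subject_id, arm = arm,
                   unit = gp$unit)
}

#' Multi-arm study design
#'
#' @param arms A list of arms, each a list with elements `label`,
#'   `gp` ([gompertz_params()]), optional `course` ([therapy_course()]),
#'   `n_subjects` (`>= 1`), `days` (strictly increasing observation days)
#'   and optional `seed` (integer; arms with their own seed are
#'   bit-reproducible independently of the other arms).
#' @param noise A [noise_model()] shared by all arms.
#' @return An object of class `study_design`.
#' @export
study_design <- function(arms, noise = noise_model()) {
  stopifnot(is.list(arms), length(arms) >= 1L,
            inherits(noise, "noise_model"))
  for (arm in arms) {
    stopifnot(is.list(arm), !is.null(arm$label),
              inherits(arm$gp, "gompertz_params"),
              is.numeric(arm$days), arm$n_subjects >= 1)
    if (any(diff(arm$days) <= 0))
      stop(sprintf("arm '%s': days must be strictly increasing", arm$label))
  }
  structure(list(arms = arms, noise = noise), class = "study_design")
}

#' Generate a multi-arm synthetic study
#'
#' Per-arm, per-subject trajectories with independent noise. Each subject
#' gets the deterministic seed `arm_seed + subject_index`, where
#' `arm_seed` is the arm's own seed if given, else
#' `base_seed + 1000 * arm_index`; changing one arm's seed therefore
#' leaves every other arm bit-identical.
#'
#' @param design A [study_design()].
#' @param base_seed Integer base seed.
#' @return A long-format data frame with columns `subject_id`, `arm`,
#'   `time_days`, `size`, `unit` (the CSV interchange schema).
#' @export
generate_study <- function(design, base_seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  out <- list()
  for (i in seq_along(design$arms)) {
    arm <- design$arms[[i]]
    arm_seed <- if (!is.null(arm$seed)) arm$seed else base_seed + 1000L * i
    for (s in seq_len(arm$n_subjects)) {
      tr <- generate_trajectory(arm$gp, arm$course, arm$days,
                                noise = design$noise,
                                seed = arm_seed + s,
                                subject_id = sprintf("%s_%02d", arm$label, s),
                                arm = arm$label)
      out[[length(out) + 1L]] <- as.data.frame(tr)
    }
  }
  do.call(rbind, out)
}

#' Antibody-study fixture design
#'
#' Five arms emulating an autoantibody dose study in tumor-bearing mice:
#' untreated Gompertz growth plus two agonist arms (negative
#' immunotherapy coupling, faster growth) and two antagonist arms
#' (positive coupling, suppressed growth) at two dose levels each.
#' Untreated parameters a = 0.049, k = 0.011 day^-1; observations every
#' 2 days over days 0-40.
#'
#' @param n_subjects Subjects per arm.
#' @param noise A [noise_model()].
#' @return A [study_design()].
#' @export
design_antibody_like <- function(n_subjects = 8L, noise = noise_model()) {
  gp <- gompertz_params(a = 0.049, k = 0.011, N0 = 100, unit = "mm^3")
  days <- seq(0, 40, by = 2)
  it_arm <- function(gI0) therapy_course(
    it = immunotherapy_profile(gamma = gI0, I0 = 1, rho = 0))
  arms <- list(
    list(label = "untreated", gp = gp, course = NULL,
         n_subjects = n_subjects, days = days),
    list(label = "agonist_lo", gp = gp, course = it_arm(-0.010),
         n_subjects = n_subjects, days = days),
    list(label = "agonist_hi", gp = gp, course = it_arm(-0.020),
         n_subjects = n_subjects, days = days),
    list(label = "antagonist_lo", gp = gp, course = it_arm(0.020),
         n_subjects = n_subjects, days = days),
    list(label = "antagonist_hi", gp = gp, course = it_arm(0.035),
         n_subjects = n_subjects, days = days))
  study_design(arms, noise)
}

#' Fractionated-RT + abscopal fixture design
#'
#' Emulates a fibrosarcoma-like radiotherapy study: a primary tumor arm
#' left untreated, arms receiving one or three 8 Gy fractions (days 9 and
#' 9-11 respectively, alpha = 0.3 Gy^-1, beta = alpha/10), and an
#' unirradiated metastasis arm driven by the RT-triggered immune response
#' (synergy pulses after each fraction of the 3-fraction course).
#' Untreated parameters a = 0.054, k = 0.0164 day^-1; daily observations
#' over days 0-25.
#'
#' @param n_subjects Subjects per arm.
#' @param noise A [noise_model()].
#' @param Y0 Immune-pulse amplitude for the metastasis arm.
#' @return A [study_design()].
#' @export
design_rt_abscopal_like <- function(n_subjects = 8L, noise = noise_model(),
                                    Y0 = 0.1) {
  gp <- gompertz_params(a = 0.054, k = 0.0164, N0 = 50, unit = "mm^3")
  days <- 0:25
  rt3 <- radiation_schedule(c(9, 10, 11), 8, alpha = 0.3, beta = 0.03)
  rt1 <- radiation_schedule(9, 8, alpha = 0.3, beta = 0.03)
  syn <- synergy_params(delta = 1, tau = 5, lag = 3, Y0 = Y0, t_in = 9)
  arms <- list(
    list(label = "untreated", gp = gp, course = NULL,
         n_subjects = n_subjects, days = days),
    list(label = "rt_1x8Gy", gp = gp, course = therapy_course(rt = rt1),
         n_subjects = n_subjects, days = days),
    list(label = "rt_3x8Gy", gp = gp, course = therapy_course(rt = rt3),
         n_subjects = n_subjects, days = days),
    list(label = "metastasis", gp = gp,
         course = therapy_course(rt = rt3, synergy = syn),
         n_subjects = n_subjects, days = days))
  study_design(arms, noise)
}
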