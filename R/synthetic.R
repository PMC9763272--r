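# Synthetic cohort generator.
#
# Emulates a 66-patient subacute-stroke cohort treated with planar
# end-effector robot therapy: per-patient demographics, admission (T1)
# Motricity Index sub-items, four center-out reaching trajectories with
# prescribed path error and speed, and discharge (T2) outcomes generated
# from the configured linear relation on standardized MPE_C and snapped
# to the discrete clinical score set.

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study conditions: 66 patients, demographics with
#' the cohort's marginals (age 64.97 +/- 12.75 y, 66.7% male, 59.1%
#' right-affected, onset 15.27 +/- 18.07 days, 71.2% ischemic), 200 Hz
#' sampling, 0.14 m center-out targets, and discharge-outcome
#' coefficients equal to the published single-predictor models
#' (intercept, slope on standardized MPE_C):
#' elbow 12.99/-4.89, shoulder 13.70/-4.26, total upper limb 32.50/-11.99.
#'
#' @param n_patients Cohort size (>= 2; standardization needs 2).
#' @param target_distance Center-to-peripheral-target distance (m).
#' @param sample_rate Trajectory sampling rate (Hz, > 0).
#' @param outcome_coefficients Named list `ELBOW`/`SHOULDER`/`UL`, each
#'   `c(intercept, slope)` in score points (slope per SD of MPE_C).
#' @param noise_sd Named numeric: Gaussian outcome noise SD (points) per
#'   outcome.  Defaults give signal-to-noise matching the
#'   explained-variance levels the models are reported to reach.
#' @param demographics List of marginals: `age_mean`, `age_sd`,
#'   `age_range`, `prop_male`, `prop_right`, `onset_mean`, `onset_sd`,
#'   `prop_ischemic`.
#' @param mpe_profile Per-direction `c(base, gain, sd)` (m): raw MPE =
#'   base + gain * latent impairment + Gaussian noise, floored at 0.
#'   Direction C has the steepest gain (flexor-synergy direction).
#' @param ms_profile `c(base, gain, sd, floor)` (m/s) for the mean speed
#'   of direction B; gain is negative (impaired patients move slower).
#' @param class_noise Probability that a T1 sub-item is misclassified by
#'   one class (therapist scoring noise).
#' @param n_repetitions Movement repetitions per direction.
#' @param trajectories Logical: synthesize trajectory samples (TRUE) or
#'   only the per-patient metric values (faster, for large simulation
#'   studies).
#' @param seed Integer seed; fully determines the generated cohort.
#' @return An object of class `rmk_generator_config`.
#' @export
generator_config <- function(
    n_patients = 66L,
    target_distance = 0.14,
    sample_rate = 200,
    outcome_coefficients = list(ELBOW = c(12.99, -4.89),
                                SHOULDER = c(13.70, -4.26),
                                UL = c(32.50, -11.99)),
    noise_sd = c(ELBOW = 3.4, SHOULDER = 3.5, UL = 6.9),
    demographics = list(age_mean = 64.97, age_sd = 12.75,
                        age_range = c(18, 80), prop_male = 0.667,
                        prop_right = 0.591, onset_mean = 15.27,
                        onset_sd = 18.07, prop_ischemic = 0.712),
    mpe_profile = list(A = c(base = 0.004, gain = 0.030, sd = 0.008),
                       B = c(base = 0.004, gain = 0.030, sd = 0.008),
                       C = c(base = 0.005, gain = 0.040, sd = 0.006),
                       D = c(base = 0.004, gain = 0.030, sd = 0.008)),
    ms_profile = c(base = 0.35, gain = -0.25, sd = 0.03, floor = 0.02),
    class_noise = 0.1,
    n_repetitions = 1L,
    trajectories = TRUE,
    seed = 1L) {
  if (n_patients < 2L) stop("n_patients must be >= 2 (standardization undefined below that)")
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  if (target_distance <= 0) stop("target_distance must be > 0")
  outcomes <- c("ELBOW", "SHOULDER", "UL")
  if (!all(outcomes %in% names(outcome_coefficients))) {
    stop("outcome_coefficients must name ELBOW, SHOULDER and UL")
  }
  if (!all(outcomes %in% names(noise_sd))) {
    stop("noise_sd must name ELBOW, SHOULDER and UL")
  }
  if (class_noise < 0 || class_noise > 1) stop("class_noise must be in [0, 1]")
  structure(
    list(n_patients = as.integer(n_patients),
         target_distance = target_distance, sample_rate = sample_rate,
         outcome_coefficients = outcome_coefficients, noise_sd = noise_sd,
         demographics = demographics, mpe_profile = mpe_profile,
         ms_profile = ms_profile, class_noise = class_noise,
         n_repetitions = as.integer(n_repetitions),
         trajectories = isTRUE(trajectories), seed = as.integer(seed)),
    class = "rmk_generator_config"
  )
}

# Minimum-jerk position fraction and its derivative on tau in [0, 1].
min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
min_jerk_deriv <- function(tau) 30 * tau^2 * (1 - tau)^2

# Unit movement axis (lesion frame) and its perpendicular per direction.
direction_axis <- function(direction) {
  u <- switch(direction,
              A = c(0, 1), B = c(-1, 0), C = c(0, -1), D = c(1, 0))
  list(u = u, p = c(u[2], -u[1]))
}

#' Synthesize one point-to-point reaching movement
#'
#' Generates a center-out movement of the given direction whose extracted
#' kinematic metrics converge to prescribed values.  The path runs from
#' the central target (origin) to the peripheral target at the configured
#' distance; progress along the line follows a minimum-jerk profile, and
#' the lateral deviation is a half-sine in time of amplitude
#' `a = pi * target_mpe / 2`, so the mean absolute deviation (the MPE)
#' converges to `target_mpe` under uniform sampling.  The movement
#' duration is set to the path length (computed by numeric quadrature of
#' the speed profile) divided by `mean_speed`, so the extracted mean
#' speed converges to `mean_speed`.  Analytic velocities are emitted
#' alongside positions.  Given its arguments the movement is
#' deterministic; `seed` is accepted for interface uniformity.
#'
#' @param direction `"A"`, `"B"`, `"C"` or `"D"`.
#' @param target_mpe Prescribed movement path error (m, >= 0).
#' @param mean_speed Prescribed mean movement speed (m/s, > 0).
#' @param config A [generator_config()] (distance and sample rate used).
#' @param side Affected side; left-affected movements are emitted in the
#'   device frame (x mirrored), as a robot would record them.
#' @param seed Unused; present so all generator operations share one
#'   signature.
#' @return An [trajectory()] object with positions and velocities.
#' @export
generate_trajectory <- function(direction, target_mpe, mean_speed,
                                config = generator_config(), side = "right",
                                seed = NULL) {
  direction <- match.arg(direction, DIRECTIONS)
  side <- match.arg(side, c("left", "right"))
  if (target_mpe < 0) stop("target_mpe must be >= 0")
  if (mean_speed <= 0) stop("mean_speed must be > 0")
  L <- config$target_distance
  a <- pi * target_mpe / 2
  speed_shape <- function(tau) {
    sqrt((L * min_jerk_deriv(tau))^2 + (a * pi * cos(pi * tau))^2)
  }
  path_len <- stats::integrate(speed_shape, 0, 1, rel.tol = 1e-10)$value
  duration <- path_len / mean_speed
  n <- as.integer(round(duration * config$sample_rate)) + 1L
  if (duration <= 0 || n < 2L) {
    stop("invalid parameters: non-positive duration or fewer than 2 samples")
  }
  tau <- seq(0, 1, length.out = n)
  ax <- direction_axis(direction)
  along <- L * min_jerk(tau)
  lateral <- a * sin(pi * tau)
  v_along <- (L / duration) * min_jerk_deriv(tau)
  v_lateral <- (a * pi / duration) * cos(pi * tau)
  x <- along * ax$u[1] + lateral * ax$p[1]
  y <- along * ax$u[2] + lateral * ax$p[2]
  vx <- v_along * ax$u[1] + v_lateral * ax$p[1]
  vy <- v_along * ax$u[2] + v_lateral * ax$p[2]
  if (side == "left") {  # device frame: mirror of the lesion frame
    x <- -x
    vx <- -vx
  }
  trajectory(t = tau * duration, x = x, y = y, vx = vx, vy = vy,
             direction = direction, side = side,
             sample_rate = config$sample_rate)
}

# Map latent impairment (0 best .. 1 worst) to one of the six sub-item
# classes by uniform quantile binning, with optional one-class
# misclassification noise.
impairment_to_class <- function(latent, classes, class_noise) {
  idx <- min(length(classes), floor((1 - latent) * length(classes)) + 1L)
  if (class_noise > 0 && stats::runif(1) < class_noise) {
    idx <- idx + sample(c(-1L, 1L), 1L)
    idx <- max(1L, min(length(classes), idx))
  }
  classes[idx]
}

#' Generate one synthetic patient
#'
#' Draws demographics from the configured marginals and maps a latent
#' impairment score (0 = unimpaired end of the cohort, 1 = most impaired)
#' to admission Motricity Index sub-items (monotone decreasing in
#' impairment, with optional misclassification noise) and raw kinematic
#' metrics (path errors increasing, speed decreasing in impairment).
#' Trajectories realizing the patient's metric values are synthesized
#' for all four directions.  Discharge outcomes are *not* set here: they
#' depend on cohort-level standardization of MPE_C, so
#' [generate_cohort()] adds them.
#'
#' @param latent_impairment Latent impairment in \[0, 1\].
#' @param config A [generator_config()].
#' @param seed Integer seed; the patient is a deterministic function of
#'   `(latent_impairment, config, seed)`.
#' @return List with `record` (one-row data.frame) and `trajectories`
#'   (named list A--D of repetition lists, or `NULL` when
#'   `config$trajectories` is `FALSE`).
#' @export
generate_patient <- function(latent_impairment, config = generator_config(),
                             seed = 1L) {
  if (latent_impairment < 0 || latent_impairment > 1) {
    stop("latent_impairment must be in [0, 1]")
  }
  set.seed(seed)
  dem <- config$demographics
  age <- min(dem$age_range[2],
             max(dem$age_range[1], stats::rnorm(1, dem$age_mean, dem$age_sd)))
  sex <- if (stats::runif(1) < dem$prop_male) "male" else "female"
  side <- if (stats::runif(1) < dem$prop_right) "right" else "left"
  onset <- max(1, stats::rnorm(1, dem$onset_mean, dem$onset_sd))
  etiology <- if (stats::runif(1) < dem$prop_ischemic) "ischemic" else "hemorrhagic"

  classes <- mi_scale("ELBOW")$valid
  elbow <- impairment_to_class(latent_impairment, classes, config$class_noise)
  shoulder <- impairment_to_class(latent_impairment, classes, config$class_noise)
  # pinch is never modelled (robot therapy trains elbow/shoulder); it is
  # drawn only so the T1 total can be composed with the +1 rule
  pinch <- impairment_to_class(latent_impairment, classes, config$class_noise)

  mpe <- vapply(DIRECTIONS, function(d) {
    pr <- config$mpe_profile[[d]]
    max(0, pr[["base"]] + pr[["gain"]] * latent_impairment +
          stats::rnorm(1, 0, pr[["sd"]]))
  }, numeric(1))
  ms <- config$ms_profile
  ms_b <- max(ms[["floor"]],
              ms[["base"]] + ms[["gain"]] * latent_impairment +
                stats::rnorm(1, 0, ms[["sd"]]))

  record <- data.frame(
    id = NA_character_, age = age, sex = sex, side = side, onset = onset,
    etiology = etiology, latent = latent_impairment,
    MPE_A = mpe[["A"]], MPE_C = mpe[["C"]], MPE_D = mpe[["D"]], MS_B = ms_b,
    MI_ELBOW_T1 = elbow, MI_SHOULDER_T1 = shoulder, MI_PINCH_T1 = pinch,
    MI_UL_T1 = mi_total(elbow, shoulder, pinch),
    stringsAsFactors = FALSE
  )

  trajs <- NULL
  if (config$trajectories) {
    trajs <- lapply(DIRECTIONS, function(d) {
      replicate(config$n_repetitions, simplify = FALSE,
                generate_trajectory(d, target_mpe = mpe[[d]],
                                    mean_speed = ms_b, config = config,
                                    side = side))
    })
    names(trajs) <- DIRECTIONS
  }
  list(record = record, trajectories = trajs)
}

#' Generate a full synthetic cohort
#'
#' Draws `n_patients` latent impairments uniformly, generates each
#' patient (see [generate_patient()]), standardizes the raw MPE_C values
#' across the cohort (mean 0, unit variance, n-1 denominator), and
#' generates each discharge outcome as
#' `intercept + slope * MPE_C_std + N(0, noise_sd)`, clamped to the scale
#' range and snapped to the nearest valid discrete score.  Everything is
#' a deterministic function of the config (including its seed).
#'
#' @param config A [generator_config()].
#' @return An object of class `rmk_cohort`: list with `patients` (one row
#'   per patient, demographics + T1 scores + raw kinematic metrics + T2
#'   outcomes), `trajectories` (per-patient named list, or `NULL`), and
#'   `config`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "rmk_generator_config"))
  n <- config$n_patients
  set.seed(config$seed)
  latents <- stats::runif(n)
  patient_seeds <- sample.int(.Machine$integer.max - 1L, n)
  noise_draws <- lapply(c("ELBOW", "SHOULDER", "UL"), function(o) {
    stats::rnorm(n, 0, config$noise_sd[[o]])
  })
  names(noise_draws) <- c("ELBOW", "SHOULDER", "UL")

  patients <- vector("list", n)
  trajectories <- vector("list", n)
  ids <- sprintf("P%03d", seq_len(n))
  for (i in seq_len(n)) {
    p <- generate_patient(latents[i], config, seed = patient_seeds[i])
    p$record$id <- ids[i]
    patients[[i]] <- p$record
    if (config$trajectories) trajectories[[i]] <- p$trajectories
  }
  patients <- do.call(rbind, patients)
  names(trajectories) <- ids

  z <- standardize(patients$MPE_C)$values
  patients$MPE_C_std <- z
  for (o in c("ELBOW", "SHOULDER", "UL")) {
    scale <- mi_scale(o)
    b <- config$outcome_coefficients[[o]]
    pre <- b[[1]] + b[[2]] * z + noise_draws[[o]]
    pre <- pmin(scale$max, pmax(scale$min, pre))
    patients[[paste0("MI_", o, "_T2")]] <- nearest_valid_score(pre, scale)
  }

  structure(
    list(patients = patients,
         trajectories = if (config$trajectories) trajectories else NULL,
         config = config),
    class = "rmk_cohort"
  )
}

#' @export
print.rmk_cohort <- function(x, ...) {
  cat(sprintf("<rmk_cohort> %d patients, seed %d, trajectories: %s\n",
              nrow(x$patients), x$config$seed,
              if (is.null(x$trajectories)) "no" else "yes"))
  invisible(x)
}
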