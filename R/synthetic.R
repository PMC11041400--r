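#' Signal-model parameters for one activity
#'
#' The generated accelerometer signal for an activity is
#' `g * gravity_orientation` plus a small harmonic series at multiples of
#' the step frequency (per-axis weights, per-axis random phases), a slow
#' random-walk drift and white Gaussian noise; the gyroscope signal is
#' the analogous zero-mean series. Static activities (sitting, standing)
#' have `step_frequency` 0 and amplitude 0, so they reduce to a rotated
#' gravity vector plus noise.
#'
#' @param gravity_orientation unit 3-vector: device-frame direction of
#'   gravity while performing the activity.
#' @param step_frequency fundamental gait frequency in Hz (0 = static).
#' @param accel_amplitude scalar harmonic amplitude, m/s^2.
#' @param accel_axis_weights per-axis weights of the harmonic series
#'   (signed; a negative vertical weight skews the waveform downward).
#' @param gyro_amplitude scalar rotation-rate amplitude, rad/s.
#' @param gyro_axis_weights per-axis gyroscope weights.
#' @param harmonic_weights weights of the fundamental and overtones
#'   (sum <= 1).
#' @param noise_accel_sd,noise_gyro_sd white-noise standard deviations
#'   (m/s^2, rad/s).
#' @param drift_sd slow-wander magnitude (random-walk innovation sd per
#'   sqrt(second), m/s^2; the gyroscope drift is a tenth of it).
#' @return An `activity_model_params` object.
#' @export
activity_model_params <- function(gravity_orientation = c(0, 1, 0),
                                  step_frequency = 0,
                                  accel_amplitude = 0,
                                  accel_axis_weights = c(0.5, 1, 0.4),
                                  gyro_amplitude = 0,
                                  gyro_axis_weights = c(1, 0.6, 0.8),
                                  harmonic_weights = c(0.6, 0.3, 0.1),
                                  noise_accel_sd = 0.4,
                                  noise_gyro_sd = 0.05,
                                  drift_sd = 0.05) {
  nrm <- sqrt(sum(gravity_orientation^2))
  if (abs(nrm - 1) > 1e-8) {
    if (nrm == 0) stop("gravity_orientation must be a unit vector",
                       call. = FALSE)
    gravity_orientation <- gravity_orientation / nrm
  }
  if (sum(harmonic_weights) > 1 + 1e-8) {
    stop("harmonic_weights must sum to at most 1", call. = FALSE)
  }
  if (accel_amplitude < 0 || gyro_amplitude < 0 || noise_accel_sd < 0 ||
      noise_gyro_sd < 0 || drift_sd < 0) {
    stop("amplitudes and noise magnitudes must be non-negative",
         call. = FALSE)
  }
  structure(list(gravity_orientation = gravity_orientation,
                 step_frequency = step_frequency,
                 accel_amplitude = accel_amplitude,
                 accel_axis_weights = accel_axis_weights,
                 gyro_amplitude = gyro_amplitude,
                 gyro_axis_weights = gyro_axis_weights,
                 harmonic_weights = harmonic_weights,
                 noise_accel_sd = noise_accel_sd,
                 noise_gyro_sd = noise_gyro_sd,
                 drift_sd = drift_sd),
            class = "activity_model_params")
}

unit3 <- function(v) v / sqrt(sum(v^2))

#' Default per-activity domain parameters
#'
#' The stated world of the generator: walking at 1.9 Hz / 3 m/s^2,
#' jogging at 2.8 Hz / 8 m/s^2, upstairs at 1.5 Hz / 4 m/s^2 with an
#' enlarged vertical-axis weight, downstairs at 1.7 Hz / 5 m/s^2 with a
#' negative vertical skew; sitting and standing are static with distinct
#' gravity orientations (device tilted ~60 degrees while seated;
#' top-down trouser-pocket orientation while upright). Noise is
#' 0.4 m/s^2 / 0.05 rad/s throughout.
#'
#' @param g gravitational constant, m/s^2 (default 9.81).
#' @param rotation proper 3x3 rotation applied to all signals (phone
#'   orientation; default identity).
#' @return A `domain_params` object: per-activity
#'   [activity_model_params()], `g` and `rotation`.
#' @export
default_domain_params <- function(g = 9.81, rotation = diag(3)) {
  pocket <- c(0, 1, 0)                      # top-down pocket, upright
  acts <- list(
    dws = activity_model_params(unit3(c(0, 0.94, -0.34)), 1.7, 5,
                                accel_axis_weights = c(0.4, -1.3, 0.5),
                                gyro_amplitude = 1.2),
    jog = activity_model_params(unit3(c(0.20, 0.95, 0.15)), 2.8, 8,
                                accel_axis_weights = c(0.6, 1, 0.5),
                                gyro_amplitude = 1.5),
    sit = activity_model_params(unit3(c(0, 0.5, sqrt(3) / 2))),  # ~60 deg
    std = activity_model_params(pocket),
    ups = activity_model_params(unit3(c(0, 0.94, 0.34)), 1.5, 4,
                                accel_axis_weights = c(0.4, 1.3, 0.5),
                                gyro_amplitude = 1.0),
    wlk = activity_model_params(unit3(c(0.15, 0.98, 0.10)), 1.9, 3,
                                accel_axis_weights = c(0.5, 1, 0.4),
                                gyro_amplitude = 0.8))
  domain_params(acts, g = g, rotation = rotation)
}

#' @rdname default_domain_params
#' @param activities named list of [activity_model_params()], one per
#'   activity code.
#' @export
domain_params <- function(activities, g = 9.81, rotation = diag(3)) {
  stopifnot(setequal(names(activities), activity_codes()))
  if (g <= 0) stop("g must be positive", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8) {
    stop("rotation must be a proper rotation matrix", call. = FALSE)
  }
  structure(list(activities = activities[activity_codes()], g = g,
                 rotation = rotation),
            class = "domain_params")
}

#' The default ~300 s activity course
#'
#' Walking, jogging, sitting, ascending stairs, standing, descending
#' stairs, in that order, totalling 300 seconds.
#'
#' @return A data.frame with columns `label` and `duration` (seconds).
#' @export
course_plan <- function() {
  plan <- data.frame(label = c("wlk", "jog", "sit", "ups", "std", "dws"),
                     duration = c(70, 50, 50, 45, 45, 40),
                     stringsAsFactors = FALSE)
  class(plan) <- c("course_plan", "data.frame")
  plan
}

#' Generate one activity segment
#'
#' Uses R's global RNG (per-axis harmonic phases, drift and noise); seed
#' with `set.seed()` or wrap in `withr::with_seed()` for determinism.
#' The domain rotation is *not* applied here; [synth_recording()] rotates
#' the assembled signal.
#'
#' @param label activity code (for validation only).
#' @param duration segment length in seconds (> 0).
#' @param rate sampling rate in Hz (> 0).
#' @param params an [activity_model_params()].
#' @param g gravitational constant, m/s^2.
#' @return Numeric 6 x round(duration*rate) matrix in the default
#'   channel order.
#' @export
synth_activity_segment <- function(label, duration, rate, params,
                                   g = 9.81) {
  as_activity_code(label)
  if (duration <= 0 || rate <= 0) {
    stop("duration and rate must be positive", call. = FALSE)
  }
  n <- as.integer(round(duration * rate))
  t <- (seq_len(n) - 1) / rate
  out <- matrix(0, 6, n)
  hw <- params$harmonic_weights
  for (ax in 1:3) {
    acc <- rep(g * params$gravity_orientation[ax], n)
    gyr <- numeric(n)
    if (params$step_frequency > 0) {
      for (k in seq_along(hw)) {
        f <- k * params$step_frequency
        acc <- acc + hw[k] * params$accel_amplitude *
          params$accel_axis_weights[ax] *
          sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
        gyr <- gyr + hw[k] * params$gyro_amplitude *
          params$gyro_axis_weights[ax] *
          sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
      }
    }
    if (params$drift_sd > 0) {
      acc <- acc + cumsum(stats::rnorm(n, 0, params$drift_sd / sqrt(rate)))
      gyr <- gyr + cumsum(stats::rnorm(n, 0, 0.1 * params$drift_sd / sqrt(rate)))
    }
    if (params$noise_accel_sd > 0) {
      acc <- acc + stats::rnorm(n, 0, params$noise_accel_sd)
    }
    if (params$noise_gyro_sd > 0) {
      gyr <- gyr + stats::rnorm(n, 0, params$noise_gyro_sd)
    }
    out[ax, ] <- acc
    out[ax + 3, ] <- gyr
  }
  rownames(out) <- default_channels()$name
  out
}

#' Synthesize one labeled course recording
#'
#' Concatenates per-activity segments in plan order with a short linear
#' cross-fade (0.5 s) at activity boundaries, applies the domain's phone
#' orientation rotation to the accelerometer and gyroscope triples, and
#' attaches label spans exactly matching the plan intervals.
#'
#' @param plan a [course_plan()]-style data.frame.
#' @param domain a [domain_params()].
#' @param rate sampling rate in Hz (default 50).
#' @param participant_id participant identifier.
#' @param seed integer seed; the same seed reproduces the recording
#'   exactly.
#' @param crossfade cross-fade length in seconds (default 0.5).
#' @return A labeled [recording()] of `round(sum(duration) * rate)`
#'   samples.
#' @export
synth_recording <- function(plan, domain, rate = 50,
                            participant_id = "p1", seed = 1L,
                            crossfade = 0.5) {
  stopifnot(is.data.frame(plan), all(plan$duration > 0))
  segs <- withr::with_seed(seed, lapply(seq_len(nrow(plan)), function(i) {
    synth_activity_segment(plan$label[i], plan$duration[i], rate,
                           domain$activities[[plan$label[i]]], g = domain$g)
  }))
  nf <- as.integer(round(crossfade * rate))
  for (i in seq_along(segs)[-1]) {
    L <- ncol(segs[[i]])
    k <- min(nf, L)
    if (k > 0) {
      w <- matrix(seq_len(k) / k, 6, k, byrow = TRUE)
      anchor <- segs[[i - 1]][, ncol(segs[[i - 1]])]
      segs[[i]][, seq_len(k)] <-
        (1 - w) * anchor + w * segs[[i]][, seq_len(k), drop = FALSE]
    }
  }
  mat <- do.call(cbind, segs)
  mat[1:3, ] <- domain$rotation %*% mat[1:3, ]
  mat[4:6, ] <- domain$rotation %*% mat[4:6, ]
  # span boundaries from the realized segment lengths, so that rounding
  # of duration * rate can never push a span past the recording extent
  ends <- cumsum(vapply(segs, ncol, integer(1))) / rate
  spans <- label_spans(start = c(0, ends[-length(ends)]), end = ends,
                       label = plan$label)
  recording(mat, sampling_rate = rate, participant_id = participant_id,
            t0 = 0, label_spans = spans)
}

#' Synthesize a windowed multi-participant dataset
#'
#' Generates one course recording per participant with small seeded
#' participant-level jitter (step frequencies multiplied by a factor in
#' [0.92, 1.08], amplitudes in [0.85, 1.15]) and windows them with the
#' default segmentation (128-sample windows, 50% overlap, pure label
#' policy). All six classes are present under the default plan.
#'
#' @param n_participants number of participants (>= 1).
#' @param domain a [domain_params()] (default [default_domain_params()]).
#' @param plan a [course_plan()]-style data.frame.
#' @param rate sampling rate in Hz.
#' @param seed integer master seed (participant seeds derive from it).
#' @param id dataset identifier.
#' @param window_len,step segmentation parameters.
#' @return A `har_dataset`; the per-participant jittered domains are
#'   attached as attribute `"participant_domains"`.
#' @export
synth_dataset <- function(n_participants, domain = default_domain_params(),
                          plan = course_plan(), rate = 50, seed = 1L,
                          id = "synthetic", window_len = 128L, step = 64L) {
  if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  jit <- participant_jitter(n_participants, seed)
  pdomains <- list()
  windows <- list()
  for (p in seq_len(n_participants)) {
    dom <- jitter_domain(domain, jit[[p]])
    pid <- sprintf("p%02d", p)
    pdomains[[pid]] <- dom
    rec <- synth_recording(plan, dom, rate = rate, participant_id = pid,
                           seed = jit[[p]]$rec_seed)
    windows <- c(windows, segment_windows(rec, window_len = window_len,
                                          step = step,
                                          label_policy = "pure"))
  }
  ds <- har_dataset(windows, id = id)
  attr(ds, "participant_domains") <- pdomains
  ds
}

#' Seeded per-participant jitter factors
#' @param n_participants count; seed master seed.
#' @return List of lists: `freq`, `amp` multipliers and `rec_seed`.
#' @keywords internal
participant_jitter <- function(n_participants, seed) {
  withr::with_seed(seed, lapply(seq_len(n_participants), function(p) {
    list(freq = stats::runif(1, 0.92, 1.08),
         amp = stats::runif(1, 0.85, 1.15),
         rec_seed = sample.int(.Machine$integer.max, 1))
  }))
}

#' Apply jitter multipliers to every activity of a domain
#' @keywords internal
jitter_domain <- function(domain, jit) {
  for (a in names(domain$activities)) {
    domain$activities[[a]]$step_frequency <-
      domain$activities[[a]]$step_frequency * jit$freq
    domain$activities[[a]]$accel_amplitude <-
      domain$activities[[a]]$accel_amplitude * jit$amp
    domain$activities[[a]]$gyro_amplitude <-
      domain$activities[[a]]$gyro_amplitude * jit$amp
  }
  domain
}

#' Controlled domain shift
#'
#' Returns a new domain emulating a different recording domain: the phone
#' orientation is rotated about a seeded random axis by
#' `severity * max_angle`, harmonic amplitudes are scaled by
#' `1 + 0.5 * severity` and step frequencies by `1 + 0.2 * severity`.
#' Severity 0 returns a domain equal to the base.
#'
#' @param base a [domain_params()].
#' @param severity shift severity in [0, 1].
#' @param seed integer seed for the rotation axis.
#' @param max_angle rotation at severity 1, radians (default pi/2, 90
#'   degrees).
#' @return A `domain_params` with a `$shift` record
#'   (`angle`, `amp_scale`, `freq_scale`).
#' @export
shifted_domain <- function(base, severity, seed = 1L, max_angle = pi / 2) {
  if (severity < 0 || severity > 1) {
    stop("severity must lie in [0, 1]", call. = FALSE)
  }
  axis <- withr::with_seed(seed, unit3(stats::rnorm(3)))
  angle <- severity * max_angle
  amp_scale <- 1 + 0.5 * severity
  freq_scale <- 1 + 0.2 * severity
  dom <- base
  dom$rotation <- rotation_about(axis, angle) %*% base$rotation
  for (a in names(dom$activities)) {
    dom$activities[[a]]$step_frequency <-
      dom$activities[[a]]$step_frequency * freq_scale
    dom$activities[[a]]$accel_amplitude <-
      dom$activities[[a]]$accel_amplitude * amp_scale
    dom$activities[[a]]$gyro_amplitude <-
      dom$activities[[a]]$gyro_amplitude * amp_scale
  }
  dom$shift <- list(angle = angle, amp_scale = amp_scale,
                    freq_scale = freq_scale, axis = axis)
  dom
}

#' Rodrigues rotation about a unit axis
#' @param axis unit 3-vector; angle radians.
#' @keywords internal
rotation_about <- function(axis, angle) {
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
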