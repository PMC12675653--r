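# Ground-truth-known session simulation.
#
# A session is n_trials x (bright period, dark period), each period split
# into a target-free adaptation phase and a fixation measurement phase.
# Measurement gaze is target + calibration bias (+ PSA shift in dark) plus
# isotropic AR(1) noise; blinks are a Poisson process that invalidates
# samples (NaN), optionally flanked by large excursions.

# AR(1) noise with stationary per-axis sd `sd_axis` and coefficient `phi`.
ar1_noise <- function(n, sd_axis, phi) {
  if (n == 0L) return(numeric(0))
  if (sd_axis == 0) return(rep(0, n))
  innov_sd <- sd_axis * sqrt(1 - phi^2)
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd_axis)
  if (n > 1) {
    w <- stats::rnorm(n - 1, 0, innov_sd)
    for (i in 2:n) e[i] <- phi * e[i - 1] + w[i - 1]
  }
  e
}

# AR(1) coefficient that realizes the requested RMS-S2S given the
# stationary dispersion. Per axis: E[(e_{t+1}-e_t)^2] = 2 sd_axis^2 (1-phi),
# and the two axes add in quadrature, so for isotropic noise
# RMS-S2S = 2 * sd_axis * sqrt(1 - phi) with sd_axis = noise_std / sqrt(2).
ar1_phi_for_s2s <- function(noise_std, s2s_noise) {
  if (is.null(s2s_noise)) return(0)
  sd_axis <- noise_std / sqrt(2)
  phi <- 1 - (s2s_noise / (2 * sd_axis))^2
  max(min(phi, 1 - 1e-9), -1 + 1e-9)
}

# Poisson blink process over n samples at `rate` Hz; returns a logical
# invalid mask and the list of blink index ranges.
blink_mask <- function(n, rate, blink_rate, blink_duration) {
  invalid <- rep(FALSE, n)
  spans <- list()
  if (blink_rate > 0 && blink_duration > 0 && n > 0) {
    dur <- n / rate
    k <- stats::rpois(1, blink_rate * dur)
    if (k > 0) {
      onsets <- sort(stats::runif(k, 0, dur))
      len <- max(1L, as.integer(round(blink_duration * rate)))
      for (on in onsets) {
        i0 <- as.integer(floor(on * rate)) + 1L
        i1 <- min(n, i0 + len - 1L)
        if (i0 <= n) {
          invalid[i0:i1] <- TRUE
          spans[[length(spans) + 1L]] <- c(i0, i1)
        }
      }
    }
  }
  list(invalid = invalid, spans = spans)
}

# Pupil diameter at time `tt` seconds within a period, approaching `target`
# from `from` with time constant `tau` seconds.
pupil_approach <- function(tt, from, target, tau = 1.0) {
  target + (from - target) * exp(-tt / tau)
}

#' Generate one ground-truth-known bright/dark session
#'
#' Produces one [gaze_recording()] per trial phase (adaptation and
#' measurement, bright and dark, for each trial) in degree space with the
#' target at the origin, plus a ground-truth record for testing. Bright
#' measurement samples are distributed around `bias_bright`; dark
#' measurement samples around `bias_bright + psa_shift`. Blink events
#' invalidate samples (coordinates and pupil set to NaN) without deleting
#' them, so per-phase sample counts always equal `round(duration * rate)`.
#'
#' @param device A [device_profile()].
#' @param participant A [participant_profile()].
#' @param schedule A [trial_schedule()].
#' @param seed Integer seed; identical inputs and seed reproduce the session
#'   bit-for-bit.
#' @return A list with elements `recordings` (list of `psaqc_gaze`, ordered
#'   trial-major: bright adaptation, bright measurement, dark adaptation,
#'   dark measurement) and `truth` (list: `true_gaze_angle`,
#'   `injected_shift`, `injected_loss_fraction`, `true_distance`, and
#'   per-recording bookkeeping `n_invalid`, `n_excursion`).
#' @export
generate_session <- function(device, participant, schedule, seed) {
  stopifnot(inherits(device, "psaqc_device"),
            inherits(participant, "psaqc_participant"),
            inherits(schedule, "psaqc_schedule"))
  rate <- device$sampling_rate
  phi <- ar1_phi_for_s2s(device$noise_std, device$s2s_noise)
  sd_axis <- device$noise_std / sqrt(2)
  excursion_amp <- 15   # degrees; well beyond the 10-degree distance filter
  excursion_len <- 2L   # samples on each side of a blink gap

  with_local_seed(seed, {
    recordings <- list()
    n_invalid <- integer(0)
    n_excursion <- integer(0)
    t0 <- 0
    for (trial in seq_len(schedule$n_trials)) {
      for (cond in c("bright", "dark")) {
        center <- participant$bias_bright
        if (cond == "dark") center <- center + participant$psa_shift
        pupil_target <- if (cond == "bright") participant$pupil_bright else participant$pupil_dark
        pupil_from <- if (cond == "bright") participant$pupil_dark else participant$pupil_bright
        for (ph in c("adaptation", "measurement")) {
          dur <- if (ph == "adaptation") schedule$adaptation_duration else schedule$measurement_duration
          n <- as.integer(round(dur * rate))
          if (n < 1L) abort_config("phase duration times sampling rate must be >= 1 sample")
          tt <- t0 + (seq_len(n) - 1) / rate
          if (ph == "adaptation") {
            # free viewing: slow wander around screen center
            x <- ar1_noise(n, 3, 0.995)
            y <- ar1_noise(n, 3, 0.995)
          } else {
            x <- center[1] + ar1_noise(n, sd_axis, phi)
            y <- center[2] + ar1_noise(n, sd_axis, phi)
          }
          t_in_period <- tt - t0 + if (ph == "measurement") schedule$adaptation_duration else 0
          pupil <- pupil_approach(t_in_period, pupil_from, pupil_target) *
            (1 + stats::rnorm(n, 0, 0.01))
          bl <- blink_mask(n, rate, device$blink_rate, device$blink_duration)
          n_exc <- 0L
          if (device$data_loss_mode == "nan_plus_excursion" && length(bl$spans)) {
            # each flanking sample is displaced exactly once (overlapping
            # blinks must not stack or cancel displacements)
            ex_dir <- stats::runif(length(bl$spans), 0, 2 * pi)
            marked <- rep(NA_integer_, n)
            for (si in seq_along(bl$spans)) {
              sp <- bl$spans[[si]]
              pre <- if (sp[1] > 1L) seq.int(max(1L, sp[1] - excursion_len), sp[1] - 1L) else integer(0)
              post <- if (sp[2] < n) seq.int(sp[2] + 1L, min(n, sp[2] + excursion_len)) else integer(0)
              for (j in c(pre, post)) {
                if (!bl$invalid[j] && is.na(marked[j])) marked[j] <- si
              }
            }
            hit <- which(!is.na(marked))
            x[hit] <- x[hit] + excursion_amp * cos(ex_dir[marked[hit]])
            y[hit] <- y[hit] + excursion_amp * sin(ex_dir[marked[hit]])
            n_exc <- length(hit)
          }
          valid <- !bl$invalid
          x[!valid] <- NaN; y[!valid] <- NaN; pupil[!valid] <- NaN
          rec <- gaze_recording(tt, x, y, valid = valid, pupil = pupil,
                                space = "deg", condition = cond, phase = ph,
                                trial_index = trial)
          recordings[[length(recordings) + 1L]] <- rec
          n_invalid <- c(n_invalid, sum(!valid))
          n_excursion <- c(n_excursion, n_exc)
          t0 <- t0 + dur
        }
      }
    }
    n_total <- sum(vapply(recordings, nrow, 1L))
    truth <- list(
      true_gaze_angle = list(bright = participant$bias_bright,
                             dark = participant$bias_bright + participant$psa_shift),
      injected_shift = participant$psa_shift,
      injected_loss_fraction = sum(n_invalid) / n_total,
      true_distance = 930,
      n_invalid = n_invalid,
      n_excursion = n_excursion
    )
    list(recordings = recordings, truth = truth)
  })
}

#' Generate a standalone pupil-diameter trace for a session
#'
#' The trace approaches `pupil_bright` during bright periods and
#' `pupil_dark` during dark periods with an exponential time constant of
#' 1 s (pupillary light reflex timescale), plus small multiplicative noise.
#'
#' @param participant A [participant_profile()].
#' @param schedule A [trial_schedule()].
#' @param seed Integer seed.
#' @param sampling_rate Hz.
#' @param noise_cv Coefficient of variation of the multiplicative noise;
#'   0 gives a piecewise-deterministic trace.
#' @return Data frame with columns `t`, `pupil`, `condition`, `phase`,
#'   `trial`.
#' @export
generate_pupil_trace <- function(participant, schedule, seed,
                                 sampling_rate = 100, noise_cv = 0.01) {
  stopifnot(inherits(participant, "psaqc_participant"),
            inherits(schedule, "psaqc_schedule"))
  if (sampling_rate <= 0) abort_config("`sampling_rate` must be positive")
  with_local_seed(seed, {
    out <- list()
    t0 <- 0
    for (trial in seq_len(schedule$n_trials)) {
      for (cond in c("bright", "dark")) {
        tgt <- if (cond == "bright") participant$pupil_bright else participant$pupil_dark
        from <- if (cond == "bright") participant$pupil_dark else participant$pupil_bright
        dur <- schedule$bright_duration
        n <- as.integer(round(dur * sampling_rate))
        tt <- (seq_len(n) - 1) / sampling_rate
        p <- pupil_approach(tt, from, tgt)
        if (noise_cv > 0) p <- p * (1 + stats::rnorm(n, 0, noise_cv))
        phase <- ifelse(tt < schedule$adaptation_duration, "adaptation", "measurement")
        out[[length(out) + 1L]] <- data.frame(
          t = t0 + tt, pupil = p, condition = cond, phase = phase, trial = trial)
        t0 <- t0 + dur
      }
    }
    do.call(rbind, out)
  })
}
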