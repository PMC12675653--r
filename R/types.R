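#' Device profile for the synthetic session generator
#'
#' Describes the signal characteristics of one (real or hypothetical)
#' eye tracker: sampling rate, gaze noise, blink behaviour and how data
#' loss manifests in the stream.
#'
#' The gaze noise is an isotropic first-order autoregressive (AR(1))
#' process in degree space. `noise_std` sets the stationary dispersion
#' (the STD precision metric of an infinitely long clean recording);
#' `s2s_noise` sets the expected RMS sample-to-sample displacement
#' independently, by solving for the AR(1) coefficient. White noise
#' (`s2s_noise = sqrt(2) * noise_std`) is the default.
#'
#' @param name Device label.
#' @param sampling_rate Samples per second (Hz), positive. Head-mounted
#'   devices in this class of study run at 30-500 Hz.
#' @param noise_std Stationary dispersion of gaze around fixation, degrees.
#' @param s2s_noise Target RMS sample-to-sample displacement, degrees, or
#'   `NULL` for temporally white noise. Must be in `(0, 2 * noise_std]`.
#' @param blink_rate Blink onsets per second (Poisson rate).
#' @param blink_duration Duration of each blink, seconds.
#' @param data_loss_mode `"nan_only"`: blinks only invalidate samples;
#'   `"nan_plus_excursion"`: each blink is additionally flanked by short
#'   large-amplitude gaze excursions (> 10 degrees from target), emulating
#'   the pupil-occlusion artifacts that the distance filter must remove.
#' @return An object of class `psaqc_device`.
#' @export
device_profile <- function(name = "synthetic-100Hz",
                           sampling_rate = 100,
                           noise_std = 0.3,
                           s2s_noise = NULL,
                           blink_rate = 0.2,
                           blink_duration = 0.15,
                           data_loss_mode = c("nan_only", "nan_plus_excursion")) {
  data_loss_mode <- match.arg(data_loss_mode)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    abort_config("`sampling_rate` must be a single positive number (Hz)")
  }
  if (!is.numeric(noise_std) || noise_std < 0) {
    abort_config("`noise_std` must be >= 0 degrees")
  }
  if (blink_rate < 0) abort_config("`blink_rate` must be >= 0 events/s")
  if (blink_duration < 0) abort_config("`blink_duration` must be >= 0 s")
  if (!is.null(s2s_noise)) {
    if (noise_std <= 0) abort_config("`s2s_noise` requires `noise_std` > 0")
    if (s2s_noise <= 0 || s2s_noise > 2 * noise_std) {
      abort_config("`s2s_noise` must lie in (0, 2 * noise_std]")
    }
  }
  structure(
    list(name = name, sampling_rate = sampling_rate, noise_std = noise_std,
         s2s_noise = s2s_noise, blink_rate = blink_rate,
         blink_duration = blink_duration, data_loss_mode = data_loss_mode),
    class = "psaqc_device"
  )
}

#' Participant profile for the synthetic session generator
#'
#' Ground-truth parameters of one simulated participant. `psa_shift` is the
#' apparent gaze displacement the device reports in the dark (dilated-pupil)
#' condition relative to the bright condition -- the pupil-size artifact
#' injected phenomenologically. `bias_bright` is an ordinary calibration
#' offset present in both conditions.
#'
#' @param psa_shift Numeric length-2 vector, degrees (x, y).
#' @param bias_bright Numeric length-2 vector, degrees (x, y).
#' @param pupil_bright,pupil_dark Steady-state pupil diameters, mm. Defaults
#'   match typical photopic/scotopic diameters observed with this paradigm
#'   (about 2.88 mm bright, 5.05 mm dark); the dark pupil must be the larger
#'   one by construction.
#' @return An object of class `psaqc_participant`.
#' @export
participant_profile <- function(psa_shift = c(2, 0),
                                bias_bright = c(0, 0),
                                pupil_bright = 2.88,
                                pupil_dark = 5.05) {
  if (length(psa_shift) != 2L || !is.numeric(psa_shift) || anyNA(psa_shift)) {
    abort_config("`psa_shift` must be a finite numeric length-2 vector (degrees)")
  }
  if (length(bias_bright) != 2L || !is.numeric(bias_bright) || anyNA(bias_bright)) {
    abort_config("`bias_bright` must be a finite numeric length-2 vector (degrees)")
  }
  if (pupil_bright <= 0 || pupil_dark <= 0) {
    abort_config("pupil diameters must be positive (mm)")
  }
  if (pupil_dark <= pupil_bright) {
    abort_config("`pupil_dark` must exceed `pupil_bright` (pupils dilate in the dark)")
  }
  structure(
    list(psa_shift = as.numeric(psa_shift), bias_bright = as.numeric(bias_bright),
         pupil_bright = pupil_bright, pupil_dark = pupil_dark),
    class = "psaqc_participant"
  )
}

#' Draw a cohort of random participant profiles
#'
#' PSA magnitudes are drawn uniformly over `shift_range` (default spans the
#' device-mean range reported for this paradigm, 0.94-3.46 degrees) and the
#' shift direction uniformly on the circle; per-participant direction is a
#' modeling choice since only magnitudes are typically reported.
#'
#' @param n Number of participants.
#' @param seed RNG seed.
#' @param shift_range Length-2 range of shift magnitudes, degrees.
#' @param bias_sd SD of the per-axis calibration offset, degrees.
#' @return List of [participant_profile()] objects.
#' @export
sample_participants <- function(n, seed, shift_range = c(0.94, 3.46),
                                bias_sd = 0.25) {
  with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      mag <- stats::runif(1, shift_range[1], shift_range[2])
      ang <- stats::runif(1, 0, 2 * pi)
      participant_profile(
        psa_shift = mag * c(cos(ang), sin(ang)),
        bias_bright = stats::rnorm(2, 0, bias_sd)
      )
    })
  })
}

#' Trial schedule of a bright/dark session
#'
#' Each trial is a bright period followed by a dark period; each period
#' starts with a target-free adaptation phase and ends with a fixation
#' measurement phase. Defaults: 3 trials, 10-s periods split 5 s + 5 s.
#'
#' @param n_trials Number of trials per session.
#' @param bright_duration,dark_duration Period lengths, seconds.
#' @param adaptation_duration,measurement_duration Phase lengths, seconds;
#'   must sum to the period length on both conditions.
#' @return An object of class `psaqc_schedule`.
#' @export
trial_schedule <- function(n_trials = 3,
                           bright_duration = 10, dark_duration = 10,
                           adaptation_duration = 5, measurement_duration = 5) {
  if (n_trials < 1) abort_config("`n_trials` must be >= 1")
  durs <- c(bright_duration, dark_duration, adaptation_duration, measurement_duration)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    abort_config("all durations must be positive and finite (seconds)")
  }
  if (abs(adaptation_duration + measurement_duration - bright_duration) > 1e-9 ||
      abs(bright_duration - dark_duration) > 1e-9) {
    abort_config("adaptation + measurement must equal both period durations")
  }
  structure(
    list(n_trials = as.integer(n_trials),
         bright_duration = bright_duration, dark_duration = dark_duration,
         adaptation_duration = adaptation_duration,
         measurement_duration = measurement_duration),
    class = "psaqc_schedule"
  )
}

#' Construct a gaze recording
#'
#' A gaze recording is one trial phase of one condition: a data frame with
#' columns `t` (seconds, strictly increasing), `x`, `y` (gaze position),
#' `valid` (logical; invalid samples carry NaN coordinates), `pupil`
#' (diameter, mm or device units) and `idx` (within-phase sample index,
#' used to define sample adjacency after filtering). The coordinate space
#' (`"px"` or `"deg"`), condition, phase and trial index are attributes.
#'
#' @param t,x,y,valid,pupil Equal-length sample channels.
#' @param space `"deg"` or `"px"`.
#' @param condition `"bright"` or `"dark"`.
#' @param phase `"adaptation"` or `"measurement"`.
#' @param trial_index 1-based trial number.
#' @param idx Within-phase sample indices (default `seq_along(t)`).
#' @return A `data.frame` of class `psaqc_gaze`.
#' @export
gaze_recording <- function(t, x, y, valid = NULL, pupil = NA_real_,
                           space = c("deg", "px"),
                           condition = c("bright", "dark"),
                           phase = c("measurement", "adaptation"),
                           trial_index = 1L,
                           idx = NULL) {
  space <- match.arg(space)
  condition <- match.arg(condition)
  phase <- match.arg(phase)
  n <- length(t)
  if (length(x) != n || length(y) != n) {
    abort_config("`t`, `x`, `y` must have equal length")
  }
  if (n > 1 && any(diff(t) <= 0)) {
    abort_config("timestamps must be strictly increasing")
  }
  if (is.null(valid)) valid <- is.finite(x) & is.finite(y)
  if (length(valid) != n) abort_config("`valid` length mismatch")
  x[!valid] <- NaN
  y[!valid] <- NaN
  if (length(pupil) == 1L) pupil <- rep(pupil, n)
  if (is.null(idx)) idx <- seq_len(n)
  rec <- data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                    valid = as.logical(valid), pupil = as.numeric(pupil),
                    idx = as.integer(idx))
  structure(rec,
            class = c("psaqc_gaze", "data.frame"),
            space = space, condition = condition, phase = phase,
            trial_index = as.integer(trial_index))
}

# Rebuild a psaqc_gaze from a row subset, preserving metadata.
gaze_subset <- function(rec, keep) {
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  attributes(out) <- c(attributes(out)[c("names", "row.names")],
                       list(class = class(rec),
                            space = attr(rec, "space"),
                            condition = attr(rec, "condition"),
                            phase = attr(rec, "phase"),
                            trial_index = attr(rec, "trial_index")))
  out
}

#' @export
print.psaqc_gaze <- function(x, ...) {
  cat(sprintf("<gaze recording: trial %d, %s/%s, %d samples, space=%s>\n",
              attr(x, "trial_index"), attr(x, "condition"), attr(x, "phase"),
              nrow(x), attr(x, "space")))
  utils::str(utils::head(as.data.frame(x), 3))
  invisible(x)
}

#' Scene-camera model (pinhole + Brown-Conrady distortion)
#'
#' @param fx,fy Focal lengths, pixels; positive.
#' @param cx,cy Principal point, pixels (1-based pixel-center convention:
#'   the center of the top-left pixel is (1, 1)); must lie inside the image.
#' @param distortion Coefficients `(k1, k2, p1, p2, k3)` in the usual
#'   radial/tangential convention; shorter vectors are zero-padded.
#' @param image_size `(width, height)` in pixels.
#' @return An object of class `psaqc_camera`.
#' @export
camera_model <- function(fx = 900, fy = 900,
                         cx = NULL, cy = NULL,
                         distortion = c(0, 0, 0, 0, 0),
                         image_size = c(640, 480)) {
  if (fx <= 0 || fy <= 0) abort_config("focal lengths must be positive")
  if (length(image_size) != 2L || any(image_size < 1)) {
    abort_config("`image_size` must be (width, height) in pixels")
  }
  if (is.null(cx)) cx <- (image_size[1] + 1) / 2
  if (is.null(cy)) cy <- (image_size[2] + 1) / 2
  if (cx < 1 || cx > image_size[1] || cy < 1 || cy > image_size[2]) {
    abort_config("principal point must lie inside the image")
  }
  d <- rep(0, 5)
  d[seq_along(distortion)] <- distortion
  structure(
    list(fx = fx, fy = fy, cx = cx, cy = cy, distortion = d,
         image_size = as.integer(image_size)),
    class = "psaqc_camera"
  )
}

#' Physical screen and marker layout
#'
#' Screen-centered physical coordinates in millimeters, x rightward and
#' y upward. The four corner reference markers sit `marker_inset_mm` inside
#' the screen corners; the fixation target sits at the center.
#'
#' @param width_mm,height_mm Physical screen size (defaults 476 x 268 mm).
#' @param marker_diameter_mm Physical diameter of the corner markers.
#' @param marker_inset_mm Inset of marker centers from the screen edges.
#' @param nominal_distance_mm Expected viewing distance (default 930 mm).
#' @return An object of class `psaqc_screen` with a `marker_layout` matrix
#'   (rows TL, TR, BL, BR, target; mm, y-up).
#' @export
screen_geometry <- function(width_mm = 476, height_mm = 268,
                            marker_diameter_mm = 12,
                            marker_inset_mm = 14,
                            nominal_distance_mm = 930) {
  if (width_mm <= 0 || height_mm <= 0) abort_config("screen size must be positive")
  if (nominal_distance_mm <= 0) abort_config("`nominal_distance_mm` must be positive")
  if (marker_inset_mm < marker_diameter_mm / 2 ||
      marker_inset_mm >= min(width_mm, height_mm) / 2) {
    abort_config("markers must lie fully within the screen bounds")
  }
  hx <- width_mm / 2 - marker_inset_mm
  hy <- height_mm / 2 - marker_inset_mm
  layout <- rbind(TL = c(-hx, hy), TR = c(hx, hy),
                  BL = c(-hx, -hy), BR = c(hx, -hy),
                  target = c(0, 0))
  colnames(layout) <- c("x_mm", "y_mm")
  structure(
    list(width_mm = width_mm, height_mm = height_mm,
         marker_diameter_mm = marker_diameter_mm,
         marker_inset_mm = marker_inset_mm,
         nominal_distance_mm = nominal_distance_mm,
         marker_layout = layout),
    class = "psaqc_screen"
  )
}

#' Marker detection result for one scene frame
#'
#' @param corner_points 4 x 2 matrix of pixel centers, rows named
#'   TL, TR, BL, BR (image convention, y down).
#' @param target_point Length-2 pixel center of the fixation target.
#' @param corner_sizes_px Apparent diameters of the four corner markers in
#'   pixels (same row order), or `NULL` if not measured.
#' @param frame_index Frame number the detection came from.
#' @param quality Mean pixel-to-cluster-center residual, px.
#' @return An object of class `psaqc_detection`.
#' @export
marker_detection <- function(corner_points, target_point,
                             corner_sizes_px = NULL,
                             frame_index = 1L, quality = NA_real_) {
  corner_points <- as.matrix(corner_points)
  if (!all(dim(corner_points) == c(4L, 2L))) {
    abort_config("`corner_points` must be a 4 x 2 matrix")
  }
  need <- c("TL", "TR", "BL", "BR")
  if (is.null(rownames(corner_points))) rownames(corner_points) <- need
  if (!setequal(rownames(corner_points), need)) {
    abort_config("corner rows must be named TL, TR, BL, BR")
  }
  corner_points <- corner_points[need, , drop = FALSE]
  if (length(target_point) != 2L || anyNA(target_point)) {
    abort_config("`target_point` must be a finite length-2 pixel position")
  }
  if (!is.null(corner_sizes_px) && (length(corner_sizes_px) != 4L ||
                                    any(corner_sizes_px <= 0))) {
    abort_config("`corner_sizes_px` must be four positive diameters")
  }
  # corner identities must be consistent with their quadrant relative to
  # the detection centroid (image convention: y grows downward)
  ctr <- colMeans(rbind(corner_points, target_point))
  left <- corner_points[, 1] < ctr[1]
  top  <- corner_points[, 2] < ctr[2]
  quad_ok <- (left == c(TRUE, FALSE, TRUE, FALSE)) &
             (top  == c(TRUE, TRUE, FALSE, FALSE))
  if (!all(quad_ok)) {
    abort_config("corner identities inconsistent with their image quadrants")
  }
  structure(
    list(corner_points = corner_points, target_point = as.numeric(target_point),
         corner_sizes_px = corner_sizes_px,
         frame_index = as.integer(frame_index), quality = quality),
    class = "psaqc_detection"
  )
}

#' Pupil-size calibration against an artificial pupil
#'
#' @param d_artificial Known artificial-pupil diameter, mm.
#' @param d_artificial_recorded Device-reported area of the artificial
#'   pupil, arbitrary units.
#' @return An object of class `psaqc_pupil_cal`.
#' @export
pupil_calibration <- function(d_artificial, d_artificial_recorded) {
  if (d_artificial <= 0 || d_artificial_recorded <= 0) {
    abort_config("calibration values must be strictly positive")
  }
  structure(list(d_artificial = d_artificial,
                 d_artificial_recorded = d_artificial_recorded),
            class = "psaqc_pupil_cal")
}
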