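# Data-cleaning chain: middle-75% trimming, 10-degree distance filter,
# 3-SD outlier filter, and device-units -> mm pupil conversion.
#
# Filters drop rows from the recording (membership only, never values);
# NaN (invalid) samples are exempt from both filter stages -- they are
# data loss, which is measured before cleaning.

filter_report <- function(n_input, n_invalid, n_removed_distance = 0L,
                          n_removed_sd = 0L) {
  n_valid <- n_input - n_invalid
  structure(
    list(n_input = as.integer(n_input),
         n_invalid = as.integer(n_invalid),
         n_removed_distance = as.integer(n_removed_distance),
         n_removed_sd = as.integer(n_removed_sd),
         fraction_removed = if (n_valid > 0)
           (n_removed_distance + n_removed_sd) / n_valid else 0),
    class = "psaqc_filter_report"
  )
}

merge_reports <- function(a, b) {
  filter_report(a$n_input, a$n_invalid,
                a$n_removed_distance + b$n_removed_distance,
                a$n_removed_sd + b$n_removed_sd)
}

#' Trim the unstable start and end of a measurement recording
#'
#' Keeps the middle 75% of samples: `floor(trim * N)` samples are dropped
#' from each end (by sample count, not wall time), excluding the saccades
#' toward and away from the target that cluster at trial boundaries.
#'
#' @param rec A [gaze_recording()] (measurement phase).
#' @param trim Fraction trimmed from each end; default 0.125.
#' @return The trimmed recording.
#' @export
trim_trial <- function(rec, trim = 0.125) {
  stopifnot(inherits(rec, "psaqc_gaze"))
  n <- nrow(rec)
  if (n == 0L) abort_empty_trial("cannot trim an empty recording")
  if (trim < 0 || trim >= 0.5) abort_config("`trim` must be in [0, 0.5)")
  k <- floor(trim * n)
  gaze_subset(rec, seq.int(k + 1L, n - k))
}

#' Distance-based blink-artifact filter
#'
#' Removes valid samples located more than `radius` degrees (strictly) from
#' the target. NaN samples pass through unremoved: they are data loss, not
#' outliers.
#'
#' @param rec A degree-space [gaze_recording()].
#' @param target Length-2 target position, degrees.
#' @param radius Removal radius, degrees (default 10).
#' @return List with `recording` and `report` (a filter report).
#' @export
distance_filter <- function(rec, target = c(0, 0), radius = 10) {
  stopifnot(inherits(rec, "psaqc_gaze"))
  if (attr(rec, "space") != "deg") abort_config("recording must be in degree space")
  d <- sqrt((rec$x - target[1])^2 + (rec$y - target[2])^2)
  remove <- is.finite(d) & d > radius
  out <- gaze_subset(rec, !remove)
  list(recording = out,
       report = filter_report(nrow(rec), sum(!rec$valid), n_removed_distance = sum(remove)))
}

#' Statistical outlier filter (k standard deviations per axis)
#'
#' Single pass: the mean and standard deviation of x and of y are computed
#' over the valid samples, and samples exceeding `k` SDs from the mean in
#' either dimension are removed. The population denominator (N) is used,
#' consistent with the STD precision metric. A zero SD on an axis removes
#' nothing on that axis.
#'
#' @param rec A degree-space [gaze_recording()].
#' @param k SD multiplier (default 3).
#' @return List with `recording` and `report`.
#' @export
sd_outlier_filter <- function(rec, k = 3) {
  stopifnot(inherits(rec, "psaqc_gaze"))
  ok <- rec$valid & is.finite(rec$x) & is.finite(rec$y)
  if (sum(ok) < 2L) abort_insufficient("SD filter needs >= 2 valid samples")
  mx <- mean(rec$x[ok]); my <- mean(rec$y[ok])
  sx <- sqrt(mean((rec$x[ok] - mx)^2))
  sy <- sqrt(mean((rec$y[ok] - my)^2))
  ex_x <- if (sx > 0) ok & abs(rec$x - mx) > k * sx else rep(FALSE, nrow(rec))
  ex_y <- if (sy > 0) ok & abs(rec$y - my) > k * sy else rep(FALSE, nrow(rec))
  remove <- ex_x | ex_y
  remove[is.na(remove)] <- FALSE
  out <- gaze_subset(rec, !remove)
  list(recording = out,
       report = filter_report(nrow(rec), sum(!rec$valid), n_removed_sd = sum(remove)))
}

#' Convert device pupil area to diameter in millimeters
#'
#' `D_mm = D_artificial * sqrt(area / area_artificial)`: areas scale with
#' the square of the diameter, so the recorded-area ratio to a known
#' artificial pupil yields the diameter directly.
#'
#' @param area Recorded pupil area, device units (vectorized); NaN
#'   propagates.
#' @param cal A [pupil_calibration()].
#' @return Pupil diameter, mm.
#' @export
pupil_area_to_mm <- function(area, cal) {
  stopifnot(inherits(cal, "psaqc_pupil_cal"))
  if (any(area < 0, na.rm = TRUE)) abort_domain("pupil area must be >= 0")
  cal$d_artificial * sqrt(area / cal$d_artificial_recorded)
}

#' Full cleaning pipeline for one measurement recording
#'
#' Applies, in order: trimming of the initial and final fraction, the
#' distance filter, then the single-pass SD outlier filter ("two-stage
#' filtering"). The report aggregates removals over both stages. The
#' pipeline is idempotent on its own output except that the SD stage,
#' recomputing mean and SD on the filtered set, may remove further points
#' when re-applied; this is expected of a single-pass filter.
#'
#' If fewer than 2 valid samples survive to the SD stage, the SD stage is
#' skipped (degenerate recordings pass through with their report).
#'
#' @param rec A degree-space measurement [gaze_recording()].
#' @param target Length-2 target position, degrees.
#' @param config List of `trim` (default 0.125), `radius` (10), `k` (3),
#'   `sd_iterate` (FALSE; when TRUE the SD stage repeats to a fixed point).
#' @return List with `recording` and `report`.
#' @export
clean_pipeline <- function(rec, target = c(0, 0), config = list()) {
  trim <- config$trim %||% 0.125
  radius <- config$radius %||% 10
  k <- config$k %||% 3
  sd_iterate <- isTRUE(config$sd_iterate)
  trimmed <- trim_trial(rec, trim)
  st1 <- distance_filter(trimmed, target, radius)
  cur <- st1$recording
  report <- st1$report
  repeat {
    n_ok <- sum(cur$valid & is.finite(cur$x) & is.finite(cur$y))
    if (n_ok < 2L) break
    st2 <- sd_outlier_filter(cur, k)
    report <- merge_reports(report, st2$report)
    removed <- nrow(cur) - nrow(st2$recording)
    cur <- st2$recording
    if (!sd_iterate || removed == 0L) break
  }
  list(recording = cur, report = report)
}
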