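# Gaze data-quality metrics: accuracy, apparent gaze shift, STD precision,
# RMS sample-to-sample, data loss. All operate on degree-space recordings;
# all but data_loss expect cleaned recordings, data_loss is defined on the
# raw (pre-cleaning) trial.

valid_xy <- function(rec) {
  ok <- rec$valid & is.finite(rec$x) & is.finite(rec$y)
  cbind(rec$x[ok], rec$y[ok])
}

#' Spatial accuracy: mean offset from the target
#'
#' Mean over valid samples of the Euclidean distance between each gaze
#' point and the target (the mean of distances, not the distance of the
#' mean). Lower is better.
#'
#' @param rec A degree-space [gaze_recording()] (cleaned).
#' @param target Length-2 target position, degrees.
#' @return Accuracy, degrees.
#' @export
accuracy <- function(rec, target = c(0, 0)) {
  xy <- valid_xy(rec)
  if (nrow(xy) < 1L) abort_insufficient("accuracy needs >= 1 valid sample")
  mean(sqrt((xy[, 1] - target[1])^2 + (xy[, 2] - target[2])^2))
}

#' Apparent gaze shift between sequential bright/dark pairs
#'
#' For each sequential bright/dark trial pair, the Euclidean distance
#' between the bright-phase mean gaze position and the dark-phase mean gaze
#' position; the result is the mean over pairs. Pairing sequential trials
#' sidesteps slow gaze drift (e.g. headset slippage) that would contaminate
#' a pooled comparison.
#'
#' @param pairs List of pairs; each element a list with components `bright`
#'   and `dark`, both cleaned degree-space [gaze_recording()]s from the
#'   same trial.
#' @return List of class `psaqc_shift`: `per_trial_shift` (degrees, one per
#'   pair), `mean_shift`, `n_pairs`.
#' @export
apparent_gaze_shift <- function(pairs) {
  if (length(pairs) < 1L) abort_insufficient("need at least one bright/dark pair")
  per <- vapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    b <- valid_xy(p$bright); d <- valid_xy(p$dark)
    if (nrow(b) < 1L || nrow(d) < 1L) {
      abort_insufficient(sprintf("pair %d has an empty phase", i))
    }
    sqrt((mean(b[, 1]) - mean(d[, 1]))^2 + (mean(b[, 2]) - mean(d[, 2]))^2)
  }, numeric(1))
  structure(list(per_trial_shift = per, mean_shift = mean(per),
                 n_pairs = length(per)),
            class = "psaqc_shift")
}

#' STD precision: overall spatial spread around the centroid
#'
#' Square root of the mean squared Euclidean deviation from the mean gaze
#' position, with the population denominator N; equals
#' `sqrt(var_pop(x) + var_pop(y))`.
#'
#' @param rec A degree-space [gaze_recording()] (cleaned).
#' @return STD, degrees.
#' @export
std_precision <- function(rec) {
  xy <- valid_xy(rec)
  if (nrow(xy) < 1L) abort_insufficient("STD needs >= 1 valid sample")
  mx <- mean(xy[, 1]); my <- mean(xy[, 2])
  sqrt(mean((xy[, 1] - mx)^2 + (xy[, 2] - my)^2))
}

#' RMS sample-to-sample precision
#'
#' Root mean square of the Euclidean displacement between consecutive
#' samples. Only pairs whose members are both valid and adjacent in the
#' original sampling (consecutive `idx`) are used; pairs spanning a NaN gap
#' or a filtered-out sample are excluded, and the denominator is the count
#' of used pairs (which reduces to N - 1 on gap-free data).
#'
#' @param rec A degree-space [gaze_recording()] (cleaned).
#' @return RMS-S2S, degrees.
#' @export
rms_s2s <- function(rec) {
  stopifnot(inherits(rec, "psaqc_gaze"))
  ok <- rec$valid & is.finite(rec$x) & is.finite(rec$y)
  if (sum(ok) < 2L) abort_insufficient("RMS-S2S needs >= 2 valid samples")
  x <- rec$x[ok]; y <- rec$y[ok]; idx <- rec$idx[ok]
  adj <- which(diff(idx) == 1L)
  if (length(adj) == 0L) abort_insufficient("no adjacent valid sample pairs")
  sq <- (x[adj + 1L] - x[adj])^2 + (y[adj + 1L] - y[adj])^2
  sqrt(mean(sq))
}

#' Data loss: percentage of invalid samples before cleaning
#'
#' `100 * N_invalid / N_total` on the raw (un-cleaned) trial recording.
#' Invalid samples are those flagged by the device (NaN coordinates).
#'
#' @param rec The raw [gaze_recording()] for the trial period.
#' @return Data loss, percent in [0, 100].
#' @export
data_loss <- function(rec) {
  stopifnot(inherits(rec, "psaqc_gaze"))
  n <- nrow(rec)
  if (n == 0L) abort_empty_trial("data loss undefined on an empty trial")
  100 * sum(!rec$valid) / n
}

#' Per-trial quality metrics for one raw measurement recording
#'
#' Runs the cleaning pipeline and computes accuracy, STD, RMS-S2S on the
#' cleaned recording and data loss on the raw recording.
#'
#' @param raw Raw degree-space measurement [gaze_recording()].
#' @param target Length-2 target position, degrees.
#' @param config Cleaning configuration, see [clean_pipeline()].
#' @return One-row data frame: `trial`, `condition`, `accuracy`, `std`,
#'   `rms_s2s`, `data_loss`, `n_valid`, plus the cleaned recording and the
#'   filter report as attributes `recording` and `report`.
#' @export
trial_metrics <- function(raw, target = c(0, 0), config = list()) {
  cl <- clean_pipeline(raw, target, config)
  rec <- cl$recording
  xy <- valid_xy(rec)
  res <- data.frame(
    trial = attr(raw, "trial_index"),
    condition = attr(raw, "condition"),
    accuracy = if (nrow(xy) >= 1) accuracy(rec, target) else NA_real_,
    std = if (nrow(xy) >= 1) std_precision(rec) else NA_real_,
    rms_s2s = tryCatch(rms_s2s(rec), psaqc_insufficient_data = function(e) NA_real_),
    data_loss = data_loss(raw),
    n_valid = nrow(xy)
  )
  attr(res, "recording") <- rec
  attr(res, "report") <- cl$report
  res
}

#' Analyze one generated or recorded session
#'
#' Computes per-trial, per-condition quality metrics from the measurement
#' phases and the session's apparent gaze shift over sequential bright/dark
#' trial pairs (phase means taken after cleaning).
#'
#' @param recordings List of [gaze_recording()]s (as returned in
#'   `generate_session()$recordings`); only measurement phases are used.
#' @param target Length-2 target position, degrees.
#' @param config Cleaning configuration, see [clean_pipeline()].
#' @return List: `metrics` (data frame, one row per trial x condition),
#'   `shift` (a `psaqc_shift`).
#' @export
analyze_session <- function(recordings, target = c(0, 0), config = list()) {
  meas <- Filter(function(r) attr(r, "phase") == "measurement", recordings)
  rows <- list(); cleaned <- list()
  for (r in meas) {
    tm <- trial_metrics(r, target, config)
    rows[[length(rows) + 1L]] <- tm
    key <- paste(attr(r, "trial_index"), attr(r, "condition"), sep = ".")
    cleaned[[key]] <- attr(tm, "recording")
  }
  trials <- sort(unique(vapply(meas, function(r) attr(r, "trial_index"), 1L)))
  pairs <- lapply(trials, function(tr) {
    list(bright = cleaned[[paste(tr, "bright", sep = ".")]],
         dark = cleaned[[paste(tr, "dark", sep = ".")]])
  })
  pairs <- Filter(function(p) !is.null(p$bright) && !is.null(p$dark), pairs)
  list(metrics = do.call(rbind, rows), shift = apparent_gaze_shift(pairs))
}
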