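# Session interchange: one CSV per trial phase, a ground-truth sidecar
# JSON, and a YAML manifest echoing all generation parameters.

#' Write a generated session to a directory
#'
#' Writes one CSV per trial phase with columns
#' `timestamp_s, x, y, valid, pupil, condition, phase, trial` (plus the
#' within-phase sample index `idx`), the ground truth to
#' `ground_truth.json`, and all generation parameters to `manifest.yaml`.
#'
#' @param session Result of [generate_session()].
#' @param dir Output directory (created if needed).
#' @param device,participant,schedule,seed The generation inputs, echoed
#'   into the manifest; optional.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, device = NULL, participant = NULL,
                          schedule = NULL, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in session$recordings) {
    df <- data.frame(timestamp_s = rec$t, x = rec$x, y = rec$y,
                     valid = rec$valid, pupil = rec$pupil,
                     condition = attr(rec, "condition"),
                     phase = attr(rec, "phase"),
                     trial = attr(rec, "trial_index"),
                     idx = rec$idx)
    fn <- sprintf("trial%02d_%s_%s.csv", attr(rec, "trial_index"),
                  attr(rec, "condition"), attr(rec, "phase"))
    utils::write.csv(df, file.path(dir, fn), row.names = FALSE)
  }
  jsonlite::write_json(session$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(
    generator = "psaqc",
    seed = seed,
    device = if (!is.null(device)) unclass(device),
    participant = if (!is.null(participant)) unclass(participant),
    schedule = if (!is.null(schedule)) unclass(schedule)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a gaze CSV back as a gaze recording
#'
#' Expects the column schema written by [write_session()]; `space` is not
#' stored in the CSV and must be stated by the caller (generated sessions
#' are in degrees).
#'
#' @param path CSV file path.
#' @param space `"deg"` or `"px"`.
#' @return A [gaze_recording()].
#' @export
read_gaze_csv <- function(path, space = "deg") {
  df <- utils::read.csv(path)
  need <- c("timestamp_s", "x", "y", "valid", "pupil", "condition", "phase", "trial")
  if (!all(need %in% names(df))) {
    abort_config(sprintf("gaze CSV must have columns: %s", paste(need, collapse = ", ")))
  }
  gaze_recording(df$timestamp_s, df$x, df$y, valid = df$valid, pupil = df$pupil,
                 space = space, condition = df$condition[1], phase = df$phase[1],
                 trial_index = df$trial[1],
                 idx = if ("idx" %in% names(df)) df$idx else NULL)
}

#' Read a marker-detection CSV
#'
#' Bypass route for the detection stage: a CSV with columns `frame_index`,
#' `element_id` (TL, TR, BL, BR, target), `x_px`, `y_px` and optionally
#' `size_px` (apparent corner diameters). One detection per frame index.
#'
#' @param path CSV file path.
#' @return List of [marker_detection()]s, one per frame.
#' @export
read_marker_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame_index", "element_id", "x_px", "y_px")
  if (!all(need %in% names(df))) {
    abort_config("marker CSV must have columns frame_index, element_id, x_px, y_px")
  }
  lapply(unique(df$frame_index), function(fi) {
    sub <- df[df$frame_index == fi, ]
    rn <- sub$element_id
    get <- function(id) {
      row <- sub[rn == id, ]
      if (nrow(row) != 1L) abort_config(sprintf("frame %s: need exactly one '%s'", fi, id))
      row
    }
    corners <- t(vapply(c("TL", "TR", "BL", "BR"),
                        function(id) c(get(id)$x_px, get(id)$y_px), numeric(2)))
    tgt <- get("target")
    sizes <- if ("size_px" %in% names(sub)) {
      vapply(c("TL", "TR", "BL", "BR"), function(id) get(id)$size_px, numeric(1))
    } else NULL
    marker_detection(corner_points = corners,
                     target_point = c(tgt$x_px, tgt$y_px),
                     corner_sizes_px = sizes, frame_index = fi)
  })
}

#' Read a camera model from a YAML file
#'
#' Expected keys: `fx`, `fy`, `cx`, `cy`, `distortion` (list of up to five
#' coefficients), `image_size` (width, height).
#'
#' @param path YAML file path.
#' @return A [camera_model()].
#' @export
read_camera_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  camera_model(fx = y$fx, fy = y$fy, cx = y$cx, cy = y$cy,
               distortion = unlist(y$distortion %||% 0),
               image_size = unlist(y$image_size))
}

#' Read a screen geometry from a YAML file
#'
#' @param path YAML file path with keys matching [screen_geometry()]
#'   arguments.
#' @return A [screen_geometry()].
#' @export
read_screen_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(screen_geometry, y[intersect(names(y), names(formals(screen_geometry)))])
}
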