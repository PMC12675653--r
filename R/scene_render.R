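# Synthetic scene-camera frame rendering.
#
# Frames are grayscale matrices in [0, 1] (rows = image y, cols = image x,
# pixel centers at integer coordinates). The rendered luminances are chosen
# so a single intensity band separates the five screen elements from both
# the white and the black screen background and from the room:
#   room 0.25, bright screen 1.0, dark screen 0.0,
#   target outer disc 0.5, target inner dot 0.35, corner markers 0.6
# (0.6 is the grayscale luminance of a saturated green disc).

.render_levels <- list(room = 0.25, target = 0.5, target_inner = 0.35,
                       marker = 0.6)

#' Render one synthetic scene-camera frame
#'
#' Draws the screen (white in the bright condition, black in the dark
#' condition) with the gray bullseye target at the center and four green
#' corner reference markers, through the camera's lens distortion, and
#' returns the exact projected pixel centers of all five elements and of
#' the requested gaze angle as ground truth.
#'
#' @param camera A [camera_model()].
#' @param screen A [screen_geometry()].
#' @param condition `"bright"` or `"dark"`.
#' @param gaze_angle True gaze direction, degrees (x right, y up), mapped
#'   per axis through `tan` at the viewing distance.
#' @param distance_mm Viewing distance; default the screen's nominal
#'   distance.
#' @param noise_sd Gaussian intensity noise SD in [0, 1] units (e.g. 2/255).
#' @param seed Seed for the intensity noise.
#' @return List with `image` (H x W matrix), and `truth`: `marker_px`
#'   (5 x 2, rows TL, TR, BL, BR, target), `gaze_px`, `true_distance`.
#' @export
render_scene_frame <- function(camera, screen,
                               condition = c("bright", "dark"),
                               gaze_angle = c(0, 0),
                               distance_mm = NULL,
                               noise_sd = 0, seed = 1L) {
  condition <- match.arg(condition)
  stopifnot(inherits(camera, "psaqc_camera"), inherits(screen, "psaqc_screen"))
  z <- if (is.null(distance_mm)) screen$nominal_distance_mm else distance_mm
  if (z <= 0) abort_config("`distance_mm` must be positive")
  w <- camera$image_size[1]; h <- camera$image_size[2]

  corners_mm <- rbind(c(-screen$width_mm / 2, screen$height_mm / 2),
                      c(screen$width_mm / 2, screen$height_mm / 2),
                      c(-screen$width_mm / 2, -screen$height_mm / 2),
                      c(screen$width_mm / 2, -screen$height_mm / 2))
  cpx <- project_screen_points(corners_mm, z, camera)
  if (any(cpx[, 1] < 1 | cpx[, 1] > w | cpx[, 2] < 1 | cpx[, 2] > h)) {
    abort_geometry("screen is not fully inside the camera field of view")
  }

  bg <- if (condition == "bright") 1 else 0
  lv <- .render_levels

  # paint the screen rectangle: back-project every pixel to the screen plane
  uu <- rep(seq_len(w), each = h)
  vv <- rep(seq_len(h), times = w)
  mm <- pixels_to_screen_mm(cbind(uu, vv), z, camera)
  inside <- abs(mm[, 1]) <= screen$width_mm / 2 & abs(mm[, 2]) <= screen$height_mm / 2
  img <- matrix(lv$room, nrow = h, ncol = w)
  img[cbind(vv[inside], uu[inside])] <- bg

  # element discs: center (mm), radius (mm), luminance; target = disc + dot
  target_r_outer <- z * tan(0.3 * pi / 180)
  target_r_inner <- z * tan(0.1 * pi / 180)
  elems <- list()
  for (nm in c("TL", "TR", "BL", "BR")) {
    elems[[length(elems) + 1L]] <- list(c = screen$marker_layout[nm, ],
                                        r = screen$marker_diameter_mm / 2,
                                        col = lv$marker)
  }
  elems[[length(elems) + 1L]] <- list(c = c(0, 0), r = target_r_outer, col = lv$target)
  elems[[length(elems) + 1L]] <- list(c = c(0, 0), r = target_r_inner, col = lv$target_inner)

  sub <- (seq_len(3) - 2) / 3  # 3x3 supersampling offsets
  for (el in elems) {
    c_px <- project_screen_points(rbind(el$c), z, camera)
    r_px <- el$r * max(camera$fx, camera$fy) / z
    pad <- ceiling(r_px * 1.3 + 3)
    u0 <- max(1L, floor(c_px[1] - pad)); u1 <- min(w, ceiling(c_px[1] + pad))
    v0 <- max(1L, floor(c_px[2] - pad)); v1 <- min(h, ceiling(c_px[2] + pad))
    us <- seq.int(u0, u1); vs <- seq.int(v0, v1)
    cov <- matrix(0, nrow = length(vs), ncol = length(us))
    for (du in sub) for (dv in sub) {
      gu <- rep(us + du, each = length(vs))
      gv <- rep(vs + dv, times = length(us))
      pm <- pixels_to_screen_mm(cbind(gu, gv), z, camera)
      hit <- (pm[, 1] - el$c[1])^2 + (pm[, 2] - el$c[2])^2 <= el$r^2
      cov <- cov + matrix(hit, nrow = length(vs))
    }
    cov <- cov / length(sub)^2
    img[vs, us] <- img[vs, us] * (1 - cov) + el$col * cov
  }

  if (noise_sd > 0) {
    img <- with_local_seed(seed, {
      img + matrix(stats::rnorm(w * h, 0, noise_sd), nrow = h)
    })
    img[img < 0] <- 0
    img[img > 1] <- 1
  }

  marker_px <- project_screen_points(screen$marker_layout, z, camera)
  rownames(marker_px) <- rownames(screen$marker_layout)
  gaze_mm <- z * tan(gaze_angle * pi / 180)
  gaze_px <- project_screen_points(rbind(gaze_mm), z, camera)

  list(image = img,
       truth = list(marker_px = marker_px,
                    gaze_px = as.numeric(gaze_px),
                    true_distance = z))
}

#' Write a rendered frame to a PNG file
#'
#' Thin wrapper around the `png` package (Suggests); errors clearly when it
#' is unavailable. Frames are written as 8-bit grayscale.
#'
#' @param image H x W matrix in [0, 1].
#' @param path Output file path.
#' @export
write_frame_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort_config("writing PNG frames requires the `png` package")
  }
  png::writePNG(image, target = path)
  invisible(path)
}

#' Read a frame from a PNG file as a grayscale matrix
#'
#' @param path PNG file path.
#' @return H x W matrix in [0, 1] (RGB input is converted by luminance).
#' @export
read_frame_png <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort_config("reading PNG frames requires the `png` package")
  }
  to_gray(png::readPNG(path))
}

# Accept H x W matrices or H x W x {1,3,4} arrays; convert to grayscale by
# the usual luminance weights.
to_gray <- function(image) {
  if (is.matrix(image)) return(image)
  if (length(dim(image)) == 3L) {
    nc <- dim(image)[3]
    if (nc == 1L) return(image[, , 1])
    return(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  }
  abort_config("frame must be a matrix or an H x W x channels array")
}
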