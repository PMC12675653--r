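# Scene-camera gaze mapping: fiducial detection, undistortion, scaling,
# pinhole viewing-distance estimation, pixel -> degree conversion.

# Two-pass connected-component labeling (8-connectivity) over a logical
# mask; returns an integer label matrix (0 = background).
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  next_label <- 0L
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(labels)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  for (k in seq_len(nrow(idx))) {
    r <- idx[k, 1]; c <- idx[k, 2]
    neigh <- integer(0)
    if (c > 1L && labels[r, c - 1L] > 0L) neigh <- c(neigh, labels[r, c - 1L])
    if (r > 1L) {
      for (cc in max(1L, c - 1L):min(w, c + 1L)) {
        if (labels[r - 1L, cc] > 0L) neigh <- c(neigh, labels[r - 1L, cc])
      }
    }
    if (length(neigh) == 0L) {
      next_label <- next_label + 1L
      parent[next_label] <- next_label
      labels[r, c] <- next_label
    } else {
      roots <- unique(vapply(neigh, find, 1L))
      labels[r, c] <- roots[1]
      for (rt in roots[-1]) parent[rt] <- roots[1]
    }
  }
  # flatten
  flat <- vapply(seq_len(next_label), find, 1L)
  relabel <- match(flat, unique(flat))
  pos <- labels > 0L
  labels[pos] <- relabel[labels[pos]]
  labels
}

#' Detect the five screen elements in a scene-camera frame
#'
#' Grayscale conversion, intensity-band thresholding, connected-component
#' contour extraction and k-means grouping into five clusters, mirroring
#' the classic detection chain for this stimulus (gray bullseye target plus
#' four green corner markers). Threshold values are supplied per recording,
#' as in manual threshold selection; [auto_threshold_band()] offers an
#' automatic starting point.
#'
#' Cluster centers are coverage-weighted centroids: each pixel near a
#' cluster is weighted by its estimated sub-pixel coverage
#' `(I - background) / (foreground - background)`, which also yields the
#' apparent marker diameters used for viewing-distance estimation.
#'
#' @param frame Grayscale matrix in [0, 1] or an RGB array.
#' @param threshold_config List with `lo`, `hi` (intensity band selecting
#'   the five elements) and optionally `background` (screen background
#'   level; estimated from the image when omitted) and `min_area`
#'   (component size floor, px, default 3).
#' @param frame_index Frame number recorded in the result.
#' @return A [marker_detection()].
#' @export
detect_markers <- function(frame,
                           threshold_config = list(lo = 0.4, hi = 0.7),
                           frame_index = 1L) {
  img <- to_gray(frame)
  lo <- threshold_config$lo; hi <- threshold_config$hi
  if (is.null(lo) || is.null(hi) || lo >= hi) {
    abort_config("`threshold_config` must supply lo < hi")
  }
  min_area <- threshold_config$min_area %||% 3L
  mask <- img >= lo & img <= hi
  labels <- label_components(mask)
  if (max(labels) == 0L) abort_no_markers("no candidate regions in the intensity band")
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= min_area)
  if (length(keep) < 5L) {
    abort_no_markers(sprintf("found %d candidate region(s); need 5", length(keep)))
  }

  pix <- which(labels > 0L & matrix(labels %in% keep, nrow(labels)), arr.ind = TRUE)
  pts <- cbind(x = pix[, 2], y = pix[, 1])
  comp <- labels[pix]

  # initial centers: centroids of the five largest components
  big5 <- keep[order(sizes[keep], decreasing = TRUE)][1:5]
  init <- t(vapply(big5, function(l) colMeans(pts[comp == l, , drop = FALSE]),
                   numeric(2)))
  if (length(keep) == 5L) {
    assign <- match(comp, big5)
    centers <- init
  } else {
    km <- stats::kmeans(pts, centers = init, iter.max = 50)
    assign <- km$cluster
    centers <- km$centers
  }

  refine <- function(ci) {
    sel <- pts[assign == ci, , drop = FALSE]
    # pad the cluster's bounding box to catch partial-coverage edge pixels
    u0 <- max(1L, min(sel[, 1]) - 2L); u1 <- min(ncol(img), max(sel[, 1]) + 2L)
    v0 <- max(1L, min(sel[, 2]) - 2L); v1 <- min(nrow(img), max(sel[, 2]) + 2L)
    us <- seq.int(u0, u1); vs <- seq.int(v0, v1)
    block <- img[vs, us, drop = FALSE]
    ctr0 <- colMeans(sel)
    fg_px <- sel[which.min((sel[, 1] - ctr0[1])^2 + (sel[, 2] - ctr0[2])^2), ]
    fg <- img[fg_px[2], fg_px[1]]
    # local screen background: median of the bounding-box border ring
    border <- c(block[1, ], block[nrow(block), ], block[, 1], block[, ncol(block)])
    bg <- threshold_config$background %||% stats::median(border)
    wgt <- (block - bg) / (fg - bg)
    wgt[wgt < 0] <- 0; wgt[wgt > 1] <- 1
    total <- sum(wgt)
    gu <- rep(us, each = length(vs)); gv <- rep(vs, times = length(us))
    ctr <- c(sum(gu * wgt) / total, sum(gv * wgt) / total)
    list(center = ctr, area = total)
  }
  ref <- lapply(seq_len(5), refine)
  centers <- t(vapply(ref, `[[`, numeric(2), "center"))
  areas <- vapply(ref, `[[`, numeric(1), "area")
  diam <- 2 * sqrt(areas / pi)

  dmat <- as.matrix(stats::dist(centers))
  diag(dmat) <- Inf
  if (min(dmat) < max(diam)) {
    abort_ambiguous("two clusters closer than the apparent marker diameter")
  }

  ctr_all <- colMeans(centers)
  d_ctr <- sqrt(rowSums(sweep(centers, 2, ctr_all)^2))
  i_target <- which.min(d_ctr)
  corners <- setdiff(seq_len(5), i_target)
  # quadrant assignment relative to the overall centroid (image y down);
  # ties broken by distance to the image corners
  quad_of <- function(i) {
    paste0(if (centers[i, 2] < ctr_all[2]) "T" else "B",
           if (centers[i, 1] < ctr_all[1]) "L" else "R")
  }
  qs <- vapply(corners, quad_of, "")
  if (anyDuplicated(qs) || !setequal(qs, c("TL", "TR", "BL", "BR"))) {
    abort_ambiguous("corner markers do not occupy the four image quadrants")
  }
  ord <- corners[match(c("TL", "TR", "BL", "BR"), qs)]
  corner_points <- centers[ord, , drop = FALSE]
  rownames(corner_points) <- c("TL", "TR", "BL", "BR")

  quality <- mean(sqrt(rowSums((pts - centers[assign, , drop = FALSE])^2)))

  marker_detection(corner_points = corner_points,
                   target_point = centers[i_target, ],
                   corner_sizes_px = stats::setNames(diam[ord], c("TL", "TR", "BL", "BR")),
                   frame_index = frame_index,
                   quality = quality)
}

#' Suggest an intensity band for marker detection
#'
#' Convenience extension (the reference procedure selects thresholds
#' manually per recording): picks the band between the screen background
#' and the room level that brackets the rendered element luminances.
#'
#' @param frame Grayscale matrix or RGB array.
#' @return List with `lo` and `hi`.
#' @export
auto_threshold_band <- function(frame) {
  img <- to_gray(frame)
  list(lo = 0.4, hi = 0.7, background = stats::median(img))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Undistort pixel coordinates to ideal pinhole coordinates
#'
#' Identity when all distortion coefficients are zero. Points outside the
#' invertible domain of the distortion model raise a domain error.
#'
#' @param points n x 2 matrix (or length-2 vector) of pixel coordinates.
#' @param camera A [camera_model()].
#' @return n x 2 matrix of undistorted pixel coordinates.
#' @export
undistort_points <- function(points, camera) {
  stopifnot(inherits(camera, "psaqc_camera"))
  pts <- matrix(points, ncol = 2)
  if (all(camera$distortion == 0)) return(pts)
  nd <- pixels_to_normalized(pts, camera)
  nu <- undistort_normalized(nd[, 1], nd[, 2], camera$distortion, check = TRUE)
  normalized_to_pixels(nu, camera)
}

#' Undistort a full marker detection
#'
#' Applies [undistort_points()] to the four corner points and the target
#' point; apparent marker sizes are corrected by the local radial scale of
#' the undistortion (measured numerically along the radial direction).
#'
#' @param detection A [marker_detection()] in distorted pixel coordinates.
#' @param camera A [camera_model()].
#' @return A [marker_detection()] in ideal pinhole coordinates.
#' @export
undistort_detection <- function(detection, camera) {
  stopifnot(inherits(detection, "psaqc_detection"))
  pts <- rbind(detection$corner_points, detection$target_point)
  und <- undistort_points(pts, camera)
  sizes <- detection$corner_sizes_px
  if (!is.null(sizes)) {
    pp <- c(camera$cx, camera$cy)
    for (i in 1:4) {
      c_d <- detection$corner_points[i, ]
      rad <- c_d - pp
      nr <- sqrt(sum(rad^2))
      rhat <- if (nr > 1e-9) rad / nr else c(1, 0)
      that <- c(-rhat[2], rhat[1])
      # the distorted disc is elliptical: area-equivalent diameter scales
      # with the geometric mean of the radial and tangential local scales
      e_rad <- undistort_points(rbind(c_d + rhat * sizes[i] / 2), camera)
      e_tan <- undistort_points(rbind(c_d + that * sizes[i] / 2), camera)
      r_rad <- sqrt(sum((e_rad - und[i, ])^2))
      r_tan <- sqrt(sum((e_tan - und[i, ])^2))
      sizes[i] <- 2 * sqrt(r_rad * r_tan)
    }
  }
  marker_detection(corner_points = und[1:4, , drop = FALSE],
                   target_point = und[5, ],
                   corner_sizes_px = sizes,
                   frame_index = detection$frame_index,
                   quality = detection$quality)
}

#' Millimeter-per-pixel scaling factor from detected reference points
#'
#' The known physical distances between reference points are divided by
#' their apparent pixel distances in the undistorted image; the ratio is
#' averaged over all six corner-marker pairs to reduce sensitivity to any
#' single detection.
#'
#' @param detection An undistorted [marker_detection()].
#' @param screen A [screen_geometry()].
#' @return Scaling factor, mm per pixel.
#' @export
compute_scaling_factor <- function(detection, screen) {
  stopifnot(inherits(detection, "psaqc_detection"), inherits(screen, "psaqc_screen"))
  phys <- screen$marker_layout[c("TL", "TR", "BL", "BR"), ]
  app <- detection$corner_points
  pairs <- utils::combn(4, 2)
  ratios <- apply(pairs, 2, function(p) {
    d_mm <- sqrt(sum((phys[p[1], ] - phys[p[2], ])^2))
    d_px <- sqrt(sum((app[p[1], ] - app[p[2], ])^2))
    if (d_px < 1e-9) abort_degenerate("coincident detected reference points")
    d_mm / d_px
  })
  mean(ratios)
}

#' Pinhole viewing-distance estimate from apparent marker size
#'
#' `distance = focal_length_px * physical_size_mm / apparent_size_px`,
#' averaged over the four corner markers. If the four per-marker estimates
#' disagree by more than 10 % a warning is emitted (oblique viewing), not
#' an error.
#'
#' @param detection An undistorted [marker_detection()] carrying
#'   `corner_sizes_px`.
#' @param screen A [screen_geometry()].
#' @param camera A [camera_model()].
#' @return Estimated viewing distance, mm.
#' @export
estimate_viewing_distance <- function(detection, screen, camera) {
  stopifnot(inherits(detection, "psaqc_detection"), inherits(screen, "psaqc_screen"),
            inherits(camera, "psaqc_camera"))
  sizes <- detection$corner_sizes_px
  if (is.null(sizes) || any(!is.finite(sizes)) || any(sizes <= 0)) {
    abort_degenerate("apparent marker sizes unavailable or zero")
  }
  f <- (camera$fx + camera$fy) / 2
  est <- f * screen$marker_diameter_mm / sizes
  if ((max(est) - min(est)) / mean(est) > 0.10) {
    warning("per-marker viewing-distance estimates disagree by more than 10%",
            call. = FALSE)
  }
  mean(est)
}

#' Map scene-camera gaze pixels to screen-centered degrees
#'
#' Subtracts the detected target-center pixel, converts to millimeters with
#' the scaling factor, and converts to degrees per axis via
#' `atan(mm / distance)`. Output is screen-centered degrees with x positive
#' rightward and y positive upward (the sign flip from the image's y-down
#' convention is applied here and only here). Non-finite gaze coordinates
#' propagate NaN so invalid samples survive to the data-loss metric.
#'
#' @param gaze_px n x 2 matrix (or length-2 vector) of undistorted gaze
#'   pixels.
#' @param detection An undistorted [marker_detection()].
#' @param scale Scaling factor, mm/px ([compute_scaling_factor()]).
#' @param distance Viewing distance, mm ([estimate_viewing_distance()]).
#' @return n x 2 matrix of degrees.
#' @export
map_gaze_to_degrees <- function(gaze_px, detection, scale, distance) {
  stopifnot(inherits(detection, "psaqc_detection"))
  if (scale <= 0 || distance <= 0) abort_config("scale and distance must be positive")
  g <- matrix(gaze_px, ncol = 2)
  dx_mm <- (g[, 1] - detection$target_point[1]) * scale
  dy_mm <- (g[, 2] - detection$target_point[2]) * scale
  deg_x <- atan(dx_mm / distance) * 180 / pi
  deg_y <- -atan(dy_mm / distance) * 180 / pi   # image y-down -> screen y-up
  cbind(deg_x, deg_y)
}

#' Desktop-tracker pixel-to-degree conversion
#'
#' Linear per-axis conversion used by desktop systems that report their own
#' pixels-per-degree resolution:
#' `degrees = (pixels - screen_center) / resolution`. NaN propagates.
#'
#' @param gaze_px n x 2 matrix (or length-2 vector) of screen pixels.
#' @param screen_center_px Length-2 screen-center pixel position.
#' @param resolution Pixels per degree, length 1 or 2 (per axis), positive.
#' @return n x 2 matrix of degrees.
#' @export
eyelink_pixels_to_degrees <- function(gaze_px, screen_center_px, resolution) {
  if (length(resolution) == 1L) resolution <- rep(resolution, 2)
  if (any(!is.finite(resolution)) || any(resolution <= 0)) {
    abort_config("`resolution` must be positive pixels/degree")
  }
  g <- matrix(gaze_px, ncol = 2)
  cbind((g[, 1] - screen_center_px[1]) / resolution[1],
        (g[, 2] - screen_center_px[2]) / resolution[2])
}

#' Map a pixel-space gaze recording to degrees using one frame's geometry
#'
#' Convenience wrapper for the full per-frame chain: undistort the
#' detection and the gaze samples, compute the scaling factor and viewing
#' distance, and convert every sample to screen-centered degrees.
#'
#' @param rec A [gaze_recording()] with `space = "px"` (scene-camera
#'   pixels).
#' @param detection A raw (distorted-image) [marker_detection()].
#' @param screen A [screen_geometry()].
#' @param camera A [camera_model()].
#' @return List: `recording` (degree-space [gaze_recording()]),
#'   `scale_mm_per_px`, `distance_mm`.
#' @export
scene_map_recording <- function(rec, detection, screen, camera) {
  stopifnot(inherits(rec, "psaqc_gaze"))
  if (attr(rec, "space") != "px") abort_config("recording must be in pixel space")
  det_u <- undistort_detection(detection, camera)
  scale <- compute_scaling_factor(det_u, screen)
  distance <- estimate_viewing_distance(det_u, screen, camera)
  ok <- is.finite(rec$x) & is.finite(rec$y)
  px <- cbind(rec$x, rec$y)
  px[ok, ] <- undistort_points(px[ok, , drop = FALSE], camera)
  deg <- map_gaze_to_degrees(px, det_u, scale, distance)
  out <- gaze_recording(rec$t, deg[, 1], deg[, 2], valid = rec$valid,
                        pupil = rec$pupil, space = "deg",
                        condition = attr(rec, "condition"),
                        phase = attr(rec, "phase"),
                        trial_index = attr(rec, "trial_index"),
                        idx = rec$idx)
  list(recording = out, scale_mm_per_px = scale, distance_mm = distance)
}
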