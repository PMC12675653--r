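# Pinhole projection with Brown-Conrady radial/tangential distortion.
# Normalized coordinates use the image convention (x right, y down);
# physical screen coordinates are y-up, the flip happens at projection.

distort_normalized <- function(xn, yn, d) {
  k1 <- d[1]; k2 <- d[2]; p1 <- d[3]; p2 <- d[4]; k3 <- d[5]
  r2 <- xn^2 + yn^2
  radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  xd <- xn * radial + 2 * p1 * xn * yn + p2 * (r2 + 2 * xn^2)
  yd <- yn * radial + p1 * (r2 + 2 * yn^2) + 2 * p2 * xn * yn
  cbind(xd, yd)
}

# Iterative inverse of distort_normalized (fixed point on the radial part).
undistort_normalized <- function(xd, yd, d, tol = 1e-10, max_iter = 60L,
                                 check = TRUE) {
  if (all(d == 0)) return(cbind(xd, yd))
  x <- xd; y <- yd
  for (i in seq_len(max_iter)) {
    k1 <- d[1]; k2 <- d[2]; p1 <- d[3]; p2 <- d[4]; k3 <- d[5]
    r2 <- x^2 + y^2
    radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
    dx <- 2 * p1 * x * y + p2 * (r2 + 2 * x^2)
    dy <- p1 * (r2 + 2 * y^2) + 2 * p2 * x * y
    x_new <- (xd - dx) / radial
    y_new <- (yd - dy) / radial
    delta <- max(abs(x_new - x), abs(y_new - y), na.rm = TRUE)
    x <- x_new; y <- y_new
    if (!is.finite(delta) || delta < tol) break
  }
  if (check) {
    back <- distort_normalized(x, y, d)
    err <- pmax(abs(back[, 1] - xd), abs(back[, 2] - yd))
    ok <- is.na(err) | err < 1e-6
    if (!all(ok)) {
      abort_domain("point(s) outside the invertible domain of the distortion model")
    }
  }
  cbind(x, y)
}

normalized_to_pixels <- function(xy, camera) {
  cbind(camera$fx * xy[, 1] + camera$cx, camera$fy * xy[, 2] + camera$cy)
}

pixels_to_normalized <- function(px, camera) {
  cbind((px[, 1] - camera$cx) / camera$fx, (px[, 2] - camera$cy) / camera$fy)
}

# Project screen-centered physical points (mm, y-up) at viewing distance
# `z_mm` through the camera (axis through screen center) to pixel coords.
project_screen_points <- function(points_mm, z_mm, camera) {
  points_mm <- matrix(points_mm, ncol = 2)
  xn <- points_mm[, 1] / z_mm
  yn <- -points_mm[, 2] / z_mm   # physical y-up -> image y-down
  normalized_to_pixels(distort_normalized(xn, yn, camera$distortion), camera)
}

# Inverse: pixel coords -> screen-centered mm (y-up) on the plane at z_mm.
pixels_to_screen_mm <- function(px, z_mm, camera, check = FALSE) {
  nd <- pixels_to_normalized(matrix(px, ncol = 2), camera)
  nu <- undistort_normalized(nd[, 1], nd[, 2], camera$distortion, check = check)
  cbind(nu[, 1] * z_mm, -nu[, 2] * z_mm)
}
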