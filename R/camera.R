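# Pinhole camera model with Brown-Conrady lens distortion.
#
# Conventions: pixel origin at the upper-left image corner, x right, y down;
# camera frame right-handed with z along the principal axis (positive depth
# in front of the camera); p_cam = R %*% p_world + t.

#' Camera intrinsics with Brown-Conrady distortion
#'
#' Bundles the pinhole calibration matrix parameters (focal lengths and
#' principal point, in pixels) with the image size and the five Brown-Conrady
#' distortion coefficients (k1, k2, p1, p2, k3): radial terms k1..k3,
#' tangential terms p1, p2.
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param cx,cy Principal point in pixels; must lie inside the image.
#' @param width,height Image size in pixels.
#' @param distortion Numeric length-5 vector (k1, k2, p1, p2, k3); defaults
#'   to all zero (ideal pinhole).
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height,
                              distortion = c(0, 0, 0, 0, 0)) {
  stopifnot(fx > 0, fy > 0, width > 0, height > 0,
            cx >= 0, cx < width, cy >= 0, cy < height,
            length(distortion) == 5, all(is.finite(distortion)))
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = width, height = height,
                 distortion = as.numeric(distortion)),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics: fx=%.1f fy=%.1f cx=%.1f cy=%.1f (%dx%d)\n",
              x$fx, x$fy, x$cx, x$cy, as.integer(x$width), as.integer(x$height)))
  cat("  distortion (k1,k2,p1,p2,k3):", format(x$distortion, digits = 4), "\n")
  invisible(x)
}

#' Calibration matrix K of a camera
#' @param intr A `camera_intrinsics` object.
#' @return 3x3 upper-triangular calibration matrix.
#' @export
calibration_matrix <- function(intr) {
  matrix(c(intr$fx, 0, 0,
           0, intr$fy, 0,
           intr$cx, intr$cy, 1), 3, 3)
}

#' Camera extrinsics (world-to-camera transform)
#'
#' Pose of a camera in the world frame under the convention
#' `p_cam = R %*% p_world + t`. Either `t` or the camera centre `center`
#' (with `t = -R %*% center`) may be given.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation Translation 3-vector `t` (same units as world points).
#' @param center Optional camera centre in world coordinates; used to derive
#'   `t` when `translation` is missing.
#' @return An object of class `camera_extrinsics` with fields `R` and `t`.
#' @export
camera_extrinsics <- function(rotation, translation = NULL, center = NULL) {
  if (!is_rotation(rotation))
    stop("rotation must be a proper 3x3 rotation matrix (R'R = I, det = +1)")
  if (is.null(translation)) {
    if (is.null(center)) stop("supply either translation or center")
    translation <- -rotation %*% center
  }
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "camera_extrinsics")
}

#' @export
print.camera_extrinsics <- function(x, ...) {
  cat("camera_extrinsics: p_cam = R p_world + t\n")
  cat("  center (world):", format(-crossprod(x$R, x$t), digits = 5), "\n")
  invisible(x)
}

identity_extrinsics <- function() camera_extrinsics(diag(3), c(0, 0, 0))

#' Apply Brown-Conrady distortion to ideal normalized coordinates
#'
#' @param xy n x 2 matrix of ideal normalized image coordinates (x/z, y/z).
#' @param distortion Length-5 coefficient vector (k1, k2, p1, p2, k3).
#' @return n x 2 matrix of distorted normalized coordinates.
#' @keywords internal
#' @export
distort_normalized <- function(xy, distortion) {
  xy <- matrix(xy, ncol = 2)
  k1 <- distortion[1]; k2 <- distortion[2]
  p1 <- distortion[3]; p2 <- distortion[4]; k3 <- distortion[5]
  x <- xy[, 1]; y <- xy[, 2]
  r2 <- x^2 + y^2
  radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  xd <- x * radial + 2 * p1 * x * y + p2 * (r2 + 2 * x^2)
  yd <- y * radial + p1 * (r2 + 2 * y^2) + 2 * p2 * x * y
  cbind(xd, yd, deparse.level = 0)
}

#' Project world points into distorted pixel coordinates
#'
#' Transforms points to the camera frame, perspective-divides, applies
#' Brown-Conrady distortion, and maps through the calibration matrix.
#'
#' @param p_world 3-vector or n x 3 matrix of world points.
#' @param intr A `camera_intrinsics` object.
#' @param extr A `camera_extrinsics` object (default: identity, world frame
#'   equals camera frame).
#' @return n x 2 matrix of pixel coordinates (u, v).
#' @export
project_points <- function(p_world, intr, extr = identity_extrinsics()) {
  p_world <- matrix(p_world, ncol = 3)
  p_cam <- p_world %*% t(extr$R) + matrix(extr$t, nrow(p_world), 3, byrow = TRUE)
  z <- p_cam[, 3]
  bad <- which(z <= 0)
  if (length(bad) > 0)
    stop(sprintf("behind camera: %d point(s) with non-positive depth (first index %d)",
                 length(bad), bad[1]))
  xy <- cbind(p_cam[, 1] / z, p_cam[, 2] / z)
  xyd <- distort_normalized(xy, intr$distortion)
  cbind(intr$fx * xyd[, 1] + intr$cx,
        intr$fy * xyd[, 2] + intr$cy, deparse.level = 0)
}

#' Undistort pixel coordinates to normalized image coordinates
#'
#' Applies the inverse calibration matrix and inverts the Brown-Conrady
#' distortion polynomial by fixed-point iteration. With zero distortion this
#' reduces exactly to the closed form ((u - cx)/fx, (v - cy)/fy).
#'
#' @param px 2-vector or n x 2 matrix of pixel coordinates.
#' @param intr A `camera_intrinsics` object.
#' @param max_iter Maximum fixed-point iterations (default 20).
#' @param tol Convergence tolerance in normalized units (default 1e-10).
#' @return n x 2 matrix of normalized image coordinates (x/z, y/z).
#' @export
undistort_to_normalized <- function(px, intr, max_iter = 20L, tol = 1e-10) {
  px <- matrix(px, ncol = 2)
  if (!all(is.finite(px))) stop("pixel coordinates must be finite")
  x0 <- (px[, 1] - intr$cx) / intr$fx
  y0 <- (px[, 2] - intr$cy) / intr$fy
  d <- intr$distortion
  if (all(d == 0)) return(cbind(x0, y0, deparse.level = 0))
  k1 <- d[1]; k2 <- d[2]; p1 <- d[3]; p2 <- d[4]; k3 <- d[5]
  x <- x0; y <- y0
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    r2 <- x^2 + y^2
    radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
    dx <- 2 * p1 * x * y + p2 * (r2 + 2 * x^2)
    dy <- p1 * (r2 + 2 * y^2) + 2 * p2 * x * y
    xn <- (x0 - dx) / radial
    yn <- (y0 - dy) / radial
    delta <- max(abs(xn - x), abs(yn - y))
    x <- xn; y <- yn
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("undistortion fixed-point iteration did not converge below %g in %d iterations; returning best iterate",
                    tol, max_iter))
  cbind(x, y, deparse.level = 0)
}

#' Read a per-camera intrinsics configuration file
#'
#' YAML or JSON file mapping camera labels (e.g. "front", "lateral") to
#' fields fx, fy, cx, cy, width, height and dist (k1, k2, p1, p2, k3).
#'
#' @param path Path to a .yaml/.yml or .json config file.
#' @return Named list of `camera_intrinsics`.
#' @export
read_camera_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(cfg, function(cc) {
    dist <- if (is.null(cc$dist)) c(0, 0, 0, 0, 0) else as.numeric(unlist(cc$dist))
    camera_intrinsics(cc$fx, cc$fy, cc$cx, cc$cy, cc$width, cc$height, dist)
  })
}

#' Write a per-camera intrinsics configuration file (YAML)
#' @param cameras Named list of `camera_intrinsics`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_camera_config <- function(cameras, path) {
  cfg <- lapply(cameras, function(intr) {
    list(fx = intr$fx, fy = intr$fy, cx = intr$cx, cy = intr$cy,
         width = intr$width, height = intr$height,
         dist = as.numeric(intr$distortion))
  })
  yaml::write_yaml(cfg, path)
  invisible(path)
}
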