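# 3D reconstruction: DLT triangulation under self-calibrated geometry, and
# the orthogonal-combination reference fusion.

# Triangulate homogeneous normalized points (rows of X1, X2) under
# P1 = [I | 0] and a given 3x4 P2; returns n x 3 points in the camera-1
# frame, NA rows for points at infinity.
triangulate_pair <- function(X1, X2, P2) {
  n <- nrow(X1)
  out <- matrix(NA_real_, n, 3)
  P1 <- cbind(diag(3), c(0, 0, 0))
  for (i in seq_len(n)) {
    A <- rbind(X1[i, 1] * P1[3, ] - P1[1, ],
               X1[i, 2] * P1[3, ] - P1[2, ],
               X2[i, 1] * P2[3, ] - P2[1, ],
               X2[i, 2] * P2[3, ] - P2[2, ])
    Xh <- svd(A, nu = 0, nv = 4)$v[, 4]
    if (abs(Xh[4]) < 1e-12) next  # point at infinity
    out[i, ] <- Xh[1:3] / Xh[4]
  }
  out
}

#' Triangulate a correspondence by the Direct Linear Transform
#'
#' Builds the 4x4 DLT system from the two cross-product row pairs under
#' P1 = [I | 0] and P2 = [R21' | -R21' t21] and returns the dehomogenized
#' right singular vector of the smallest singular value. The output lives in
#' the camera-1 (frontal) frame at the arbitrary global scale fixed by
#' ||t21|| = 1.
#'
#' @param x1,x2 Normalized image coordinates (2-vectors or n x 2 matrices)
#'   in cameras 1 and 2.
#' @param geom A `stereo_geometry` (or any list with `R21`, `t21`).
#' @return n x 3 matrix of triangulated points; rows of NA where the
#'   homogeneous w-component vanished (point at infinity).
#' @export
triangulate_dlt <- function(x1, x2, geom) {
  x1 <- matrix(x1, ncol = 2); x2 <- matrix(x2, ncol = 2)
  P2 <- cbind(t(geom$R21), -crossprod(geom$R21, geom$t21))
  triangulate_pair(cbind(x1, 1), cbind(x2, 1), P2)
}

# Undistort one keypoint sequence to an (T*J) x 2 normalized coordinate
# matrix (column-major over joints) plus the visibility gate.
undistort_sequence <- function(kp, intr) {
  undistort_to_normalized(cbind(as.vector(kp$u), as.vector(kp$v)), intr)
}

#' Reconstruct a 3D pose sequence from two camera views
#'
#' Undistorts both keypoint streams to normalized coordinates, self-calibrates
#' the rig once per recording by robust essential-matrix estimation on
#' correspondences pooled over all frames and joints, and triangulates every
#' joint/frame where both detections pass the visibility gate.
#'
#' @param seq_front,seq_lat `keypoint_sequence` objects (equal frame counts
#'   and fps; camera 1 = frontal, camera 2 = lateral).
#' @param intr_front,intr_lat `camera_intrinsics` for the two cameras.
#' @param seed Integer RNG seed for the robust estimator.
#' @param visibility_threshold Minimum per-joint visibility in both views
#'   (default 0.5).
#' @param n_subsets Random samples for the robust estimator (default 2000).
#' @return List with `pose` (a `pose3d_sequence`, arbitrary scale, frontal
#'   camera frame) and `geometry` (the fitted `stereo_geometry`).
#' @export
reconstruct_sequence <- function(seq_front, seq_lat, intr_front, intr_lat,
                                 seed, visibility_threshold = 0.5,
                                 n_subsets = 2000L) {
  if (n_frames(seq_front) != n_frames(seq_lat))
    stop(sprintf("frame-count mismatch: frontal has %d frames, lateral has %d",
                 n_frames(seq_front), n_frames(seq_lat)))
  if (seq_front$fps != seq_lat$fps)
    stop("fps mismatch between the two keypoint streams; resample upstream")
  if (!identical(seq_front$joint_labels, seq_lat$joint_labels))
    stop("joint label mismatch between the two keypoint streams")
  T_ <- n_frames(seq_front); J <- length(seq_front$joint_labels)

  n1 <- undistort_sequence(seq_front, intr_front)
  n2 <- undistort_sequence(seq_lat, intr_lat)
  w <- pmin(as.vector(seq_front$visibility), as.vector(seq_lat$visibility))
  corrs <- correspondence_set(
    n1, n2,
    frame_index = rep(seq_len(T_) - 1L, J),
    joint_id = rep(seq_front$joint_labels, each = T_),
    weight = w)

  geom <- estimate_essential_lms(corrs, seed = seed, n_subsets = n_subsets,
                                 visibility_threshold = visibility_threshold)

  gate <- w >= visibility_threshold
  pts <- matrix(NA_real_, T_ * J, 3)
  if (any(gate)) {
    pts[gate, ] <- triangulate_dlt(n1[gate, , drop = FALSE],
                                   n2[gate, , drop = FALSE], geom)
  }
  valid <- gate & apply(is.finite(pts), 1, all)
  pts[!valid, ] <- 0
  coords <- array(pts, c(T_, J, 3))
  pose <- pose3d_sequence(coords, seq_front$joint_labels, seq_front$fps,
                          matrix(valid, T_, J))
  list(pose = pose, geometry = geom)
}

#' Orthogonal-combination reference fusion
#'
#' Baseline 3D reconstruction that assumes the two cameras are exactly
#' perpendicular (relative rotation (0 0 1; 0 1 0; -1 0 0) from the lateral
#' to the frontal camera): each joint's fused coordinates are
#' (x_front, y_front, x_lateral) in a frontal-camera-aligned frame, i.e. the
#' lateral camera's x-coordinate stands in for the frontal camera's depth.
#' Coordinates are in normalized-image units; the global scale is resolved
#' later by similarity alignment.
#'
#' @inheritParams reconstruct_sequence
#' @return A `pose3d_sequence`.
#' @export
orthogonal_fuse <- function(seq_front, seq_lat, intr_front, intr_lat,
                            visibility_threshold = 0.5) {
  if (n_frames(seq_front) != n_frames(seq_lat))
    stop(sprintf("frame-count mismatch: frontal has %d frames, lateral has %d",
                 n_frames(seq_front), n_frames(seq_lat)))
  T_ <- n_frames(seq_front); J <- length(seq_front$joint_labels)
  n1 <- undistort_sequence(seq_front, intr_front)
  n2 <- undistort_sequence(seq_lat, intr_lat)
  gate <- pmin(as.vector(seq_front$visibility),
               as.vector(seq_lat$visibility)) >= visibility_threshold
  pts <- cbind(n1[, 1], n1[, 2], n2[, 1])
  pts[!gate, ] <- 0
  pose3d_sequence(array(pts, c(T_, J, 3)), seq_front$joint_labels,
                  seq_front$fps, matrix(gate, T_, J))
}

#' The fixed perpendicular-rig rotation assumed by the orthogonal fusion
#'
#' Rotation from the lateral camera frame to the frontal camera frame when
#' the cameras are exactly 90 degrees apart (lateral camera on the subject's
#' right, both level).
#'
#' @return 3x3 rotation matrix (0 0 1; 0 1 0; -1 0 0).
#' @export
orthogonal_rig_rotation <- function() {
  matrix(c(0, 0, -1,
           0, 1, 0,
           1, 0, 0), 3, 3)
}
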