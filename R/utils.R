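# Small internal helpers shared across modules.

#' Run code with a temporarily seeded RNG
#'
#' Restores the caller's RNG state afterwards so seeded package functions do
#' not perturb the session's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Skew-symmetric (cross-product) matrix of a 3-vector
#' @noRd
skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

#' Check a 3x3 matrix is a proper rotation
#' @noRd
is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}

#' Angle of a rotation matrix in degrees
#' @noRd
rotation_angle_deg <- function(R) {
  c_ang <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, c_ang))) * 180 / pi
}

#' Angle between two rotations (geodesic distance) in degrees
#' @noRd
rotation_distance_deg <- function(R1, R2) rotation_angle_deg(crossprod(R1, R2))

#' Angle between two vectors in degrees (sign-insensitive optional)
#' @noRd
vector_angle_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(max(-1, min(1, ca))) * 180 / pi
}

#' Rotation about an axis through the origin (Rodrigues)
#' @noRd
axis_angle_rotation <- function(axis, angle_rad) {
  axis <- axis / sqrt(sum(axis^2))
  K <- skew3(axis)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' The 12-joint label set shared by reconstruction, ground truth and metrics
#'
#' The common subset of body landmarks tracked on both the camera and the
#' motion-capture side: shoulder, elbow, wrist, hip, knee and ankle, for the
#' left and right side.
#'
#' @return Character vector of 12 joint labels.
#' @export
joint_labels <- function() {
  c("left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle")
}

#' Map the 12 joint labels to 33-landmark pose indices (0-based ids 11-16, 23-28)
#' @noRd
landmark_ids <- function() {
  c(left_shoulder = 11L, right_shoulder = 12L,
    left_elbow = 13L, right_elbow = 14L,
    left_wrist = 15L, right_wrist = 16L,
    left_hip = 23L, right_hip = 24L,
    left_knee = 25L, right_knee = 26L,
    left_ankle = 27L, right_ankle = 28L)
}
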