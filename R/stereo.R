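# Self-calibration of the stereo rig from pooled keypoint correspondences.
#
# The essential matrix E relates normalized image coordinates of the two
# cameras through x1' E x2 = 0, where E = [t21]_x R21 and
# p_c1 = R21 p_c2 + t21 (camera 2 -> camera 1). E is estimated by the
# normalized 8-point algorithm inside a least-median-of-squares loop so that
# sporadic gross 2D mis-detections (which can carry high visibility) do not
# bias the geometry, then decomposed by SVD with cheirality resolution.

#' Build a correspondence set from two normalized keypoint tables
#'
#' @param x1,x2 n x 2 matrices of normalized image coordinates in camera 1
#'   (frontal) and camera 2 (lateral).
#' @param frame_index,joint_id Optional per-row annotations.
#' @param weight Per-row weight, the minimum of the two detection
#'   visibilities (default 1).
#' @return A `correspondence_set`: data frame with columns x1, y1, x2, y2,
#'   frame_index, joint_id, weight.
#' @export
correspondence_set <- function(x1, x2, frame_index = NA_integer_,
                               joint_id = NA_character_, weight = 1) {
  x1 <- matrix(x1, ncol = 2); x2 <- matrix(x2, ncol = 2)
  stopifnot(nrow(x1) == nrow(x2))
  out <- data.frame(x1 = x1[, 1], y1 = x1[, 2], x2 = x2[, 1], y2 = x2[, 2],
                    frame_index = frame_index, joint_id = joint_id,
                    weight = weight)
  class(out) <- c("correspondence_set", "data.frame")
  out
}

corr_h1 <- function(corrs) cbind(corrs$x1, corrs$y1, 1)
corr_h2 <- function(corrs) cbind(corrs$x2, corrs$y2, 1)

#' Sampson residual of correspondences under an essential matrix
#'
#' First-order geometric approximation of the squared distance of a
#' correspondence to the epipolar constraint manifold x1' E x2 = 0, in
#' squared normalized-coordinate units. Zero exactly when the constraint is
#' satisfied, and invariant to rescaling E.
#'
#' @param E 3x3 essential (or fundamental) matrix, nonzero.
#' @param corrs A `correspondence_set` (or anything with columns x1, y1,
#'   x2, y2).
#' @return Numeric vector of residuals, one per correspondence.
#' @export
sampson_residual <- function(E, corrs) {
  if (all(E == 0)) stop("E must be nonzero")
  X1 <- corr_h1(corrs); X2 <- corr_h2(corrs)
  Ex2 <- X2 %*% t(E)        # rows: E %*% x2
  Etx1 <- X1 %*% E          # rows: t(E) %*% x1
  num <- rowSums(X1 * Ex2)^2
  den <- Ex2[, 1]^2 + Ex2[, 2]^2 + Etx1[, 1]^2 + Etx1[, 2]^2
  num / den
}

# Isotropic (Hartley) conditioning transform: translate to centroid, scale
# mean distance to sqrt(2).
conditioning_transform <- function(X) {
  mu <- colMeans(X[, 1:2, drop = FALSE])
  d <- sqrt(rowSums((X[, 1:2, drop = FALSE] -
                       matrix(mu, nrow(X), 2, byrow = TRUE))^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  matrix(c(s, 0, 0,
           0, s, 0,
           -s * mu[1], -s * mu[2], 1), 3, 3)
}

# Linear 8-point solve on (possibly more than 8) correspondences with
# Hartley conditioning; returns the unconstrained 3x3 estimate or NULL when
# the design matrix is rank-deficient (degenerate sample).
eightpoint_solve <- function(X1, X2) {
  T1 <- conditioning_transform(X1)
  T2 <- conditioning_transform(X2)
  Y1 <- X1 %*% t(T1)
  Y2 <- X2 %*% t(T2)
  # row for x1' E x2 = 0 with E row-major: coefficients x1_i * x2_j
  A <- cbind(Y1[, 1] * Y2[, 1], Y1[, 1] * Y2[, 2], Y1[, 1] * Y2[, 3],
             Y1[, 2] * Y2[, 1], Y1[, 2] * Y2[, 2], Y1[, 2] * Y2[, 3],
             Y1[, 3] * Y2[, 1], Y1[, 3] * Y2[, 2], Y1[, 3] * Y2[, 3])
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] < 1e-12 * sv$d[1]) return(NULL)  # rank-deficient design
  e <- sv$v[, 9]
  Ec <- matrix(e, 3, 3, byrow = TRUE)
  t(T1) %*% Ec %*% T2
}

# Project a 3x3 matrix to the essential manifold: singular values
# (sigma, sigma, 0) with sigma the mean of the two largest; then normalize
# Frobenius norm to 1 and fix the sign so the largest-magnitude entry is
# positive.
project_to_essential <- function(E) {
  sv <- svd(E)
  s <- mean(sv$d[1:2])
  E <- sv$u %*% diag(c(s, s, 0)) %*% t(sv$v)
  E <- E / sqrt(sum(E^2))
  if (E[which.max(abs(E))] < 0) E <- -E
  E
}

#' Robust essential-matrix estimation by least median of squares
#'
#' Repeatedly samples 8 correspondences, solves the conditioned 8-point
#' linear system by SVD, projects onto the essential manifold, and scores
#' each candidate by the median Sampson residual over all correspondences.
#' The minimizer is refit once on its inliers (residuals within 2.5 robust
#' standard deviations, scale 1.4826 * sqrt(median residual)).
#'
#' @param corrs A `correspondence_set`; rows with weight below
#'   `visibility_threshold` are excluded. At least 8 usable rows required.
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @param n_subsets Number of random 8-point samples (default 2000).
#' @param visibility_threshold Minimum correspondence weight (default 0.5).
#' @return A `stereo_geometry` object: fields `E` (Frobenius-normalized),
#'   `R21`, `t21` (unit norm), `inlier_mask` (over the usable rows, aligned
#'   with `used` indexing into `corrs`), `median_residual`, `n_used`.
#' @export
estimate_essential_lms <- function(corrs, seed, n_subsets = 2000L,
                                   visibility_threshold = 0.5) {
  usable <- which(corrs$weight >= visibility_threshold)
  n <- length(usable)
  if (n < 8)
    stop(sprintf("need at least 8 usable correspondences, got %d (visibility threshold %.2f)",
                 n, visibility_threshold))
  cu <- corrs[usable, , drop = FALSE]
  X1 <- corr_h1(cu); X2 <- corr_h2(cu)

  best <- with_seed(seed, {
    best_med <- Inf; best_E <- NULL
    for (i in seq_len(n_subsets)) {
      idx <- sample.int(n, 8L)
      E0 <- eightpoint_solve(X1[idx, , drop = FALSE], X2[idx, , drop = FALSE])
      if (is.null(E0)) next  # degenerate sample: resample
      E0 <- project_to_essential(E0)
      med <- stats::median(sampson_residual(E0, cu))
      if (med < best_med) { best_med <- med; best_E <- E0 }
    }
    list(E = best_E, med = best_med)
  })
  if (is.null(best$E))
    stop("all sampled 8-point systems were degenerate; cannot estimate geometry")

  # robust scale from the LMS median; inliers within 2.5 sigma
  res <- sampson_residual(best$E, cu)
  scale <- 1.4826 * sqrt(best$med)
  inliers <- sqrt(res) <= 2.5 * scale
  E <- best$E
  if (sum(inliers) >= 8) {
    Ef <- eightpoint_solve(X1[inliers, , drop = FALSE], X2[inliers, , drop = FALSE])
    if (!is.null(Ef)) E <- project_to_essential(Ef)
  }
  med_final <- stats::median(sampson_residual(E, cu))

  dec <- decompose_essential(E, cu[inliers, , drop = FALSE])
  structure(list(E = E, R21 = dec$R21, t21 = dec$t21,
                 inlier_mask = inliers, used = usable,
                 median_residual = med_final, n_used = n),
            class = "stereo_geometry")
}

#' @export
print.stereo_geometry <- function(x, ...) {
  cat("stereo_geometry (self-calibrated two-view rig)\n")
  cat(sprintf("  inter-camera rotation: %.2f deg; inliers: %d / %d; median Sampson residual: %.3g\n",
              rotation_angle_deg(x$R21), sum(x$inlier_mask), x$n_used,
              x$median_residual))
  invisible(x)
}

#' Decompose an essential matrix into relative rotation and translation
#'
#' Enumerates the four (R, +/-t) candidates of the SVD factorization and
#' selects the one under which the largest number of correspondences
#' triangulates with positive depth in both cameras (cheirality).
#'
#' @param E 3x3 essential matrix; projected onto the essential manifold
#'   first if it does not already satisfy the constraints.
#' @param corrs Correspondences used for the cheirality vote (inliers).
#' @return List with `R21` (proper rotation) and `t21` (unit 3-vector),
#'   the transform p_c1 = R21 p_c2 + t21.
#' @export
decompose_essential <- function(E, corrs) {
  E <- project_to_essential(E)
  sv <- svd(E)
  U <- sv$u; V <- sv$v
  if (det(U) < 0) U <- -U
  if (det(V) < 0) V <- -V
  W <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  Ra <- U %*% W %*% t(V)
  Rb <- U %*% t(W) %*% t(V)
  tu <- U[, 3]
  cands <- list(list(R = Ra, t = tu), list(R = Ra, t = -tu),
                list(R = Rb, t = tu), list(R = Rb, t = -tu))
  X1 <- corr_h1(corrs); X2 <- corr_h2(corrs)
  votes <- vapply(cands, function(cd) {
    P2 <- cbind(t(cd$R), -crossprod(cd$R, cd$t))
    pts <- triangulate_pair(X1, X2, P2)
    z1 <- pts[, 3]
    pc2 <- cbind(pts, 1) %*% t(P2)
    sum(z1 > 0 & pc2[, 3] > 0, na.rm = TRUE)
  }, numeric(1))
  top <- max(votes)
  if (sum(votes == top) > 1)
    stop("cheirality ambiguous: multiple decompositions front-project equally (degenerate geometry)")
  best <- cands[[which.max(votes)]]
  list(R21 = best$R, t21 = best$t / sqrt(sum(best$t^2)))
}

#' Serialize a stereo geometry to JSON
#' @param geom A `stereo_geometry`.
#' @param path Optional output path; if omitted the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
stereo_geometry_json <- function(geom, path = NULL) {
  obj <- list(E = geom$E, R21 = geom$R21, t21 = geom$t21,
              n_inliers = sum(geom$inlier_mask), n_used = geom$n_used,
              median_sampson_residual = geom$median_residual,
              inter_camera_angle_deg = rotation_angle_deg(geom$R21))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
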