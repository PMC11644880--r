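# Evaluation against ground truth: similarity alignment and RMSE/MPJPE,
# 3D joint angles, angle RMSE, repetition extreme summaries, and paired
# significance testing between methods.

#' Least-squares similarity alignment of a reconstruction to ground truth
#'
#' Closed-form (Umeyama) fit of one similarity transform
#' `gt ~ s * R %*% recon + t` over all joint-frame pairs valid in both
#' sequences, pooled; reflection is forbidden (det R = +1). Scale is included
#' because triangulated output carries an arbitrary global scale.
#'
#' @param recon,gt `pose3d_sequence` objects with identical joint labels and
#'   frame counts; `gt` in millimetres.
#' @return An `alignment_report`: `scale`, `rotation`, `translation`,
#'   `rmse_mm` (root of the mean squared Euclidean joint error after the
#'   transform, over all valid joint-frames; comparable to MPJPE),
#'   `n_points`, and `aligned` (the transformed reconstruction as a
#'   `pose3d_sequence`).
#' @export
similarity_align <- function(recon, gt) {
  stopifnot(identical(recon$joint_labels, gt$joint_labels))
  if (n_frames(recon) != n_frames(gt))
    stop(sprintf("frame-count mismatch: recon %d vs gt %d",
                 n_frames(recon), n_frames(gt)))
  both <- recon$valid_mask & gt$valid_mask
  idx <- which(both)
  T_ <- n_frames(recon); J <- length(recon$joint_labels)
  X <- matrix(recon$coords, T_ * J, 3)[idx, , drop = FALSE]
  Y <- matrix(gt$coords, T_ * J, 3)[idx, , drop = FALSE]
  n <- nrow(X)
  if (n < 3) stop("degenerate alignment: fewer than 3 shared valid points")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  var_x <- sum(Xc^2) / n
  S <- crossprod(Yc, Xc) / n         # covariance of gt vs recon
  sv <- svd(S)
  if (sv$d[2] < 1e-15 * max(sv$d[1], 1))
    stop("degenerate alignment: shared valid points are collinear")
  D <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% D %*% t(sv$v)
  s <- sum(diag(D %*% diag(sv$d))) / var_x
  if (s <= 0) stop("degenerate alignment: non-positive fitted scale")
  t_ <- my - s * as.vector(R %*% mx)

  all_pts <- matrix(recon$coords, T_ * J, 3)
  mapped <- s * all_pts %*% t(R) + matrix(t_, T_ * J, 3, byrow = TRUE)
  res2 <- rowSums((mapped[idx, , drop = FALSE] - Y)^2)
  rmse <- sqrt(mean(res2))
  aligned <- pose3d_sequence(array(mapped, c(T_, J, 3)), recon$joint_labels,
                             recon$fps, recon$valid_mask)
  structure(list(scale = s, rotation = R, translation = t_,
                 rmse_mm = rmse, n_points = n,
                 n_frames = T_, n_joints = J, aligned = aligned),
            class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("alignment_report: rmse = %.3f mm over %d valid joint-frames (scale %.4g)\n",
              x$rmse_mm, x$n_points, x$scale))
  invisible(x)
}

#' 3D joint angle at a vertex
#'
#' Interior angle at vertex B spanned by points A and C: the arccos of the
#' clamped normalized dot product of (A - B) and (C - B), in degrees.
#' Invariant under global rotation, translation and positive scaling, so no
#' alignment is needed before computing angles.
#'
#' @param A,C End points (3-vectors or n x 3 matrices).
#' @param B Vertex (same shape).
#' @return Angle(s) in degrees in [0, 180]; NA where a limb vector has zero
#'   length.
#' @export
joint_angle <- function(A, B, C) {
  A <- matrix(A, ncol = 3); B <- matrix(B, ncol = 3); C <- matrix(C, ncol = 3)
  u <- A - B; v <- C - B
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  ca <- rowSums(u * v) / (nu * nv)
  ca[nu == 0 | nv == 0] <- NA
  rad2deg(acos(pmin(1, pmax(-1, ca))))
}

# Triples defining the squat-relevant angles: interior angle at the vertex.
angle_definitions <- function() {
  list(
    left_knee  = c("left_hip", "left_knee", "left_ankle"),
    right_knee = c("right_hip", "right_knee", "right_ankle"),
    left_hip   = c("left_shoulder", "left_hip", "left_knee"),
    right_hip  = c("right_shoulder", "right_hip", "right_knee")
  )
}

#' Knee/hip angle trajectory of a pose sequence
#'
#' @param pose A `pose3d_sequence` with the 12-joint label set.
#' @param kind One of "left_knee", "right_knee", "left_hip", "right_hip":
#'   knee = interior angle hip-knee-ankle, hip = shoulder-hip-knee.
#' @return An `angle_trajectory`: numeric degrees per frame with attributes
#'   `fps`, `kind`, `valid` (logical; FALSE where any defining joint is
#'   invalid or a limb vector degenerate).
#' @export
angle_trajectory <- function(pose, kind = c("left_knee", "right_knee",
                                            "left_hip", "right_hip")) {
  kind <- match.arg(kind)
  triple <- angle_definitions()[[kind]]
  ji <- match(triple, pose$joint_labels)
  if (anyNA(ji)) stop("pose lacks joints: ", paste(triple[is.na(ji)], collapse = ", "))
  ang <- joint_angle(pose$coords[, ji[1], ], pose$coords[, ji[2], ],
                     pose$coords[, ji[3], ])
  valid <- pose$valid_mask[, ji[1]] & pose$valid_mask[, ji[2]] &
    pose$valid_mask[, ji[3]] & !is.na(ang)
  structure(ang, fps = pose$fps, kind = kind, valid = valid,
            class = "angle_trajectory")
}

#' RMSE between two angle trajectories (degrees)
#'
#' Computed on the time-aligned trajectories directly: joint angles are
#' similarity-invariant, so no spatial alignment is involved.
#'
#' @param recon_angles,gt_angles Equal-length `angle_trajectory` objects (or
#'   plain numeric vectors).
#' @return RMSE in degrees over frames valid in both.
#' @export
angle_rmse <- function(recon_angles, gt_angles) {
  stopifnot(length(recon_angles) == length(gt_angles))
  v1 <- attr(recon_angles, "valid"); v2 <- attr(gt_angles, "valid")
  if (is.null(v1)) v1 <- !is.na(recon_angles)
  if (is.null(v2)) v2 <- !is.na(gt_angles)
  ok <- v1 & v2
  if (!any(ok)) stop("no overlapping valid frames between the two angle trajectories")
  sqrt(mean((as.numeric(recon_angles)[ok] - as.numeric(gt_angles)[ok])^2))
}

# Local extrema with a prominence and separation constraint. Prominence of a
# peak: height above the higher of the two lowest points separating it from
# higher terrain (the standard topographic definition).
find_prominent_peaks <- function(x, min_prominence, min_separation) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(i) {
    left_min <- x[i]; j <- i
    while (j > 1 && x[j] <= x[i]) { left_min <- min(left_min, x[j]); j <- j - 1 }
    if (x[j] <= x[i]) left_min <- min(left_min, x[j])  # hit the edge
    right_min <- x[i]; j <- i
    while (j < n && x[j] <= x[i]) { right_min <- min(right_min, x[j]); j <- j + 1 }
    if (x[j] <= x[i]) right_min <- min(right_min, x[j])
    x[i] - max(left_min, right_min)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) <= 1) return(keep)
  # enforce separation, preferring higher peaks
  ord <- keep[order(x[keep], decreasing = TRUE)]
  accepted <- integer(0)
  for (i in ord) {
    if (all(abs(i - accepted) >= min_separation)) accepted <- c(accepted, i)
  }
  sort(accepted)
}

#' Mean of the first repetition extremes of an angle trajectory
#'
#' Detects local maxima (or, with `troughs = TRUE`, local minima) with a
#' minimum prominence and minimum temporal separation and returns the mean
#' value of the first `n_peaks` in time order. For interior knee/hip angles
#' the squat repetitions appear as troughs (the angle dips at the bottom of
#' each squat), so the repetition summary used to discriminate exercise
#' variants is `peak_summary(x, troughs = TRUE)`.
#'
#' @param angles An `angle_trajectory` (or numeric vector with an `fps`
#'   attribute / `fps` argument).
#' @param n_peaks Number of leading extremes to average (default 3).
#' @param min_prominence Minimum prominence in degrees (default 10).
#' @param min_separation_s Minimum separation between extremes in seconds
#'   (default 1).
#' @param troughs If TRUE detect local minima instead of maxima.
#' @param fps Frame rate; taken from the trajectory's attribute if absent.
#' @return Mean extreme value in degrees.
#' @export
peak_summary <- function(angles, n_peaks = 3L, min_prominence = 10,
                         min_separation_s = 1, troughs = FALSE, fps = NULL) {
  if (is.null(fps)) fps <- attr(angles, "fps")
  if (is.null(fps)) stop("fps must be supplied (or present as an attribute)")
  x <- as.numeric(angles)
  valid <- attr(angles, "valid")
  if (!is.null(valid)) x[!valid] <- NA
  # bridge isolated NAs so extrema detection sees a continuous signal
  if (anyNA(x)) {
    ok <- which(!is.na(x))
    if (length(ok) < 2) stop("too few valid samples for peak detection")
    x <- stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
  }
  sig <- if (troughs) -x else x
  idx <- find_prominent_peaks(sig, min_prominence,
                              max(1, round(min_separation_s * fps)))
  if (length(idx) < n_peaks)
    stop(sprintf("found only %d extreme(s) with prominence >= %g deg; %d requested",
                 length(idx), min_prominence, n_peaks))
  mean(x[idx[seq_len(n_peaks)]])
}

#' Paired comparison of two methods' per-recording scores
#'
#' Two-sided paired t-test on per-recording scores (the recording is the
#' pairing unit), significance level 0.05. All-zero differences return
#' p = 1 by convention.
#'
#' @param scores_a,scores_b Equal-length numeric vectors of per-recording
#'   scores for the two methods.
#' @param alpha Significance level (default 0.05).
#' @return List with `t`, `p_value`, `significant`, `mean_difference`, `n`.
#' @export
compare_methods <- function(scores_a, scores_b, alpha = 0.05) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2)
  d <- scores_a - scores_b
  if (all(d == 0)) {
    return(list(t = 0, p_value = 1, significant = FALSE,
                mean_difference = 0, n = length(d)))
  }
  if (stats::sd(d) == 0) {
    # constant nonzero shift: t is infinite, p underflows to 0
    return(list(t = sign(mean(d)) * Inf, p_value = 0, significant = TRUE,
                mean_difference = mean(d), n = length(d)))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value < alpha,
       mean_difference = unname(tt$estimate), n = length(d))
}
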