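# Synthetic study conditions: ground-truth squat kinematics for three
# exercise variants, a virtual two-camera rig ~90 degrees apart, realistic
# detection noise, and an emulated noisy monocular-depth baseline. This is
# the validation bed standing in for a private motion-capture dataset.
#
# The skeleton is a stylized planar kinematic chain per body side (sagittal
# plane), with the lateral weight shift of variant E3 realised as a rigid
# frontal-plane lean about the feet centre. Interior knee and hip angles are
# driven directly by a raised-cosine repetition cycle between a standing
# value and a configured bottom-of-squat value, so the generated angle
# extremes -- and the between-variant gaps used for exercise-error
# discrimination -- are exact by construction.

#' Squat scenario: ground-truth kinematic parameters
#'
#' Variants: E1 = correct execution (symmetric, moderate depth); E2 =
#' excessive forward lean (extra trunk pitch at the bottom, deeper knee
#' flexion); E3 = lateral weight shift to the right (asymmetric knee
#' flexion plus a rigid body lean), also with deeper knee flexion. Defaults
#' configure a 20 degree gap between E1 and E2/E3 in the bottom-of-squat
#' knee angle and a 10 degree gap between E2 and E3 in the bottom hip angle.
#'
#' @param variant "E1", "E2" or "E3".
#' @param reps Repetitions per trial (default 10).
#' @param duration_s Trial length in seconds (default 30; cadence =
#'   reps/duration).
#' @param fps Frame rate (default 30).
#' @param standing_knee_deg Interior knee angle when standing (default 175).
#' @param peak_knee_flexion Knee flexion at the bottom of the squat, degrees
#'   from straight; bottom interior knee angle = 180 - flexion. Defaults:
#'   40 (E1), 60 (E2, E3).
#' @param trunk_lean_extra Extra bottom-of-squat hip flexion for E2 in
#'   degrees (default 15; zero unless variant is E2).
#' @param lateral_shift Peak lateral pelvis displacement for E3 in mm
#'   (default 120; zero unless variant is E3).
#' @param knee_asymmetry Additional right-knee flexion for E3 in degrees
#'   (default 10; zero unless variant is E3).
#' @param e3_hip_extra Extra bottom hip flexion for E3 beyond E2's, in
#'   degrees (default 10): sets the E2-vs-E3 hip-angle gap.
#' @param segments Named list of segment lengths in mm: trunk, thigh, shank,
#'   upper_arm, forearm, shoulder_width, hip_width, ankle_height.
#' @param seed Scenario seed (recorded; the GT kinematics are deterministic).
#' @return A `squat_scenario`.
#' @export
squat_scenario <- function(variant = c("E1", "E2", "E3"), reps = 10L,
                           duration_s = 30, fps = 30,
                           standing_knee_deg = 175,
                           peak_knee_flexion = NULL,
                           trunk_lean_extra = NULL,
                           lateral_shift = NULL,
                           knee_asymmetry = NULL,
                           e3_hip_extra = 10,
                           segments = NULL, seed = 1L) {
  variant <- match.arg(variant)
  if (is.null(peak_knee_flexion))
    peak_knee_flexion <- if (variant == "E1") 40 else 60
  if (is.null(trunk_lean_extra)) trunk_lean_extra <- if (variant == "E2") 15 else 0
  if (is.null(lateral_shift)) lateral_shift <- if (variant == "E3") 120 else 0
  if (is.null(knee_asymmetry)) knee_asymmetry <- if (variant == "E3") 10 else 0
  if (variant != "E2" && trunk_lean_extra != 0)
    stop("trunk_lean_extra is an E2 parameter; must be zero for ", variant)
  if (variant != "E3" && (lateral_shift != 0 || knee_asymmetry != 0))
    stop("lateral_shift/knee_asymmetry are E3 parameters; must be zero for ", variant)
  seg_default <- list(trunk = 500, thigh = 420, shank = 410, upper_arm = 280,
                      forearm = 250, shoulder_width = 380, hip_width = 320,
                      ankle_height = 80)
  if (!is.null(segments)) seg_default[names(segments)] <- segments
  stopifnot(all(unlist(seg_default) > 0), reps >= 1, duration_s > 0, fps > 0,
            peak_knee_flexion > 0, peak_knee_flexion < 180 - (180 - standing_knee_deg))
  structure(list(variant = variant, reps = as.integer(reps),
                 duration_s = duration_s, fps = fps,
                 cadence_hz = reps / duration_s,
                 standing_knee_deg = standing_knee_deg,
                 peak_knee_flexion = peak_knee_flexion,
                 trunk_lean_extra = trunk_lean_extra,
                 lateral_shift = lateral_shift,
                 knee_asymmetry = knee_asymmetry,
                 e3_hip_extra = e3_hip_extra,
                 segments = seg_default, seed = as.integer(seed)),
            class = "squat_scenario")
}

#' @export
print.squat_scenario <- function(x, ...) {
  cat(sprintf("squat_scenario %s: %d reps / %gs @ %g fps; bottom knee %g deg, bottom hip %g deg\n",
              x$variant, x$reps, x$duration_s, x$fps,
              scenario_bottom_knee(x)["left"], scenario_bottom_hip(x)))
  invisible(x)
}

# Configured bottom-of-squat interior knee angle per side, degrees.
scenario_bottom_knee <- function(scn) {
  left <- 180 - scn$peak_knee_flexion
  right <- 180 - (scn$peak_knee_flexion + scn$knee_asymmetry)
  c(left = left, right = right)
}

# Configured bottom-of-squat interior hip angle (both sides), degrees.
# E1 baseline 140; E2 subtracts the extra trunk lean; E3 subtracts E2's
# default lean plus e3_hip_extra, setting the configured E2-E3 gap.
scenario_bottom_hip <- function(scn) {
  base <- 140
  switch(scn$variant,
         E1 = base,
         E2 = base - scn$trunk_lean_extra,
         E3 = base - 15 - scn$e3_hip_extra)
}

#' Generate ground-truth squat kinematics
#'
#' Deterministic closed-form kinematics: interior knee and hip angles follow
#' a raised-cosine cycle between standing and the configured bottom values;
#' each side is a planar chain (ankle -> knee -> hip -> shoulder, arms
#' hanging with a fixed elbow angle); E3 additionally applies a rigid
#' frontal-plane lean about the feet centre (which preserves all interior
#' angles exactly). World frame: feet centre at the origin, y up, z towards
#' the frontal camera; units mm.
#'
#' @param scn A `squat_scenario`.
#' @return A `pose3d_sequence` (12 joints, mm, at `scn$fps`).
#' @export
generate_squat <- function(scn) {
  T_ <- round(scn$duration_s * scn$fps)
  t <- (seq_len(T_) - 1) / scn$fps
  cyc <- (1 - cos(2 * pi * scn$cadence_hz * t)) / 2  # 0 standing .. 1 bottom

  seg <- scn$segments
  bk <- scenario_bottom_knee(scn)
  bh <- scenario_bottom_hip(scn)
  standing_hip <- 175

  labels <- joint_labels()
  coords <- array(0, c(T_, 12, 3))
  side_sign <- c(left = 1, right = -1)  # +x = subject's left

  for (side in c("left", "right")) {
    sx <- side_sign[[side]]
    kappa <- scn$standing_knee_deg - (scn$standing_knee_deg - bk[[side]]) * cyc
    eta <- standing_hip - (standing_hip - bh) * cyc
    flex <- deg2rad(180 - kappa)
    a <- flex / 2                      # shank forward tilt from vertical
    b <- flex - a                      # thigh backward tilt from vertical
    g <- deg2rad(180 - eta) - b        # trunk forward pitch from vertical

    ankle_x <- sx * seg$hip_width / 2
    ankle <- cbind(rep(ankle_x, T_), rep(seg$ankle_height, T_), 0)
    knee <- ankle + cbind(0, seg$shank * cos(a), seg$shank * sin(a))
    hip <- knee + cbind(0, seg$thigh * cos(b), -seg$thigh * sin(b))
    shoulder <- hip + cbind(0, seg$trunk * cos(g), seg$trunk * sin(g))
    shoulder[, 1] <- sx * seg$shoulder_width / 2
    # arms: upper arm swings slightly forward with depth, elbow nearly straight
    arm_pitch <- deg2rad(25) * cyc
    elbow <- shoulder + cbind(0, -seg$upper_arm * cos(arm_pitch),
                              seg$upper_arm * sin(arm_pitch))
    fore_pitch <- arm_pitch + deg2rad(15)  # fixed 165 deg interior elbow angle
    wrist <- elbow + cbind(0, -seg$forearm * cos(fore_pitch),
                           seg$forearm * sin(fore_pitch))
    ji <- function(nm) match(paste0(side, "_", nm), labels)
    coords[, ji("ankle"), ] <- ankle
    coords[, ji("knee"), ] <- knee
    coords[, ji("hip"), ] <- hip
    coords[, ji("shoulder"), ] <- shoulder
    coords[, ji("elbow"), ] <- elbow
    coords[, ji("wrist"), ] <- wrist
  }

  if (scn$variant == "E3" && scn$lateral_shift != 0) {
    # rigid lean towards the subject's right (-x) about the feet centre
    hip_h <- seg$ankle_height + seg$shank + seg$thigh
    rho <- atan2(scn$lateral_shift, hip_h)
    for (i in seq_len(T_)) {
      Rz <- matrix(c(cos(rho * cyc[i]), -sin(rho * cyc[i]), 0,
                     sin(rho * cyc[i]), cos(rho * cyc[i]), 0,
                     0, 0, 1), 3, 3, byrow = TRUE)
      coords[i, , ] <- coords[i, , ] %*% t(Rz)
    }
  }

  if (min(coords[, , 2]) < 0)
    stop("infeasible geometry: a joint dropped below the floor")
  pose3d_sequence(coords, labels, scn$fps)
}

#' Virtual stereo rig specification
#'
#' Two level pinhole cameras on tripods: a frontal camera on the +z world
#' axis and a lateral camera separated by `azimuth_deg` (default 90, placed
#' on the subject's right at -x), both at `height_mm` and `distance_mm`
#' from the feet centre, in portrait orientation.
#'
#' @param azimuth_deg Inter-camera azimuth in degrees (default 90).
#' @param height_mm Camera height (default 1300).
#' @param distance_mm Horizontal camera-subject distance (default 2500).
#' @param intr_front,intr_lat `camera_intrinsics`; default portrait
#'   1080x1920, fx = fy = 1400 px, centred principal point, no distortion.
#' @return A `rig_spec` with per-camera intrinsics and extrinsics.
#' @export
rig_spec <- function(azimuth_deg = 90, height_mm = 1300, distance_mm = 2500,
                     intr_front = NULL, intr_lat = NULL) {
  default_intr <- function() camera_intrinsics(1400, 1400, 540, 960, 1080, 1920)
  if (is.null(intr_front)) intr_front <- default_intr()
  if (is.null(intr_lat)) intr_lat <- default_intr()

  look_at_level <- function(center) {
    # level camera looking horizontally at the vertical axis through the
    # subject; image y points down
    fwd <- c(-center[1], 0, -center[3])
    fwd <- fwd / sqrt(sum(fwd^2))
    down <- c(0, -1, 0)
    right <- c(down[2] * fwd[3] - down[3] * fwd[2],
               down[3] * fwd[1] - down[1] * fwd[3],
               down[1] * fwd[2] - down[2] * fwd[1])
    R <- rbind(right, down, fwd)
    dimnames(R) <- NULL
    camera_extrinsics(R, center = center)
  }
  c_front <- c(0, height_mm, distance_mm)
  az <- deg2rad(azimuth_deg)
  # rotate the frontal camera position about the vertical axis towards the
  # subject's right (-x for a 90 degree azimuth)
  c_lat <- c(-sin(az) * distance_mm, height_mm, cos(az) * distance_mm)
  structure(list(front = list(intr = intr_front, extr = look_at_level(c_front)),
                 lateral = list(intr = intr_lat, extr = look_at_level(c_lat)),
                 azimuth_deg = azimuth_deg, height_mm = height_mm,
                 distance_mm = distance_mm),
            class = "rig_spec")
}

#' @export
print.rig_spec <- function(x, ...) {
  cat(sprintf("rig_spec: azimuth %g deg, height %g mm, distance %g mm\n",
              x$azimuth_deg, x$height_mm, x$distance_mm))
  invisible(x)
}

#' True relative geometry of a rig (lateral camera -> frontal camera)
#'
#' @param rig A `rig_spec`.
#' @return List with `R21`, `t21` (unit norm) and `E` (Frobenius-normalized,
#'   sign-fixed essential matrix) of the ground-truth rig.
#' @export
rig_relative_geometry <- function(rig) {
  R1 <- rig$front$extr$R; t1 <- rig$front$extr$t
  R2 <- rig$lateral$extr$R; t2 <- rig$lateral$extr$t
  R21 <- R1 %*% t(R2)
  t21 <- t1 - as.vector(R21 %*% t2)
  t21u <- t21 / sqrt(sum(t21^2))
  E <- skew3(t21u) %*% R21
  E <- E / sqrt(sum(E^2))
  if (E[which.max(abs(E))] < 0) E <- -E
  list(R21 = R21, t21 = t21u, E = E)
}

#' Detection noise specification
#'
#' @param pixel_sigma Gaussian noise on detections in pixels (default 2).
#' @param dropout_prob Probability a detection is dropped: its visibility is
#'   drawn below the gate (default 0.02).
#' @param outlier_prob Probability a detection is replaced by a gross
#'   outlier drawn uniformly in a distractor region of the image while its
#'   visibility stays high -- emulating confident mis-detections such as
#'   background clothing mistaken for a limb. Default 0: such confident
#'   gross mis-detections arise from exceptional scene clutter, not from
#'   ordinary detector noise; robustness analyses switch them on
#'   explicitly.
#' @param mono_depth_sigma_scale Multiplier (>= 1) on the noise of the
#'   emulated monocular depth coordinate relative to in-plane noise
#'   (default 5).
#' @return A `noise_spec`.
#' @export
noise_spec <- function(pixel_sigma = 2, dropout_prob = 0.02,
                       outlier_prob = 0, mono_depth_sigma_scale = 5) {
  stopifnot(pixel_sigma >= 0, dropout_prob >= 0, dropout_prob < 1,
            outlier_prob >= 0, outlier_prob < 1, mono_depth_sigma_scale >= 1)
  structure(list(pixel_sigma = pixel_sigma, dropout_prob = dropout_prob,
                 outlier_prob = outlier_prob,
                 mono_depth_sigma_scale = mono_depth_sigma_scale),
            class = "noise_spec")
}

# Project one pose through one camera; returns list(u, v, behind) matrices.
project_pose <- function(gt, cam) {
  T_ <- n_frames(gt); J <- length(gt$joint_labels)
  pts <- matrix(gt$coords, T_ * J, 3)
  p_cam <- pts %*% t(cam$extr$R) + matrix(cam$extr$t, T_ * J, 3, byrow = TRUE)
  behind <- p_cam[, 3] <= 0
  u <- v <- rep(NA_real_, T_ * J)
  if (any(!behind)) {
    px <- project_points(pts[!behind, , drop = FALSE], cam$intr, cam$extr)
    u[!behind] <- px[, 1]; v[!behind] <- px[, 2]
  }
  list(u = matrix(u, T_, J), v = matrix(v, T_, J),
       behind = matrix(behind, T_, J))
}

render_one_view <- function(gt, cam, noise, camera_label) {
  pr <- project_pose(gt, cam)
  T_ <- n_frames(gt); J <- length(gt$joint_labels)
  u <- pr$u + matrix(stats::rnorm(T_ * J, 0, noise$pixel_sigma), T_, J)
  v <- pr$v + matrix(stats::rnorm(T_ * J, 0, noise$pixel_sigma), T_, J)
  vis <- matrix(stats::runif(T_ * J, 0.9, 1.0), T_, J)
  drop <- matrix(stats::runif(T_ * J) < noise$dropout_prob, T_, J) | pr$behind
  vis[drop] <- stats::runif(sum(drop), 0, 0.3)
  out <- matrix(stats::runif(T_ * J) < noise$outlier_prob, T_, J) & !drop
  n_out <- sum(out)
  if (n_out > 0) {
    # distractor region: a band along the image's right quarter
    w <- cam$intr$width; h <- cam$intr$height
    u[out] <- stats::runif(n_out, 0.7 * w, w)
    v[out] <- stats::runif(n_out, 0.2 * h, 0.8 * h)
  }
  u[!is.finite(u)] <- 0; v[!is.finite(v)] <- 0
  kp <- keypoint_sequence(u, v, vis, gt$joint_labels, gt$fps,
                          c(cam$intr$width, cam$intr$height),
                          camera = camera_label)
  attr(kp, "outlier_mask") <- out
  attr(kp, "dropout_mask") <- drop
  kp
}

#' Render a ground-truth pose through the virtual rig
#'
#' Projects every joint into both cameras (full pinhole + distortion model),
#' adds Gaussian pixel noise, dropout (visibility drawn below the gate) and
#' sporadic confident outliers (position replaced, visibility kept high).
#' The two cameras use independent RNG streams derived from `seed`.
#'
#' @param gt A `pose3d_sequence` in mm (world frame).
#' @param rig A `rig_spec`.
#' @param noise A `noise_spec`.
#' @param seed Integer seed.
#' @return List with `front` and `lateral` `keypoint_sequence` objects; each
#'   carries attributes `outlier_mask` and `dropout_mask` (T x J logical)
#'   for diagnostic use.
#' @export
render_views <- function(gt, rig, noise = noise_spec(), seed = 1L) {
  check_rig_visibility(gt, rig)
  front <- with_seed(seed, render_one_view(gt, rig$front, noise, "front"))
  lateral <- with_seed(seed + 1000003L,
                       render_one_view(gt, rig$lateral, noise, "lateral"))
  list(front = front, lateral = lateral)
}

check_rig_visibility <- function(gt, rig) {
  for (nm in c("front", "lateral")) {
    cam <- rig[[nm]]
    pr <- project_pose(gt, cam)
    if (any(pr$behind))
      stop("rig visibility check failed: joints behind the ", nm, " camera")
    if (min(pr$u, na.rm = TRUE) < 0 || max(pr$u, na.rm = TRUE) > cam$intr$width ||
        min(pr$v, na.rm = TRUE) < 0 || max(pr$v, na.rm = TRUE) > cam$intr$height)
      stop("rig visibility check failed: skeleton leaves the ", nm, " camera's image")
  }
  invisible(TRUE)
}

#' Emulate a noisy monocular 3D baseline
#'
#' Expresses the ground truth in one camera's frame and perturbs it with
#' pixel-equivalent in-plane noise and `mono_depth_sigma_scale` times larger
#' depth noise -- a stand-in for single-view 3D landmark output, whose depth
#' axis is the unreliable one.
#'
#' @param gt A `pose3d_sequence` in mm (world frame).
#' @param rig A `rig_spec`.
#' @param noise A `noise_spec`.
#' @param camera "front" or "lateral".
#' @param seed Integer seed.
#' @return A `pose3d_sequence` in that camera's frame (mm).
#' @export
emulate_monocular3d <- function(gt, rig, noise = noise_spec(),
                                camera = c("front", "lateral"), seed = 1L) {
  camera <- match.arg(camera)
  cam <- rig[[camera]]
  T_ <- n_frames(gt); J <- length(gt$joint_labels)
  pts <- matrix(gt$coords, T_ * J, 3)
  p_cam <- pts %*% t(cam$extr$R) + matrix(cam$extr$t, T_ * J, 3, byrow = TRUE)
  # pixel-equivalent in-plane noise at the subject's mean depth
  sigma_mm <- noise$pixel_sigma / cam$intr$fx * mean(p_cam[, 3])
  with_seed(seed, {
    p_cam[, 1] <- p_cam[, 1] + stats::rnorm(T_ * J, 0, sigma_mm)
    p_cam[, 2] <- p_cam[, 2] + stats::rnorm(T_ * J, 0, sigma_mm)
    p_cam[, 3] <- p_cam[, 3] +
      stats::rnorm(T_ * J, 0, sigma_mm * noise$mono_depth_sigma_scale)
  })
  pose3d_sequence(array(p_cam, c(T_, J, 3)), gt$joint_labels, gt$fps,
                  gt$valid_mask)
}

#' Write a complete synthetic scenario to disk
#'
#' Emits the artifacts of one simulated recording: ground truth (TRC and
#' wide CSV), both keypoint JSON streams, the rig's camera config YAML, and
#' a manifest JSON recording every parameter and seed.
#'
#' @param scn A `squat_scenario`.
#' @param rig A `rig_spec`.
#' @param noise A `noise_spec`.
#' @param out_dir Output directory (created if needed).
#' @param seed Render seed (default: the scenario seed).
#' @return Named list of written paths, invisibly.
#' @export
write_scenario <- function(scn, rig, noise = noise_spec(), out_dir,
                           seed = scn$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gt <- generate_squat(scn)
  views <- render_views(gt, rig, noise, seed = seed)
  paths <- list(
    gt_trc = file.path(out_dir, "gt.trc"),
    gt_csv = file.path(out_dir, "gt.csv"),
    front = file.path(out_dir, "keypoints_front.json"),
    lateral = file.path(out_dir, "keypoints_lateral.json"),
    cameras = file.path(out_dir, "cameras.yaml"),
    manifest = file.path(out_dir, "manifest.json"))
  write_trc(gt, paths$gt_trc)
  write_pose_csv(gt, paths$gt_csv)
  write_keypoints(views$front, paths$front)
  write_keypoints(views$lateral, paths$lateral)
  write_camera_config(list(front = rig$front$intr, lateral = rig$lateral$intr),
                      paths$cameras)
  manifest <- list(scenario = unclass(scn), noise = unclass(noise),
                   rig = list(azimuth_deg = rig$azimuth_deg,
                              height_mm = rig$height_mm,
                              distance_mm = rig$distance_mm),
                   render_seed = seed)
  manifest$scenario$segments <- scn$segments
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
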