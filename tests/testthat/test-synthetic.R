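test_that("E1 kinematics are left-right symmetric with the configured knee minimum", {
  scn <- test_scenario("E1")
  gt <- generate_squat(scn)
  kl <- angle_trajectory(gt, "left_knee")
  kr <- angle_trajectory(gt, "right_knee")
  expect_lt(max(abs(as.numeric(kl) - as.numeric(kr))), 1e-9)
  expect_equal(max(kl), scn$standing_knee_deg, tolerance = 1e-6)
  expect_equal(min(kl), 180 - scn$peak_knee_flexion, tolerance = 1e-6)
})

test_that("per-cycle knee minima follow the generator's closed form", {
  scn <- squat_scenario("E1", reps = 4, duration_s = 12,
                        peak_knee_flexion = 55)
  gt <- generate_squat(scn)
  ka <- as.numeric(angle_trajectory(gt, "left_knee"))
  # bottom of cycle k at t = (k - 1/2) / cadence
  for (k in 1:4) {
    i <- round(((k - 0.5) / scn$cadence_hz) * scn$fps) + 1
    expect_equal(ka[i], 180 - 55, tolerance = 0.01)
  }
})

test_that("generation is deterministic and variants differ only in their degrees of freedom", {
  expect_identical(generate_squat(test_scenario("E1")),
                   generate_squat(test_scenario("E1")))
  g1 <- generate_squat(test_scenario("E1"))
  g2 <- generate_squat(test_scenario("E2"))
  g3 <- generate_squat(test_scenario("E3"))
  # E2 deepens the squat and the lean, in the sagittal plane only:
  # no lateral (x) difference from E1
  expect_lt(max(abs(g2$coords[, , 1] - g1$coords[, , 1])), 1e-9)
  expect_gt(max(abs(g2$coords[, , 2] - g1$coords[, , 2])), 1)
  # E3 shifts laterally: x differs, and asymmetrically
  expect_gt(max(abs(g3$coords[, , 1] - g1$coords[, , 1])), 50)
  kl <- angle_trajectory(g3, "left_knee")
  kr <- angle_trajectory(g3, "right_knee")
  expect_gt(max(abs(as.numeric(kl) - as.numeric(kr))), 5)
})

test_that("variant parameter invariants are enforced", {
  expect_error(squat_scenario("E1", lateral_shift = 50), "E3 parameter")
  expect_error(squat_scenario("E1", trunk_lean_extra = 10), "E2 parameter")
  expect_error(squat_scenario("E3", trunk_lean_extra = 10), "E2 parameter")
})

test_that("the configured between-variant angle gaps hold in ground truth", {
  knee_bottom <- function(v) {
    peak_summary(angle_trajectory(generate_squat(test_scenario(v)), "left_knee"),
                 troughs = TRUE)
  }
  hip_bottom <- function(v) {
    peak_summary(angle_trajectory(generate_squat(test_scenario(v)), "left_hip"),
                 troughs = TRUE)
  }
  expect_equal(knee_bottom("E1") - knee_bottom("E2"), 20, tolerance = 0.1)
  expect_equal(knee_bottom("E1") - knee_bottom("E3"), 20, tolerance = 0.1)
  expect_equal(hip_bottom("E2") - hip_bottom("E3"), 10, tolerance = 0.1)
})

test_that("noise-free rendering reprojects the ground truth exactly", {
  scn <- test_scenario()
  gt <- generate_squat(scn)
  rig <- rig_spec()
  views <- render_views(gt, rig, noise_spec(pixel_sigma = 0, dropout_prob = 0,
                                            outlier_prob = 0), seed = 1)
  T_ <- n_frames(gt)
  pts <- matrix(gt$coords, T_ * 12, 3)
  exact <- project_points(pts, rig$front$intr, rig$front$extr)
  expect_lt(max(abs(cbind(as.vector(views$front$u),
                          as.vector(views$front$v)) - exact)), 1e-10)
  expect_true(all(views$front$visibility >= 0.5))
})

test_that("rendered pixel noise and outlier fraction match the configuration", {
  scn <- squat_scenario("E1", reps = 5, duration_s = 20)
  gt <- generate_squat(scn)
  rig <- rig_spec()
  clean <- render_views(gt, rig, noise_spec(pixel_sigma = 0, dropout_prob = 0),
                        seed = 3)
  noisy <- render_views(gt, rig, noise_spec(pixel_sigma = 2, dropout_prob = 0),
                        seed = 3)
  dev <- c(noisy$front$u - clean$front$u, noisy$front$v - clean$front$v,
           noisy$lateral$u - clean$lateral$u, noisy$lateral$v - clean$lateral$v)
  expect_gt(length(dev), 1e4)
  expect_lt(abs(sd(dev) - 2) / 2, 0.05)

  contaminated <- render_views(gt, rig,
                               noise_spec(pixel_sigma = 0, dropout_prob = 0,
                                          outlier_prob = 0.2), seed = 9)
  frac <- mean(attr(contaminated$front, "outlier_mask"))
  expect_lt(abs(frac - 0.2), 0.02)
  # outliers keep high visibility (the hard case for downstream robustness)
  out_mask <- attr(contaminated$front, "outlier_mask")
  expect_true(all(contaminated$front$visibility[out_mask] >= 0.5))
})

test_that("dropout lowers visibility below the gate and rendering is seed-stable", {
  scn <- test_scenario()
  gt <- generate_squat(scn)
  rig <- rig_spec()
  v1 <- render_views(gt, rig, noise_spec(dropout_prob = 0.1), seed = 4)
  v2 <- render_views(gt, rig, noise_spec(dropout_prob = 0.1), seed = 4)
  expect_identical(v1$front$u, v2$front$u)
  expect_identical(v1$lateral$visibility, v2$lateral$visibility)
  drop <- attr(v1$front, "dropout_mask")
  expect_gt(mean(drop), 0.05)
  expect_true(all(v1$front$visibility[drop] < 0.5))
  expect_true(all(v1$front$visibility[!drop] >= 0.5))
})

test_that("emulated monocular depth noise scales as configured", {
  scn <- squat_scenario("E1", reps = 5, duration_s = 20)
  gt <- generate_squat(scn)
  rig <- rig_spec()
  exact <- emulate_monocular3d(gt, rig, noise_spec(pixel_sigma = 0), "front",
                               seed = 1)
  # zero pixel noise: exact GT in the camera frame
  pts <- matrix(gt$coords, n_frames(gt) * 12, 3)
  p_cam <- pts %*% t(rig$front$extr$R) +
    matrix(rig$front$extr$t, nrow(pts), 3, byrow = TRUE)
  expect_equal(matrix(exact$coords, nrow(pts), 3), p_cam, tolerance = 1e-10)

  noisy <- emulate_monocular3d(gt, rig,
                               noise_spec(pixel_sigma = 2,
                                          mono_depth_sigma_scale = 5),
                               "front", seed = 2)
  err <- matrix(noisy$coords - exact$coords, nrow(pts), 3)
  ratio <- var(err[, 3]) / mean(c(var(err[, 1]), var(err[, 2])))
  expect_lt(abs(ratio - 25) / 25, 0.15)
})

test_that("monocular 3D is beaten by epipolar reconstruction at default noise", {
  scn <- test_scenario()
  gt <- generate_squat(scn)
  rig <- rig_spec()
  wins_f <- wins_l <- 0L
  n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    views <- render_views(gt, rig, noise_spec(), seed = 600 + s)
    rec <- reconstruct_sequence(views$front, views$lateral, rig$front$intr,
                                rig$lateral$intr, seed = 700 + s,
                                n_subsets = 300)
    epi <- similarity_align(rec$pose, gt)$rmse_mm
    mf <- similarity_align(emulate_monocular3d(gt, rig, noise_spec(), "front",
                                               seed = 800 + s), gt)$rmse_mm
    ml <- similarity_align(emulate_monocular3d(gt, rig, noise_spec(), "lateral",
                                               seed = 900 + s), gt)$rmse_mm
    wins_f <- wins_f + (epi < mf)
    wins_l <- wins_l + (epi < ml)
  }
  expect_equal(wins_f, n_seeds)
  expect_equal(wins_l, n_seeds)
})

test_that("infeasible scenarios and rigs are rejected", {
  expect_error(squat_scenario("E1", segments = list(shank = -10)))
  scn <- test_scenario()
  gt <- generate_squat(scn)
  # camera too close: skeleton leaves the frame
  rig <- rig_spec(distance_mm = 600)
  expect_error(render_views(gt, rig, noise_spec(), seed = 1), "visibility check")
})
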