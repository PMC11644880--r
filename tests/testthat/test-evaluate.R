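make_cloud_pose <- function(n = 50, seed = 1, fps = 30) {
  set.seed(seed)
  coords <- array(rnorm(n * 12 * 3, 0, 300), c(n, 12, 3))
  pose3d_sequence(coords, joint_labels(), fps)
}

apply_similarity <- function(pose, s, R, t) {
  T_ <- n_frames(pose); J <- length(pose$joint_labels)
  pts <- matrix(pose$coords, T_ * J, 3)
  out <- s * pts %*% t(R) + matrix(t, T_ * J, 3, byrow = TRUE)
  pose3d_sequence(array(out, c(T_, J, 3)), pose$joint_labels, pose$fps,
                  pose$valid_mask)
}

test_that("aligning ground truth to itself is the identity transform", {
  gt <- make_cloud_pose()
  al <- similarity_align(gt, gt)
  expect_equal(al$scale, 1, tolerance = 1e-10)
  expect_equal(al$rotation, diag(3), tolerance = 1e-10)
  expect_equal(al$translation, c(0, 0, 0), tolerance = 1e-7)
  expect_lt(al$rmse_mm, 1e-10 * 300)
})

test_that("an applied similarity transform is recovered exactly", {
  gt <- make_cloud_pose(seed = 2)
  R <- axis_angle_rotation(c(1, 2, 3), 0.8)
  recon <- apply_similarity(gt, 1 / 2.5, t(R), -c(10, 20, 30))
  al <- similarity_align(recon, gt)
  expect_equal(al$scale, 2.5, tolerance = 1e-9)
  expect_equal(al$rotation, R, tolerance = 1e-9)
  expect_lt(al$rmse_mm, 1e-9)
  # and the rmse is invariant to any pre-applied similarity of the input
  recon2 <- apply_similarity(recon, 3, axis_angle_rotation(c(0, 1, 0), 1.1),
                             c(5, 5, 5))
  expect_equal(similarity_align(recon2, gt)$rmse_mm, al$rmse_mm,
               tolerance = 1e-6)
})

test_that("with isotropic noise the aligned RMSE approaches sqrt(3) sigma and matches a numerical optimizer", {
  gt <- make_cloud_pose(n = 40, seed = 3)
  sigma <- 10
  rmses <- numeric(10)
  for (s in 1:10) {
    set.seed(100 + s)
    noisy <- gt
    noisy$coords <- gt$coords + array(rnorm(length(gt$coords), 0, sigma),
                                      dim(gt$coords))
    al <- similarity_align(noisy, gt)
    rmses[s] <- al$rmse_mm
    if (s == 1) {
      X <- matrix(noisy$coords, 40 * 12, 3)
      Y <- matrix(gt$coords, 40 * 12, 3)
      expect_equal(al$rmse_mm, oracle_similarity_rmse(X, Y), tolerance = 1e-6)
    }
  }
  expect_lt(abs(mean(rmses) - sqrt(3) * sigma) / (sqrt(3) * sigma), 0.05)
})

test_that("degenerate alignments are rejected", {
  gt <- make_cloud_pose(n = 5)
  few <- gt
  few$valid_mask[] <- FALSE
  few$valid_mask[1, 1:2] <- TRUE
  expect_error(similarity_align(few, gt), "degenerate")
  # collinear points
  coords <- array(0, c(2, 12, 3))
  coords[, , 1] <- seq_len(24)  # all points on the x axis
  line_pose <- pose3d_sequence(coords, joint_labels(), 30)
  expect_error(similarity_align(line_pose, line_pose), "collinear")
})

test_that("joint_angle matches closed forms and the law-of-cosines oracle", {
  expect_equal(joint_angle(c(-1, 0, 0), c(0, 0, 0), c(2, 0, 0)), 180)
  expect_equal(joint_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  set.seed(17)
  for (i in 1:30) {
    A <- rnorm(3); B <- rnorm(3); C <- rnorm(3)
    expect_equal(joint_angle(A, B, C), oracle_angle_lawcos(A, B, C),
                 tolerance = 1e-9)
  }
  expect_true(is.na(joint_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))))
})

test_that("joint_angle is invariant under global similarity transforms", {
  set.seed(23)
  A <- rnorm(3); B <- rnorm(3); C <- rnorm(3)
  base <- joint_angle(A, B, C)
  R <- axis_angle_rotation(c(2, -1, 0.5), 1.3)
  f <- function(p) 4.2 * as.numeric(R %*% p) + c(7, -2, 3)
  expect_equal(joint_angle(f(A), f(B), f(C)), base, tolerance = 1e-10)
})

test_that("angle RMSE reproduces offsets and matches the direct formula", {
  scn <- test_scenario()
  gt <- generate_squat(scn)
  ka <- angle_trajectory(gt, "left_knee")
  expect_equal(angle_rmse(ka, ka), 0)
  shifted <- ka + 5
  attributes(shifted) <- attributes(ka)
  expect_equal(angle_rmse(shifted, ka), 5, tolerance = 1e-12)
  set.seed(31)
  noisy <- ka + rnorm(length(ka))
  attributes(noisy) <- attributes(ka)
  expect_equal(angle_rmse(noisy, ka),
               sqrt(mean((as.numeric(noisy) - as.numeric(ka))^2)),
               tolerance = 1e-12)
})

test_that("peak summary finds sinusoid extremes and fails cleanly on flat input", {
  t <- seq(0, 9, by = 1 / 30)
  x <- 120 + 30 * sin(2 * pi * t / 3)
  expect_equal(peak_summary(x, fps = 30), 150, tolerance = 0.5)
  expect_equal(peak_summary(x, fps = 30, troughs = TRUE), 90, tolerance = 0.5)
  expect_error(peak_summary(rep(120, 300), fps = 30), "0 extreme")
  expect_error(peak_summary(x[1:100], n_peaks = 3, fps = 30), "found only")
})

test_that("GT squat angle troughs equal the configured bottom angles", {
  for (variant in c("E1", "E2", "E3")) {
    scn <- test_scenario(variant)
    gt <- generate_squat(scn)
    knee <- peak_summary(angle_trajectory(gt, "left_knee"), troughs = TRUE)
    expect_equal(knee, 180 - scn$peak_knee_flexion, tolerance = 0.5)
  }
  # hip troughs: E2 sits trunk_lean_extra below E1; E3 a further 10 deg down
  hip_of <- function(variant) {
    peak_summary(angle_trajectory(generate_squat(test_scenario(variant)),
                                  "left_hip"), troughs = TRUE)
  }
  expect_equal(hip_of("E1") - hip_of("E2"), 15, tolerance = 0.2)
  expect_equal(hip_of("E2") - hip_of("E3"), 10, tolerance = 0.2)
})

test_that("paired method comparison matches the longhand t-test", {
  expect_false(compare_methods(1:10, 1:10)$significant)
  cm <- compare_methods(1:10 + 2, 1:10)
  expect_true(cm$significant)
  expect_equal(cm$p_value, 0)

  set.seed(41)
  a <- rnorm(12, 30, 5); b <- rnorm(12, 33, 5)
  cm2 <- compare_methods(a, b)
  ref <- oracle_paired_t(a, b)
  expect_equal(cm2$t, ref$t, tolerance = 1e-12)
  expect_equal(cm2$p_value, ref$p, tolerance = 1e-12)
  expect_error(compare_methods(1:3, 1:4))
})
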