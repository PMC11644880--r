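# Test-only oracles, written independently of the package implementation.

# Scalar step-by-step transcription of the radial/tangential distortion
# polynomial (independent of the vectorised implementation).
oracle_distort <- function(x, y, d) {
  k1 <- d[1]; k2 <- d[2]; p1 <- d[3]; p2 <- d[4]; k3 <- d[5]
  r2 <- x * x + y * y
  rad <- 1 + k1 * r2 + k2 * r2 * r2 + k3 * r2 * r2 * r2
  xd <- x * rad + 2 * p1 * x * y + p2 * (r2 + 2 * x * x)
  yd <- y * rad + p1 * (r2 + 2 * y * y) + 2 * p2 * x * y
  c(xd, yd)
}

# One-line transcription of the Sampson distance for x1' E x2 = 0.
oracle_sampson <- function(E, x1, x2) {
  a <- c(x1, 1); b <- c(x2, 1)
  num <- as.numeric(t(a) %*% E %*% b)^2
  Eb <- E %*% b; Ea <- t(E) %*% a
  num / (Eb[1]^2 + Eb[2]^2 + Ea[1]^2 + Ea[2]^2)
}

# Midpoint of the common perpendicular of the two viewing rays
# (independent triangulation method). Camera 1 at the origin with ray
# direction (x1, 1); camera 2's centre in the camera-1 frame is t21 with
# ray direction R21 %*% (x2, 1).
oracle_midpoint <- function(x1, x2, R21, t21) {
  d1 <- c(x1, 1)
  d2 <- as.numeric(R21 %*% c(x2, 1))
  o1 <- c(0, 0, 0); o2 <- t21
  a <- sum(d1 * d1); b <- sum(d1 * d2); c_ <- sum(d2 * d2)
  w <- o1 - o2
  dd <- sum(d1 * w); e <- sum(d2 * w)
  den <- a * c_ - b * b
  s <- (b * e - c_ * dd) / den
  t_ <- (a * e - b * dd) / den
  (o1 + s * d1 + o2 + t_ * d2) / 2
}

# Law-of-cosines angle at vertex B from the three pairwise distances.
oracle_angle_lawcos <- function(A, B, C) {
  ab <- sqrt(sum((A - B)^2)); cb <- sqrt(sum((C - B)^2))
  ac <- sqrt(sum((A - C)^2))
  acos((ab^2 + cb^2 - ac^2) / (2 * ab * cb)) * 180 / pi
}

# Generic nonlinear minimisation of the similarity-fit objective
# mean || s R x + t - y ||^2 over (log s, rotation vector, t); returns the
# achieved RMSE. Moment-based initialisation, no closed form used.
oracle_similarity_rmse <- function(X, Y) {
  rotvec_to_R <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    k <- v / th
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  obj <- function(p) {
    s <- exp(p[1]); R <- rotvec_to_R(p[2:4]); t_ <- p[5:7]
    M <- s * X %*% t(R) + matrix(t_, nrow(X), 3, byrow = TRUE)
    mean(rowSums((M - Y)^2))
  }
  s0 <- sqrt(sum(scale(Y, scale = FALSE)^2) / sum(scale(X, scale = FALSE)^2))
  best <- Inf
  # a few rotation starts to avoid local minima of the rotation manifold
  for (v0 in list(c(0, 0, 0), c(pi, 0, 0), c(0, pi, 0), c(0, 0, pi))) {
    p0 <- c(log(s0), v0, colMeans(Y) - s0 * colMeans(X))
    fit <- stats::optim(p0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  sqrt(best)
}

# Longhand paired t-test.
oracle_paired_t <- function(a, b) {
  d <- a - b; n <- length(d)
  t_ <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t_, p = 2 * stats::pt(-abs(t_), df = n - 1))
}

# Plain (non-robust) least-squares essential fit: unconditioned 8-point
# design over ALL correspondences, projected to the essential manifold.
oracle_plain_ls_essential <- function(x1, x2) {
  X1 <- cbind(x1, 1); X2 <- cbind(x2, 1)
  A <- cbind(X1[, 1] * X2[, 1], X1[, 1] * X2[, 2], X1[, 1] * X2[, 3],
             X1[, 2] * X2[, 1], X1[, 2] * X2[, 2], X1[, 2] * X2[, 3],
             X1[, 3] * X2[, 1], X1[, 3] * X2[, 2], X1[, 3] * X2[, 3])
  e <- svd(A, nu = 0, nv = 9)$v[, 9]
  E <- matrix(e, 3, 3, byrow = TRUE)
  sv <- svd(E)
  s <- mean(sv$d[1:2])
  E <- sv$u %*% diag(c(s, s, 0)) %*% t(sv$v)
  E / sqrt(sum(E^2))
}

# --- shared fixtures ------------------------------------------------------

# A hand-built two-camera rig in the camera-1 frame: camera 2 rotated 90
# degrees about the y axis, centre at (-5, 0, 5); E built longhand.
test_rig_geometry <- function() {
  th <- pi / 2
  R21 <- matrix(c(cos(th), 0, -sin(th),
                  0, 1, 0,
                  sin(th), 0, cos(th)), 3, 3)  # column-major: Ry(+90)
  t21 <- c(-5, 0, 5)
  t21u <- t21 / sqrt(sum(t21^2))
  skew <- matrix(c(0, t21u[3], -t21u[2],
                   -t21u[3], 0, t21u[1],
                   t21u[2], -t21u[1], 0), 3, 3)
  E <- skew %*% R21
  E <- E / sqrt(sum(E^2))
  if (E[which.max(abs(E))] < 0) E <- -E
  list(R21 = R21, t21 = t21, t21u = t21u, E = E)
}

# Exact normalized correspondences of random points visible to both
# cameras of test_rig_geometry().
make_correspondences <- function(n, rig = test_rig_geometry(), seed = 42) {
  set.seed(seed)
  pts <- cbind(runif(n, -1, 1), runif(n, -1, 1), runif(n, 4, 6))
  x1 <- pts[, 1:2, drop = FALSE] / pts[, 3]
  p2 <- (pts - matrix(rig$t21, n, 3, byrow = TRUE)) %*% rig$R21
  stopifnot(all(p2[, 3] > 0))
  x2 <- p2[, 1:2, drop = FALSE] / p2[, 3]
  list(x1 = x1, x2 = x2, pts = pts,
       corrs = correspondence_set(x1, x2))
}

# Default test camera.
test_intrinsics <- function(distortion = c(0, 0, 0, 0, 0)) {
  camera_intrinsics(1000, 1000, 540, 960, 1080, 1920, distortion)
}

# Short scenario used throughout the tests (3 reps over 10 s keeps the
# suite fast while leaving 3 clean repetition extremes).
test_scenario <- function(variant = "E1", ...) {
  squat_scenario(variant, reps = 3L, duration_s = 10, ...)
}
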