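# Optional trajectory smoothing: zero-phase Butterworth low-pass, causal
# moving average, Savitzky-Golay; plus grid-search parameter selection
# against ground truth.

#' Filter specification
#'
#' @param kind One of "butterworth", "moving_average", "savitzky_golay",
#'   "none".
#' @param order Butterworth filter order (default 4) or Savitzky-Golay
#'   polynomial order (default 3).
#' @param cutoff_hz Butterworth cutoff frequency in Hz (default 2); must be
#'   below the Nyquist frequency of the sequence it is applied to.
#' @param window Window length in samples for moving average /
#'   Savitzky-Golay; odd and >= 3.
#' @return A `filter_spec`.
#' @export
filter_spec <- function(kind = c("none", "butterworth", "moving_average",
                                 "savitzky_golay"),
                        order = NULL, cutoff_hz = NULL, window = NULL) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    none = list(kind = kind),
    butterworth = list(kind = kind,
                       order = if (is.null(order)) 4L else as.integer(order),
                       cutoff_hz = if (is.null(cutoff_hz)) 2 else cutoff_hz),
    moving_average = list(kind = kind,
                          window = if (is.null(window)) 5L else as.integer(window)),
    savitzky_golay = list(kind = kind,
                          window = if (is.null(window)) 9L else as.integer(window),
                          order = if (is.null(order)) 3L else as.integer(order))
  )
  if (!is.null(spec$window)) {
    if (spec$window < 3 || spec$window %% 2 == 0)
      stop("window must be odd and >= 3")
  }
  if (kind == "savitzky_golay" && spec$order >= spec$window)
    stop("Savitzky-Golay polynomial order must be smaller than the window")
  if (kind == "butterworth" && spec$order < 1) stop("order must be >= 1")
  structure(spec, class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("filter_spec:", format_filter_spec(x), "\n")
  invisible(x)
}

format_filter_spec <- function(spec) {
  switch(spec$kind,
    none = "none",
    butterworth = sprintf("butterworth(order=%d, cutoff=%g Hz)",
                          spec$order, spec$cutoff_hz),
    moving_average = sprintf("moving_average(window=%d)", spec$window),
    savitzky_golay = sprintf("savitzky_golay(window=%d, order=%d)",
                             spec$window, spec$order))
}

# Steady-state initial filter state (direct form II transposed), so a
# constant input yields the constant output from the first sample: the same
# construction scipy uses for its filtfilt initial conditions.
lfilter_zi <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  if (n == 1) return(numeric(0))
  A <- matrix(0, n - 1, n - 1)
  A[, 1] <- -a[2:n]
  if (n > 2) A[1:(n - 2), 2:(n - 1)] <- diag(n - 2)
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - A, B)
}

# Direct-form-II-transposed IIR filter with initial state.
df2t_filter <- function(b, a, x, zi) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  y <- numeric(length(x))
  z <- c(zi, 0)
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    for (k in seq_len(n - 1)) {
      z[k] <- b[k + 1] * x[i] + z[k + 1] - a[k + 1] * y[i]
    }
  }
  y
}

# Zero-phase Butterworth: forward-backward with steady-state initial
# conditions and odd-reflection end padding, so DC gain is exactly 1 and no
# phase delay is introduced. The two passes square the magnitude response
# (amplitude 0.5 at the design cutoff).
zero_phase_butter <- function(x, order, cutoff_hz, fps) {
  if (cutoff_hz >= fps / 2)
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff_hz, fps / 2))
  bf <- signal::butter(order, cutoff_hz / (fps / 2), type = "low")
  b <- bf$b; a <- bf$a
  n <- length(x)
  padlen <- min(n - 1, 3 * (max(length(a), length(b)) - 1))
  xp <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- df2t_filter(b, a, xp, zi * xp[1])
  y <- rev(df2t_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

# Causal (trailing-window) moving average; the first window-1 samples use
# the partial window. One-pass, so peaks are delayed by ~ (window-1)/2
# samples -- the delay artifact that motivates preferring the zero-phase
# Butterworth.
moving_average_filter <- function(x, window) {
  cs <- cumsum(x)
  n <- length(x)
  lead <- pmax(0, seq_len(n) - window)
  (cs - c(0, cs)[lead + 1]) / (seq_len(n) - lead)
}

filter_channel <- function(x, spec, fps) {
  switch(spec$kind,
    none = x,
    butterworth = zero_phase_butter(x, spec$order, spec$cutoff_hz, fps),
    moving_average = moving_average_filter(x, spec$window),
    savitzky_golay = as.numeric(signal::sgolayfilt(x, p = spec$order,
                                                   n = spec$window)))
}

min_filter_length <- function(spec) {
  switch(spec$kind,
    none = 1L,
    butterworth = 3L * spec$order,
    moving_average = spec$window,
    savitzky_golay = spec$window)
}

# Bridge invalid samples by linear interpolation (constant extrapolation at
# the ends) so the filter sees a gap-free channel; the mask is reapplied by
# the caller.
bridge_gaps <- function(x, valid) {
  if (all(valid)) return(x)
  ok <- which(valid)
  if (length(ok) == 0) return(x)
  if (length(ok) == 1) { x[] <- x[ok]; return(x) }
  stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}

#' Apply a smoothing filter to a 3D pose or 2D keypoint sequence
#'
#' Each scalar channel (per joint, per coordinate) is filtered independently.
#' Invalid gaps are linearly bridged before filtering and re-masked after;
#' the validity mask itself is never changed. The Butterworth filter is
#' applied forward-backward (zero phase), so it introduces no delay.
#'
#' @param seq A `pose3d_sequence` or `keypoint_sequence`.
#' @param spec A `filter_spec`.
#' @return The filtered sequence, same class and mask as the input.
#' @export
apply_filter <- function(seq, spec) {
  if (spec$kind == "none") return(seq)
  n <- n_frames(seq)
  need <- min_filter_length(spec)
  if (inherits(seq, "pose3d_sequence")) {
    for (j in seq_along(seq$joint_labels)) {
      valid <- seq$valid_mask[, j]
      if (sum(valid) == 0) next
      if (n < need)
        stop(sprintf("sequence too short to filter joint '%s': %d frames < minimum %d",
                     seq$joint_labels[j], n, need))
      for (k in 1:3) {
        x <- bridge_gaps(seq$coords[, j, k], valid)
        seq$coords[, j, k] <- filter_channel(x, spec, seq$fps)
      }
      seq$coords[!valid, j, ] <- 0
    }
    seq
  } else if (inherits(seq, "keypoint_sequence")) {
    for (j in seq_along(seq$joint_labels)) {
      valid <- is.finite(seq$u[, j]) & is.finite(seq$v[, j])
      if (sum(valid) == 0) next
      if (n < need)
        stop(sprintf("sequence too short to filter joint '%s': %d frames < minimum %d",
                     seq$joint_labels[j], n, need))
      seq$u[, j] <- filter_channel(bridge_gaps(seq$u[, j], valid), spec, seq$fps)
      seq$v[, j] <- filter_channel(bridge_gaps(seq$v[, j], valid), spec, seq$fps)
    }
    seq
  } else stop("apply_filter expects a pose3d_sequence or keypoint_sequence")
}

#' Default filter search grid
#'
#' Butterworth orders 2 and 4 at cutoffs 1-4 Hz, moving-average windows
#' 5/9/15, Savitzky-Golay windows 5/9/15 with polynomial orders 2 and 3, and
#' the identity ("none").
#'
#' @return List of `filter_spec` objects.
#' @export
default_filter_grid <- function() {
  grid <- list(filter_spec("none"))
  for (o in c(2L, 4L)) for (fc in c(1, 2, 3, 4))
    grid <- c(grid, list(filter_spec("butterworth", order = o, cutoff_hz = fc)))
  for (w in c(5L, 9L, 15L))
    grid <- c(grid, list(filter_spec("moving_average", window = w)))
  for (w in c(5L, 9L, 15L)) for (o in c(2L, 3L))
    grid <- c(grid, list(filter_spec("savitzky_golay", window = w, order = o)))
  grid
}

#' Grid-search filter selection against ground truth
#'
#' Applies each candidate filter to every reconstruction, aligns to the
#' paired ground truth, and scores by the mean aligned RMSE over recordings.
#' Ties are broken toward "none", then toward less smoothing (smaller
#' order/window).
#'
#' @param recons,gts Paired lists of `pose3d_sequence` objects.
#' @param grid List of `filter_spec` objects (default
#'   [default_filter_grid()]).
#' @return List with `best` (a `filter_spec`) and `table` (data frame of
#'   spec descriptions and mean RMSE scores).
#' @export
grid_search_filter <- function(recons, gts, grid = default_filter_grid()) {
  if (length(grid) == 0) stop("empty filter grid")
  stopifnot(length(recons) == length(gts))
  smoothing_rank <- function(spec) {
    switch(spec$kind, none = 0,
           butterworth = spec$order * 100 + (10 - spec$cutoff_hz),
           moving_average = spec$window,
           savitzky_golay = spec$window + (10 - spec$order) / 10)
  }
  scores <- vapply(grid, function(spec) {
    mean(vapply(seq_along(recons), function(i) {
      similarity_align(apply_filter(recons[[i]], spec), gts[[i]])$rmse_mm
    }, numeric(1)))
  }, numeric(1))
  tab <- data.frame(spec = vapply(grid, format_filter_spec, character(1)),
                    mean_rmse_mm = scores)
  ranks <- vapply(grid, smoothing_rank, numeric(1))
  ord <- order(scores, ranks)
  list(best = grid[[ord[1]]], table = tab[order(scores, ranks), ])
}
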