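# Motion-capture marker handling: TRC/CSV reading, short-gap filling,
# marker -> joint conversion rules, and resampling to the camera rate.

#' Marker trajectory set
#'
#' Optical motion-capture marker trajectories: one T x 3 matrix (mm) per
#' marker label, a shared frame rate (100 fps by default for the capture
#' system) and a per-marker gap mask.
#'
#' @param markers Named list of T x 3 numeric matrices (mm).
#' @param fps Frame rate in Hz (default 100).
#' @param gap_mask Optional named list of logical vectors (TRUE = gapped /
#'   missing); defaults to rows with any non-finite coordinate.
#' @return A `marker_trajectory_set`.
#' @export
marker_trajectory_set <- function(markers, fps = 100, gap_mask = NULL) {
  stopifnot(length(markers) > 0, !is.null(names(markers)), fps > 0)
  T_ <- nrow(markers[[1]])
  for (m in markers) stopifnot(is.matrix(m), ncol(m) == 3, nrow(m) == T_)
  if (is.null(gap_mask)) {
    gap_mask <- lapply(markers, function(m) !apply(is.finite(m), 1, all))
  }
  stopifnot(identical(names(gap_mask), names(markers)))
  structure(list(markers = markers, fps = fps, gap_mask = gap_mask,
                 n_frames = T_),
            class = "marker_trajectory_set")
}

#' @export
print.marker_trajectory_set <- function(x, ...) {
  cat(sprintf("marker_trajectory_set: %d markers x %d frames @ %g fps\n",
              length(x$markers), x$n_frames, x$fps))
  invisible(x)
}

#' Fill short marker trajectory gaps by linear interpolation
#'
#' Gaps strictly shorter than `max_gap` samples that are bounded by valid
#' samples on both sides are filled linearly; longer gaps and gaps touching
#' either sequence end stay invalid. Idempotent.
#'
#' @param traj A `marker_trajectory_set`.
#' @param max_gap Gap length threshold in samples (default 100; a gap of
#'   exactly `max_gap` samples is not filled).
#' @return A `marker_trajectory_set` with filled gaps.
#' @export
fill_gaps <- function(traj, max_gap = 100L) {
  for (nm in names(traj$markers)) {
    gap <- traj$gap_mask[[nm]]
    if (!any(gap)) next
    r <- rle(gap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    m <- traj$markers[[nm]]
    for (g in which(r$values)) {
      len <- r$lengths[g]
      s <- starts[g]; e <- ends[g]
      if (len >= max_gap) next
      if (s == 1L || e == traj$n_frames) next  # edge gap: no anchor
      w <- seq_len(len) / (len + 1)
      for (k in 1:3) {
        m[s:e, k] <- m[s - 1L, k] * (1 - w) + m[e + 1L, k] * w
      }
      traj$gap_mask[[nm]][s:e] <- FALSE
    }
    traj$markers[[nm]] <- m
  }
  traj
}

#' Default marker-to-joint assignment rules
#'
#' The published harmonization between the 31-marker capture set and the
#' 12-joint camera subset: single-marker passthrough for shoulders and
#' wrists, the mean of two markers for elbows, knees and ankles, and an
#' axis-composite for the hips (x from the anterior iliac marker, y and z
#' from the trochanter marker). The right-ankle pair is A27 + A29, matching
#' the left side's A26 + A28.
#'
#' @return Named list of rules; each rule is a list with `type` in
#'   {"single", "mean", "axis"} and marker fields.
#' @export
default_joint_rules <- function() {
  list(
    left_shoulder  = list(type = "single", marker = "A4"),
    right_shoulder = list(type = "single", marker = "A5"),
    left_elbow     = list(type = "mean", markers = c("A6", "A8")),
    right_elbow    = list(type = "mean", markers = c("A7", "A9")),
    left_wrist     = list(type = "single", marker = "A14"),
    right_wrist    = list(type = "single", marker = "A15"),
    left_hip       = list(type = "axis", x = "A12", yz = "A16"),
    right_hip      = list(type = "axis", x = "A13", yz = "A17"),
    left_knee      = list(type = "mean", markers = c("A18", "A20")),
    right_knee     = list(type = "mean", markers = c("A19", "A21")),
    left_ankle     = list(type = "mean", markers = c("A26", "A28")),
    right_ankle    = list(type = "mean", markers = c("A27", "A29"))
  )
}

#' Read a joint-rule set from YAML
#'
#' The YAML maps joint labels to rules in the same shape as
#' [default_joint_rules()].
#'
#' @param path YAML file path.
#' @return Named list of rules.
#' @export
read_joint_rules <- function(path) yaml::read_yaml(path)

rule_sources <- function(rule) {
  switch(rule$type,
    single = rule$marker,
    mean = rule$markers,
    axis = c(rule$x, rule$yz),
    stop("unknown rule type: ", rule$type))
}

#' Convert marker trajectories to ground-truth joint positions
#'
#' Applies each assignment rule per frame; a joint frame is valid only where
#' none of its source markers is gapped.
#'
#' @param traj A `marker_trajectory_set`.
#' @param rules Named list of rules (default [default_joint_rules()]).
#' @return A `pose3d_sequence` in millimetres at the marker frame rate.
#' @export
markers_to_joints <- function(traj, rules = default_joint_rules()) {
  labels <- names(rules)
  T_ <- traj$n_frames
  coords <- array(0, c(T_, length(labels), 3))
  valid <- matrix(TRUE, T_, length(labels))
  for (j in seq_along(rules)) {
    rule <- rules[[j]]
    src <- rule_sources(rule)
    missing <- setdiff(src, names(traj$markers))
    if (length(missing) > 0)
      stop("missing marker label(s): ", paste(missing, collapse = ", "))
    pos <- switch(rule$type,
      single = traj$markers[[rule$marker]],
      mean = (traj$markers[[rule$markers[1]]] +
                traj$markers[[rule$markers[2]]]) / 2,
      axis = cbind(traj$markers[[rule$x]][, 1, drop = FALSE],
                   traj$markers[[rule$yz]][, 2:3, drop = FALSE]))
    coords[, j, ] <- pos
    for (s in src) valid[, j] <- valid[, j] & !traj$gap_mask[[s]]
    coords[!valid[, j], j, ] <- 0
  }
  pose3d_sequence(coords, labels, traj$fps, valid)
}

#' Resample a 3D pose sequence to a lower frame rate
#'
#' Linear interpolation at target timestamps starting at t = 0; a resampled
#' frame is valid only where both bracketing source frames are valid.
#'
#' @param seq A `pose3d_sequence`.
#' @param target_fps Target frame rate in Hz (> 0, at most the source fps).
#' @return A `pose3d_sequence` at `target_fps`.
#' @export
resample_pose <- function(seq, target_fps) {
  if (target_fps <= 0) stop("target_fps must be positive")
  if (target_fps > seq$fps)
    stop(sprintf("target fps (%g) exceeds source fps (%g)", target_fps, seq$fps))
  if (target_fps == seq$fps) return(seq)
  src_t <- frame_times(seq)
  tgt_t <- seq(0, src_t[length(src_t)], by = 1 / target_fps)
  Tn <- length(tgt_t)
  J <- length(seq$joint_labels)
  lo <- pmin(findInterval(tgt_t, src_t), n_frames(seq) - 1L)
  hi <- lo + 1L
  w <- (tgt_t - src_t[lo]) * seq$fps
  coords <- array(0, c(Tn, J, 3))
  valid <- matrix(FALSE, Tn, J)
  for (j in seq_len(J)) {
    valid[, j] <- seq$valid_mask[lo, j] & seq$valid_mask[hi, j]
    for (k in 1:3) {
      coords[, j, k] <- seq$coords[lo, j, k] * (1 - w) + seq$coords[hi, j, k] * w
    }
    coords[!valid[, j], j, ] <- 0
  }
  pose3d_sequence(coords, seq$joint_labels, target_fps, valid)
}

#' Read marker trajectories from a TRC file
#'
#' Standard TRC layout: a 3-line header carrying DataRate, NumFrames and
#' NumMarkers, a marker-name row, an X1/Y1/Z1... row, then tab-separated
#' frame rows (Frame#, Time, x/y/z per marker). Empty cells become gaps.
#'
#' @param path TRC file path.
#' @return A `marker_trajectory_set`.
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  hdr_keys <- strsplit(lines[2], "\t")[[1]]
  fps <- as.numeric(hdr_vals[match("DataRate", hdr_keys)])
  name_row <- strsplit(lines[4], "\t")[[1]]
  marker_names <- name_row[-(1:2)]
  marker_names <- marker_names[marker_names != ""]
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[trimws(data_lines) != ""]
  T_ <- length(data_lines)
  J <- length(marker_names)
  vals <- matrix(NA_real_, T_, 2 + 3 * J)
  for (i in seq_len(T_)) {
    cells <- strsplit(data_lines[i], "\t", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(cells))
    vals[i, seq_along(num)] <- num
  }
  markers <- list()
  for (j in seq_len(J)) {
    markers[[marker_names[j]]] <- vals[, (3 * (j - 1) + 3):(3 * (j - 1) + 5),
                                       drop = FALSE]
  }
  marker_trajectory_set(markers, fps = fps)
}

#' Read marker trajectories from a wide CSV
#'
#' Columns `<marker>_x`, `<marker>_y`, `<marker>_z` per marker, optional
#' `time_s`.
#'
#' @param path CSV path.
#' @param fps Frame rate; inferred from `time_s` when present.
#' @return A `marker_trajectory_set`.
#' @export
read_marker_csv <- function(path, fps = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  labels <- unique(sub("_[xyz]$", "", nm[grepl("_[xyz]$", nm)]))
  if (is.null(fps)) {
    fps <- if ("time_s" %in% nm && nrow(df) > 1)
      1 / stats::median(diff(df$time_s)) else 100
  }
  markers <- lapply(labels, function(l) {
    as.matrix(df[paste0(l, c("_x", "_y", "_z"))])
  })
  names(markers) <- labels
  marker_trajectory_set(markers, fps = fps)
}
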