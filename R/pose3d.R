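# Pose3DSequence: T x J x 3 joint trajectories with a validity mask.

#' 3D pose sequence
#'
#' Container for per-frame 3D joint positions: a T x J x 3 array, joint
#' labels, frame rate and a T x J validity mask. Reconstructed sequences are
#' at an arbitrary global scale (the self-calibrated translation is unit
#' norm); ground-truth sequences are in millimetres.
#'
#' @param coords T x J x 3 numeric array.
#' @param joint_labels Character vector of length J.
#' @param fps Frame rate in Hz.
#' @param valid_mask T x J logical matrix; defaults to entries with all three
#'   coordinates finite.
#' @return An object of class `pose3d_sequence`.
#' @export
pose3d_sequence <- function(coords, joint_labels, fps, valid_mask = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3,
            dim(coords)[2] == length(joint_labels), fps > 0)
  if (is.null(valid_mask)) {
    valid_mask <- apply(is.finite(coords), c(1, 2), all)
  }
  stopifnot(is.logical(valid_mask),
            all(dim(valid_mask) == dim(coords)[1:2]))
  if (!all(is.finite(coords[rep(valid_mask, 3)])))
    stop("coordinates must be finite wherever valid_mask is TRUE")
  dimnames(coords) <- list(NULL, joint_labels, c("x", "y", "z"))
  colnames(valid_mask) <- joint_labels
  structure(list(coords = coords, joint_labels = joint_labels,
                 fps = fps, valid_mask = valid_mask),
            class = "pose3d_sequence")
}

#' @export
print.pose3d_sequence <- function(x, ...) {
  cat(sprintf("pose3d_sequence: %d frames x %d joints @ %g fps (%.1f%% valid)\n",
              n_frames(x), length(x$joint_labels), x$fps,
              100 * mean(x$valid_mask)))
  invisible(x)
}

#' Number of frames of a pose or keypoint sequence
#' @param x A `pose3d_sequence` or `keypoint_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) UseMethod("n_frames")

#' @export
n_frames.pose3d_sequence <- function(x) dim(x$coords)[1]

#' Frame timestamps (seconds, starting at 0)
#' @param x A sequence object with an `fps` field.
#' @return Numeric vector of times.
#' @export
frame_times <- function(x) (seq_len(n_frames(x)) - 1) / x$fps

#' Write a 3D pose sequence to wide CSV
#'
#' Columns: frame, time_s, then x/y/z per joint label. Invalid entries are
#' written as empty cells (NA).
#'
#' @param pose A `pose3d_sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(pose, path) {
  T_ <- n_frames(pose)
  df <- data.frame(frame = seq_len(T_) - 1L, time_s = frame_times(pose))
  for (j in seq_along(pose$joint_labels)) {
    lbl <- pose$joint_labels[j]
    xyz <- pose$coords[, j, , drop = FALSE]
    dim(xyz) <- c(T_, 3)
    xyz[!pose$valid_mask[, j], ] <- NA
    df[[paste0(lbl, "_x")]] <- xyz[, 1]
    df[[paste0(lbl, "_y")]] <- xyz[, 2]
    df[[paste0(lbl, "_z")]] <- xyz[, 3]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a 3D pose sequence from wide CSV written by [write_pose_csv()]
#' @param path CSV path.
#' @param fps Frame rate in Hz (the CSV stores times; fps must be supplied or
#'   is inferred from the time column spacing).
#' @return A `pose3d_sequence`.
#' @export
read_pose_csv <- function(path, fps = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(fps)) {
    dt <- diff(df$time_s)
    fps <- 1 / stats::median(dt)
  }
  nm <- names(df)
  labels <- unique(sub("_[xyz]$", "", nm[grepl("_[xyz]$", nm)]))
  T_ <- nrow(df)
  coords <- array(NA_real_, c(T_, length(labels), 3))
  for (j in seq_along(labels)) {
    coords[, j, 1] <- df[[paste0(labels[j], "_x")]]
    coords[, j, 2] <- df[[paste0(labels[j], "_y")]]
    coords[, j, 3] <- df[[paste0(labels[j], "_z")]]
  }
  valid <- apply(is.finite(coords), c(1, 2), all)
  coords[!is.finite(coords)] <- 0
  pose3d_sequence(coords, labels, fps, valid)
}

#' Write a 3D pose sequence to TRC
#'
#' Standard TRC header (DataRate, NumFrames, marker names) followed by
#' tab-separated frame rows. Units are millimetres.
#'
#' @param pose A `pose3d_sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(pose, path) {
  T_ <- n_frames(pose); J <- length(pose$joint_labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)),
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    sprintf("%g\t%g\t%d\t%d\tmm\t%g\t1\t%d", pose$fps, pose$fps, T_, J, pose$fps, T_),
    paste(c("Frame#", "Time", as.vector(rbind(pose$joint_labels, "", ""))), collapse = "\t"),
    paste(c("", "", paste0(rep(c("X", "Y", "Z"), J), rep(seq_len(J), each = 3))), collapse = "\t"),
    ""
  ), con)
  times <- frame_times(pose)
  for (i in seq_len(T_)) {
    vals <- as.vector(t(pose$coords[i, , ]))
    inval <- !rep(pose$valid_mask[i, ], each = 3)
    svals <- formatC(vals, format = "f", digits = 5)
    svals[inval] <- ""
    writeLines(paste(c(i, formatC(times[i], format = "f", digits = 5), svals),
                     collapse = "\t"), con)
  }
  invisible(path)
}
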