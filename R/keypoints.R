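# KeypointSequence: per-camera 2D joint detections with visibility, plus
# readers/writers for the landmark JSON dialect and wide CSV.

#' 2D keypoint sequence for one camera
#'
#' Time series of per-joint pixel detections with visibility scores in
#' [0, 1] (higher = more confident). Inputs in the normalized dialect
#' (u, v in [0, 1], as emitted by the 33-landmark pose estimators) are
#' converted to pixels via the image size at construction.
#'
#' @param u,v T x J matrices of pixel coordinates.
#' @param visibility T x J matrix in [0, 1].
#' @param joint_labels Character vector of length J.
#' @param fps Frame rate (Hz).
#' @param image_size Integer (width, height) in pixels.
#' @param camera Camera label, e.g. "front" or "lateral".
#' @param z_mono Optional T x J matrix of monocular depth estimates
#'   (landmark-dialect z); carried through for the monocular baseline only.
#' @param dialect "pixel" (default) or "normalized"; normalized inputs are
#'   scaled by image_size.
#' @return An object of class `keypoint_sequence`.
#' @export
keypoint_sequence <- function(u, v, visibility, joint_labels, fps,
                              image_size, camera = "front", z_mono = NULL,
                              dialect = c("pixel", "normalized")) {
  dialect <- match.arg(dialect)
  u <- as.matrix(u); v <- as.matrix(v); visibility <- as.matrix(visibility)
  stopifnot(all(dim(u) == dim(v)), all(dim(u) == dim(visibility)),
            ncol(u) == length(joint_labels), fps > 0,
            length(image_size) == 2, all(image_size > 0))
  if (any(visibility < 0 | visibility > 1, na.rm = TRUE)) {
    bad <- which(visibility < 0 | visibility > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("visibility out of [0,1] at frame %d, joint '%s'",
                 bad[1] - 1L, joint_labels[bad[2]]))
  }
  if (dialect == "normalized") {
    u <- u * image_size[1]
    v <- v * image_size[2]
  }
  colnames(u) <- colnames(v) <- colnames(visibility) <- joint_labels
  structure(list(u = u, v = v, visibility = visibility,
                 joint_labels = joint_labels, fps = fps,
                 image_size = as.numeric(image_size), camera = camera,
                 z_mono = z_mono),
            class = "keypoint_sequence")
}

#' @export
n_frames.keypoint_sequence <- function(x) nrow(x$u)

#' @export
print.keypoint_sequence <- function(x, ...) {
  cat(sprintf("keypoint_sequence [%s]: %d frames x %d joints @ %g fps, %gx%g px\n",
              x$camera, n_frames(x), length(x$joint_labels), x$fps,
              x$image_size[1], x$image_size[2]))
  invisible(x)
}

#' Read a keypoint stream (landmark JSON dialect or wide CSV)
#'
#' The JSON dialect is an object with fields `camera`, `fps`, `image_size`
#' ([w, h]), `dialect` ("pixel" or "normalized") and `frames`: an array of
#' per-frame objects `{t, landmarks: [{id, u, v, z, visibility}, ...]}` using
#' the 33-landmark id scheme. Only the 12-joint body subset (ids 11-16 and
#' 23-28) is extracted. The wide CSV alternative has columns `frame`,
#' `time_s`, then `u_<joint>`, `v_<joint>`, `vis_<joint>` per joint label.
#'
#' @param path Input file (.json or .csv).
#' @param dialect Override the coordinate dialect declared in the file.
#' @return A `keypoint_sequence`.
#' @export
read_keypoints <- function(path, dialect = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") read_keypoints_json(path, dialect)
  else if (ext == "csv") read_keypoints_csv(path, dialect)
  else stop("unsupported keypoint file extension: ", ext)
}

read_keypoints_json <- function(path, dialect = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(dialect)) dialect <- if (is.null(obj$dialect)) "pixel" else obj$dialect
  ids <- landmark_ids()
  labels <- names(ids)
  T_ <- length(obj$frames)
  u <- v <- vis <- zm <- matrix(NA_real_, T_, length(ids))
  tprev <- -Inf
  for (i in seq_len(T_)) {
    fr <- obj$frames[[i]]
    t_i <- if (is.null(fr$t)) (i - 1) / obj$fps else fr$t
    if (t_i <= tprev)
      stop(sprintf("non-monotonic timestamps at frame %d", i - 1L))
    tprev <- t_i
    lm_ids <- vapply(fr$landmarks, function(l) as.integer(l$id), integer(1))
    for (j in seq_along(ids)) {
      k <- match(ids[j], lm_ids)
      if (is.na(k))
        stop(sprintf("missing landmark id %d ('%s') at frame %d",
                     ids[j], labels[j], i - 1L))
      l <- fr$landmarks[[k]]
      viz <- as.numeric(l$visibility)
      if (!is.finite(viz) || viz < 0 || viz > 1)
        stop(sprintf("visibility out of [0,1] at frame %d, landmark id %d",
                     i - 1L, ids[j]))
      u[i, j] <- as.numeric(l$u); v[i, j] <- as.numeric(l$v); vis[i, j] <- viz
      if (!is.null(l$z)) zm[i, j] <- as.numeric(l$z)
    }
  }
  if (all(is.na(zm))) zm <- NULL
  keypoint_sequence(u, v, vis, labels, obj$fps,
                    as.numeric(unlist(obj$image_size)),
                    camera = if (is.null(obj$camera)) "unknown" else obj$camera,
                    z_mono = zm, dialect = dialect)
}

read_keypoints_csv <- function(path, dialect = NULL) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  nm <- names(df)
  labels <- sub("^u_", "", nm[grepl("^u_", nm)])
  u <- as.matrix(df[paste0("u_", labels)])
  v <- as.matrix(df[paste0("v_", labels)])
  vis <- as.matrix(df[paste0("vis_", labels)])
  fps <- if ("time_s" %in% nm && nrow(df) > 1) 1 / stats::median(diff(df$time_s)) else 30
  w <- if ("image_width" %in% nm) df$image_width[1] else 1080
  h <- if ("image_height" %in% nm) df$image_height[1] else 1920
  if (is.null(dialect)) dialect <- "pixel"
  keypoint_sequence(u, v, vis, labels, fps, c(w, h), dialect = dialect)
}

#' Write a keypoint sequence to the landmark JSON dialect
#'
#' Joints outside the 12-joint subset are written with zero coordinates and
#' zero visibility so the file is a complete 33-landmark record.
#'
#' @param kp A `keypoint_sequence`.
#' @param path Output path.
#' @param digits Coordinate precision (default 6 significant digits beyond
#'   the decimal point via jsonlite's `digits = NA`, i.e. full precision).
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(kp, path, digits = NA) {
  ids <- landmark_ids()
  frames <- lapply(seq_len(n_frames(kp)), function(i) {
    landmarks <- lapply(seq_along(kp$joint_labels), function(j) {
      rec <- list(id = unname(ids[kp$joint_labels[j]]),
                  u = kp$u[i, j], v = kp$v[i, j],
                  visibility = kp$visibility[i, j])
      if (!is.null(kp$z_mono)) rec$z <- kp$z_mono[i, j]
      rec
    })
    list(t = (i - 1) / kp$fps, landmarks = landmarks)
  })
  obj <- list(camera = kp$camera, fps = kp$fps,
              image_size = kp$image_size, dialect = "pixel", frames = frames)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = digits,
                       pretty = FALSE)
  invisible(path)
}
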