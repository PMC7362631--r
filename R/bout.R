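#' Walking-bout container
#'
#' A `walking_bout` holds the per-frame joint coordinates of one walking bout
#' at a fixed frame rate, together with its identifiers. Frames are rows,
#' joints are columns; a frame in which no person was detected is an all-`NA`
#' row (missing frames are retained, not dropped, so time indexing stays
#' uniform). A bout is homogeneous: either 2D (pixel `u`, `v` image
#' coordinates, `v` increasing downward, plus detection `conf`idence) or 3D
#' (metric `x` medio-lateral, `y` vertical-up, `z` anterior-posterior).
#'
#' @param bout_id,participant_id Opaque identifiers.
#' @param frame_rate Frames per second (the study hardware records at 30 Hz).
#' @param date Calendar date of the recording (`Date` or parseable string).
#' @param u,v,conf For 2D bouts: numeric frame x joint matrices of horizontal
#'   and vertical pixel coordinates and keypoint confidence in `[0, 1]`.
#' @param x,y,z For 3D bouts: numeric frame x joint matrices in metres.
#' @param joints Canonical joint names (column names of the matrices).
#' @return An object of class `walking_bout`.
#' @export
walking_bout <- function(bout_id, participant_id, frame_rate, date = NA,
                         u = NULL, v = NULL, conf = NULL,
                         x = NULL, y = NULL, z = NULL,
                         joints = NULL) {
  is2d <- !is.null(u)
  if (is2d && !is.null(x)) stop("walking_bout: supply 2D (u,v) or 3D (x,y,z), not both")
  mats <- if (is2d) list(u = u, v = v) else list(x = x, y = y, z = z)
  if (any(vapply(mats, is.null, logical(1)))) {
    stop("walking_bout: incomplete coordinate matrices")
  }
  mats <- lapply(mats, as.matrix)
  dims <- unique(lapply(mats, dim))
  if (length(dims) != 1) stop("walking_bout: coordinate matrices differ in shape")
  n <- nrow(mats[[1]])
  if (n < 2) stop("walking_bout: at least 2 frames required")
  if (is.null(joints)) joints <- colnames(mats[[1]])
  if (is.null(joints)) stop("walking_bout: joint names required")
  mats <- lapply(mats, function(m) {
    colnames(m) <- joints
    m
  })
  if (is2d) {
    if (is.null(conf)) conf <- matrix(1, n, length(joints))
    conf <- as.matrix(conf)
    colnames(conf) <- joints
    if (any(conf < 0 | conf > 1, na.rm = TRUE)) {
      stop("walking_bout: confidence outside [0, 1]")
    }
    mats$conf <- conf
  }
  structure(
    c(
      list(
        bout_id = as.character(bout_id),
        participant_id = as.character(participant_id),
        date = if (inherits(date, "Date")) date else suppressWarnings(as.Date(date)),
        frame_rate = as.numeric(frame_rate),
        dim = if (is2d) "2d" else "3d",
        joints = joints
      ),
      mats
    ),
    class = "walking_bout"
  )
}

#' @export
print.walking_bout <- function(x, ...) {
  cat(sprintf(
    "<walking_bout %s> participant %s, %s, %d frames @ %g Hz (%.2f s), %d joints\n",
    x$bout_id, x$participant_id, x$dim, n_frames(x), x$frame_rate,
    bout_duration(x), length(x$joints)
  ))
  mf <- sum(missing_frames(x))
  if (mf > 0) cat(sprintf("  %d missing-person frame(s)\n", mf))
  invisible(x)
}

#' Bout geometry helpers
#'
#' `n_frames()` is the number of frames, `bout_duration()` the bout length in
#' seconds, `bout_times()` the frame timestamps (first frame at t = 0), and
#' `missing_frames()` flags frames where no person was detected (all
#' coordinates `NA`).
#'
#' @param bout A [walking_bout()].
#' @return See description.
#' @export
n_frames <- function(bout) nrow(bout[[if (bout$dim == "2d") "u" else "x"]])

#' @rdname n_frames
#' @export
bout_duration <- function(bout) n_frames(bout) / bout$frame_rate

#' @rdname n_frames
#' @export
bout_times <- function(bout) (seq_len(n_frames(bout)) - 1) / bout$frame_rate

#' @rdname n_frames
#' @export
missing_frames <- function(bout) {
  m <- if (bout$dim == "2d") is.na(bout$u) & is.na(bout$v) else {
    is.na(bout$x) & is.na(bout$y) & is.na(bout$z)
  }
  rowSums(!m) == 0
}

# extract one joint's coordinate column, with existence check
joint_col <- function(bout, coord, joint) {
  m <- bout[[coord]]
  if (!joint %in% colnames(m)) stop("joint not present in bout: ", joint)
  m[, joint]
}

#' Fill short tracking gaps by linear interpolation
#'
#' Missing coordinates (dropped frames or undetected joints) are filled
#' linearly when the gap spans at most `max_gap` frames; longer gaps are left
#' missing and downstream features treat them as unusable. Leading/trailing
#' missing frames are never extrapolated.
#'
#' @param bout A [walking_bout()].
#' @param max_gap Longest run of consecutive missing frames to fill (frames).
#' @return A `walking_bout` with short gaps interpolated.
#' @export
interpolate_gaps <- function(bout, max_gap = 5) {
  fill <- function(m) {
    apply(m, 2, function(col) {
      if (all(is.na(col)) || !anyNA(col)) return(col)
      zoo::na.approx(col, na.rm = FALSE, maxgap = max_gap)
    })
  }
  for (nm in intersect(c("u", "v", "x", "y", "z"), names(bout))) {
    bout[[nm]] <- fill(bout[[nm]])
  }
  bout
}

#' Rigidly transform a bout (testing and invariance checks)
#'
#' For 2D bouts, applies `scale * (u, v) + (du, dv)` — the uniform
#' scale-and-translate family that hip-distance normalization must cancel.
#' For 3D bouts, applies a rotation by `angle` about the vertical axis
#' followed by a translation, the family under which all 3D features are
#' invariant because the walking direction is estimated from the data.
#'
#' @param bout A [walking_bout()].
#' @param scale Uniform scale factor (2D only).
#' @param shift Numeric length-2 (2D: du, dv) or length-3 (3D: dx, dy, dz).
#' @param angle Rotation about the vertical axis in radians (3D only).
#' @return Transformed `walking_bout`.
#' @export
transform_bout <- function(bout, scale = 1, shift = c(0, 0, 0), angle = 0) {
  if (bout$dim == "2d") {
    bout$u <- scale * bout$u + shift[1]
    bout$v <- scale * bout$v + shift[2]
  } else {
    ca <- cos(angle); sa <- sin(angle)
    x <- bout$x; z <- bout$z
    bout$x <- ca * x - sa * z + shift[1]
    bout$y <- bout$y + shift[2]
    bout$z <- sa * x + ca * z + shift[3]
  }
  bout
}
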