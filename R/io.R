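#' Read and write 2D keypoint files
#'
#' Two on-disk dialects are supported and auto-detected by extension:
#'
#' * `.json`: per-frame records in an OpenPose-style layout — a top-level
#'   object with `joint_order`, bout identifiers, `frame_rate`, and a
#'   `frames` array of `{frame, people: [{pose_keypoints: [u1, v1, c1, ...]}]}`
#'   records. Frames whose `people` array is empty (no person detected) are
#'   kept as explicit missing frames.
#' * `.csv`: long format with columns `frame, joint, u, v, confidence`.
#'   Frames absent from the file between the observed minimum and maximum
#'   frame index are treated as missing-person frames.
#'
#' Joint labels are remapped through `map` (see [joint_map()]); an unknown
#' label is a configuration error, and non-monotone frame indices in the JSON
#' dialect are a format error.
#'
#' @param path File path.
#' @param map Joint-name mapping as accepted by [joint_map()].
#' @param frame_rate,bout_id,participant_id,date Metadata for the CSV dialect
#'   (the JSON dialect embeds them; arguments override when non-`NULL`).
#' @return A 2D [walking_bout()].
#' @export
read_keypoints_2d <- function(path, map = NULL, frame_rate = 30,
                              bout_id = NULL, participant_id = NULL,
                              date = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rec <- jsonlite::read_json(path, simplifyVector = FALSE)
    order_ext <- unlist(rec$joint_order)
    map <- joint_map(map, vocabulary = mpii_joints())
    joints <- remap_joints(order_ext, map)
    idx <- vapply(rec$frames, function(f) as.numeric(f$frame), numeric(1))
    if (any(diff(idx) <= 0)) stop("read_keypoints_2d: non-monotone frame indices")
    nj <- length(joints)
    n <- length(idx)
    u <- v <- conf <- matrix(NA_real_, n, nj, dimnames = list(NULL, joints))
    for (i in seq_len(n)) {
      ppl <- rec$frames[[i]]$people
      if (length(ppl) == 0) next
      kp <- unlist(ppl[[1]]$pose_keypoints)
      if (length(kp) != 3 * nj) stop("read_keypoints_2d: keypoint vector length mismatch")
      u[i, ] <- kp[seq(1, 3 * nj, by = 3)]
      v[i, ] <- kp[seq(2, 3 * nj, by = 3)]
      conf[i, ] <- kp[seq(3, 3 * nj, by = 3)]
    }
    conf[is.na(conf)] <- 0
    walking_bout(
      bout_id = bout_id %||% rec$bout_id %||% basename(path),
      participant_id = participant_id %||% rec$participant_id %||% NA_character_,
      date = date %||% rec$date %||% NA,
      frame_rate = frame_rate %||% rec$frame_rate %||% 30,
      u = u, v = v, conf = conf
    )
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("frame", "joint", "u", "v", "confidence")
    if (!all(need %in% names(d))) {
      stop("read_keypoints_2d: CSV must have columns ", paste(need, collapse = ", "))
    }
    map <- joint_map(map, vocabulary = mpii_joints())
    d$joint <- remap_joints(d$joint, map)
    joints <- intersect(mpii_joints(), unique(d$joint))
    fr_idx <- seq(min(d$frame), max(d$frame))
    n <- length(fr_idx)
    u <- v <- matrix(NA_real_, n, length(joints), dimnames = list(NULL, joints))
    conf <- matrix(0, n, length(joints), dimnames = list(NULL, joints))
    ri <- match(d$frame, fr_idx)
    ci <- match(d$joint, joints)
    u[cbind(ri, ci)] <- d$u
    v[cbind(ri, ci)] <- d$v
    conf[cbind(ri, ci)] <- d$confidence
    walking_bout(
      bout_id = bout_id %||% basename(path),
      participant_id = participant_id %||% NA_character_,
      date = date %||% NA, frame_rate = frame_rate,
      u = u, v = v, conf = conf
    )
  }
}

#' @rdname read_keypoints_2d
#' @param bout A 2D [walking_bout()] to serialize.
#' @export
write_keypoints_2d <- function(bout, path) {
  stopifnot(inherits(bout, "walking_bout"), bout$dim == "2d")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    frames <- lapply(seq_len(n_frames(bout)), function(i) {
      if (all(is.na(bout$u[i, ]))) {
        list(frame = i - 1, people = list())
      } else {
        kp <- as.numeric(rbind(bout$u[i, ], bout$v[i, ], bout$conf[i, ]))
        list(frame = i - 1, people = list(list(pose_keypoints = kp)))
      }
    })
    rec <- list(
      bout_id = bout$bout_id, participant_id = bout$participant_id,
      date = if (is.na(bout$date)) NULL else as.character(bout$date),
      frame_rate = bout$frame_rate, joint_order = bout$joints, frames = frames
    )
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    n <- n_frames(bout)
    d <- data.frame(
      frame = rep(seq_len(n) - 1, times = length(bout$joints)),
      joint = rep(bout$joints, each = n),
      u = as.numeric(bout$u), v = as.numeric(bout$v),
      confidence = as.numeric(bout$conf)
    )
    d <- d[!is.na(d$u) | !is.na(d$v), ]
    d <- d[order(d$frame, match(d$joint, bout$joints)), ]
    utils::write.csv(d, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read and write 3D keypoint files
#'
#' Long-format CSV with columns `frame, joint, x, y, z` (metres; `x`
#' medio-lateral, `y` vertical-up, `z` anterior-posterior), using the
#' Kinect-style 25-joint vocabulary of [kinect_joints()]. A file in which
#' `spine_base` is never observed is rejected, because the sacrum-based
#' features are then impossible.
#'
#' @inheritParams read_keypoints_2d
#' @return A 3D [walking_bout()].
#' @export
read_keypoints_3d <- function(path, frame_rate = 30, bout_id = NULL,
                              participant_id = NULL, date = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "joint", "x", "y", "z")
  if (!all(need %in% names(d))) {
    stop("read_keypoints_3d: CSV must have columns ", paste(need, collapse = ", "))
  }
  unknown <- setdiff(unique(d$joint), kinect_joints())
  if (length(unknown) > 0) {
    stop("read_keypoints_3d: unknown joint name(s): ", paste(unknown, collapse = ", "))
  }
  if (!any(d$joint == "spine_base" & !is.na(d$x))) {
    stop("read_keypoints_3d: spine_base missing in all frames; sacrum features impossible")
  }
  joints <- intersect(kinect_joints(), unique(d$joint))
  fr_idx <- seq(min(d$frame), max(d$frame))
  n <- length(fr_idx)
  x <- y <- z <- matrix(NA_real_, n, length(joints), dimnames = list(NULL, joints))
  ri <- match(d$frame, fr_idx)
  ci <- match(d$joint, joints)
  x[cbind(ri, ci)] <- d$x
  y[cbind(ri, ci)] <- d$y
  z[cbind(ri, ci)] <- d$z
  walking_bout(
    bout_id = bout_id %||% basename(path),
    participant_id = participant_id %||% NA_character_,
    date = date %||% NA, frame_rate = frame_rate,
    x = x, y = y, z = z
  )
}

#' @rdname read_keypoints_3d
#' @param bout A 3D [walking_bout()] to serialize.
#' @export
write_keypoints_3d <- function(bout, path) {
  stopifnot(inherits(bout, "walking_bout"), bout$dim == "3d")
  n <- n_frames(bout)
  d <- data.frame(
    frame = rep(seq_len(n) - 1, times = length(bout$joints)),
    joint = rep(bout$joints, each = n),
    x = as.numeric(bout$x), y = as.numeric(bout$y), z = as.numeric(bout$z)
  )
  d <- d[!is.na(d$x) | !is.na(d$y) | !is.na(d$z), ]
  d <- d[order(d$frame, match(d$joint, bout$joints)), ]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read bout metadata
#'
#' CSV with one row per bout: `bout_id, participant_id, date, age, sex,
#' updrs_gait, sas_gait, frame_rate`. Both clinical scores are integer 0-4
#' ordinal severity ratings (higher = more severe parkinsonism); rows with a
#' score outside that range are rejected.
#'
#' @param path CSV path.
#' @return `data.frame` of metadata.
#' @export
read_bout_metadata <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bout_id", "participant_id", "age", "sex", "updrs_gait", "sas_gait")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop("read_bout_metadata: missing column(s): ", paste(miss, collapse = ", "))
  }
  for (sc in c("updrs_gait", "sas_gait")) {
    bad <- !is.na(d[[sc]]) & !(d[[sc]] %in% 0:4)
    if (any(bad)) stop("read_bout_metadata: ", sc, " outside 0-4 in ", sum(bad), " row(s)")
  }
  if (!all(d$sex %in% c("male", "female", NA))) {
    stop("read_bout_metadata: sex must be 'male' or 'female'")
  }
  if ("date" %in% names(d)) d$date <- as.Date(d$date)
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
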