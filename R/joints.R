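#' Joint vocabularies
#'
#' Canonical joint names for the two skeleton dialects handled by the package:
#' an MPII-style 14-joint set for 2D pixel keypoints (head, neck, shoulders,
#' elbows, wrists, hips, knees, ankles) and a Kinect-style 25-joint set for 3D
#' metric skeletons, which includes `spine_base` (the sacrum proxy used for
#' centre-of-mass features).
#'
#' @return Character vector of canonical joint names.
#' @export
mpii_joints <- function() {
  c(
    "head", "neck",
    "l_shoulder", "r_shoulder",
    "l_elbow", "r_elbow",
    "l_wrist", "r_wrist",
    "l_hip", "r_hip",
    "l_knee", "r_knee",
    "l_ankle", "r_ankle"
  )
}

#' @rdname mpii_joints
#' @export
kinect_joints <- function() {
  c(
    "spine_base", "spine_mid", "neck", "head",
    "l_shoulder", "l_elbow", "l_wrist", "l_hand",
    "r_shoulder", "r_elbow", "r_wrist", "r_hand",
    "l_hip", "l_knee", "l_ankle", "l_foot",
    "r_hip", "r_knee", "r_ankle", "r_foot",
    "spine_shoulder",
    "l_hand_tip", "l_thumb", "r_hand_tip", "r_thumb"
  )
}

#' Build a joint-name mapping
#'
#' Maps external joint labels (as found in keypoint files) onto the canonical
#' vocabulary. The identity map over a vocabulary is the default; a YAML file
#' with `external: canonical` pairs can override it, because OpenPose/MPII and
#' Kinect exports label joints differently.
#'
#' @param x Either `NULL` (identity map over `vocabulary`), a named character
#'   vector (`names` = external labels, values = canonical names), or the path
#'   to a YAML file of `external: canonical` pairs.
#' @param vocabulary Canonical joint names the map must land in.
#' @return Named character vector mapping external labels to canonical names.
#' @export
joint_map <- function(x = NULL, vocabulary = mpii_joints()) {
  if (is.null(x)) {
    m <- stats::setNames(vocabulary, vocabulary)
  } else if (is.character(x) && length(x) == 1 && file.exists(x)) {
    y <- yaml::read_yaml(x)
    m <- stats::setNames(unlist(y, use.names = FALSE), names(y))
  } else if (is.character(x) && !is.null(names(x))) {
    m <- x
  } else {
    stop("joint_map: supply NULL, a named character vector, or a YAML path")
  }
  bad <- setdiff(unname(m), vocabulary)
  if (length(bad) > 0) {
    stop(
      "joint_map: mapped names not in vocabulary: ",
      paste(bad, collapse = ", ")
    )
  }
  m
}

# remap a vector of external joint labels; unknown labels are a configuration
# error (spec: unknown joint name -> configuration error)
remap_joints <- function(labels, map) {
  unknown <- setdiff(unique(labels), names(map))
  if (length(unknown) > 0) {
    stop(
      "unknown joint name(s): ", paste(unknown, collapse = ", "),
      " (not in joint map)"
    )
  }
  unname(map[labels])
}
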