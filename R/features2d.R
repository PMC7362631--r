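#' Hip-distance normalization of 2D keypoints
#'
#' Converts pixel keypoints into a per-frame body-scaled frame: coordinates
#' are expressed relative to the hip centre and divided by the left-right hip
#' keypoint distance of that frame. This cancels the participant's distance
#' to the camera (and any uniform scaling or translation of the pixel
#' coordinates), so all downstream 2D features are in hip-width units.
#' Frames whose hips nearly coincide (hip distance below 1e-6 of the bout
#' median) are marked unusable and set to `NA`.
#'
#' @param bout A 2D [walking_bout()].
#' @return List with frame x joint matrices `u`, `v` (hip-width units,
#'   relative to the hip centre), vector `hip_dist` (pixels) and logical
#'   `usable` per frame.
#' @export
normalize_by_hip_distance <- function(bout) {
  stopifnot(bout$dim == "2d")
  lu <- joint_col(bout, "u", "l_hip"); ru <- joint_col(bout, "u", "r_hip")
  lv <- joint_col(bout, "v", "l_hip"); rv <- joint_col(bout, "v", "r_hip")
  hd <- sqrt((lu - ru)^2 + (lv - rv)^2)
  med <- stats::median(hd, na.rm = TRUE)
  usable <- !is.na(hd) & is.finite(hd) & hd > 1e-6 * max(med, .Machine$double.xmin)
  cu <- (lu + ru) / 2
  cv <- (lv + rv) / 2
  scale <- ifelse(usable, hd, NA_real_)
  list(
    u = (bout$u - cu) / scale,
    v = (bout$v - cv) / scale,
    hip_dist = hd, usable = usable
  )
}

#' Cadence
#'
#' Steps per minute from the strike series: the number of inter-strike
#' intervals divided by the time from first to last strike, times 60.
#' Undefined (`NA`) with fewer than two strikes.
#'
#' @param strikes A [foot_strikes] object.
#' @return Cadence in steps/min, or `NA`.
#' @export
cadence <- function(strikes) {
  n <- nrow(strikes$strikes)
  if (n < 2) return(NA_real_)
  span <- strikes$strikes$time[n] - strikes$strikes$time[1]
  if (span <= 0) return(NA_real_)
  (n - 1) / span * 60
}

#' Symmetry index
#'
#' Robinson symmetry index of two per-side series (conventionally step
#' times): `SI = |mean_L - mean_R| / ((mean_L + mean_R)/2) * 100`, in
#' percent; 0 for perfect left-right symmetry.
#'
#' @param left_vals,right_vals Numeric per-side series (each non-empty).
#' @return SI in percent, or `NA` when the side means sum to zero.
#' @export
symmetry_index <- function(left_vals, right_vals) {
  left_vals <- left_vals[!is.na(left_vals)]
  right_vals <- right_vals[!is.na(right_vals)]
  if (length(left_vals) < 1 || length(right_vals) < 1) {
    stop("symmetry_index: both sides need at least one value")
  }
  ml <- mean(left_vals); mr <- mean(right_vals)
  if (ml + mr == 0) return(NA_real_)
  abs(ml - mr) / ((ml + mr) / 2) * 100
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean. Undefined (`NA`) for
#' fewer than two values or a zero mean.
#'
#' @param vals Numeric series.
#' @return Unitless CV, or `NA`.
#' @export
coefficient_of_variation <- function(vals) {
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2 || mean(vals) == 0) return(NA_real_)
  stats::sd(vals) / mean(vals)
}

#' Step-width series (2D)
#'
#' Per step, the horizontal (image-u, hip-normalized) distance between the
#' two ankles at the strike frame. One value per strike; `NA` where an ankle
#' is missing at that frame even after gap interpolation.
#'
#' @param bout A 2D [walking_bout()].
#' @param strikes A [foot_strikes] object for the bout.
#' @param max_gap Gap-interpolation limit (frames).
#' @return Numeric vector of widths in hip-width units (empty if < 2 strikes).
#' @export
step_width_series <- function(bout, strikes, max_gap = 5) {
  if (nrow(strikes$strikes) < 2) return(numeric(0))
  bout <- interpolate_gaps(bout, max_gap)
  nrm <- normalize_by_hip_distance(bout)
  idx <- pmin(pmax(round(strikes$strikes$time * bout$frame_rate) + 1, 1), n_frames(bout))
  abs(nrm$u[idx, "l_ankle"] - nrm$u[idx, "r_ankle"])
}

#' Extrapolated-centre-of-mass parameters (2D)
#'
#' The 2D extrapolated centre of mass (XCoM) is the hip-centre lateral
#' position plus `velocity_scale` times its lateral velocity, all in
#' hip-normalized units; `velocity_scale` plays the role of the inverted
#' pendulum's `1/omega0` (seconds). The default 0.3 s corresponds to
#' `omega0 = sqrt(g / l)` for an effective pendulum length of about 0.9 m.
#'
#' @param velocity_scale Seconds; non-negative.
#' @return List of class `xcom_params`.
#' @export
xcom_params <- function(velocity_scale = 0.3) {
  stopifnot(velocity_scale >= 0)
  structure(list(velocity_scale = velocity_scale), class = "xcom_params")
}

#' Margin of stability (2D)
#'
#' Lateral dynamic-balance measure in hip-normalized units. Per frame the
#' XCoM is the hip centre's lateral (image-u) position plus a
#' velocity-proportional offset (see [xcom_params()]), measured relative to
#' the stance-foot ankle — the lateral base-of-support boundary. The stance
#' foot at each frame is the one whose ankle has the smaller absolute
#' vertical velocity. `avg_mos` averages the magnitude of the XCoM-to-ankle
#' difference over all frames between the first and last strike; `avg_min_mos`
#' averages each step's minimum magnitude (the step's closest approach of
#' the XCoM to the base-of-support boundary).
#'
#' @param bout A 2D [walking_bout()].
#' @param strikes A [foot_strikes] object with at least 2 strikes.
#' @param p An [xcom_params()].
#' @param cfg A [step_config()] (smoothing/gap settings reused here).
#' @return List `avg_mos`, `avg_min_mos` (hip-width units), and the per-frame
#'   signed difference `d` for inspection.
#' @export
margin_of_stability <- function(bout, strikes, p = xcom_params(),
                                cfg = step_config()) {
  st <- strikes$strikes
  if (nrow(st) < 2) {
    return(list(avg_mos = NA_real_, avg_min_mos = NA_real_, d = NULL))
  }
  bout <- interpolate_gaps(bout, cfg$max_gap)
  nrm <- normalize_by_hip_distance(bout)
  fr <- bout$frame_rate
  vl <- central_diff(moving_average(-nrm$v[, "l_ankle"], cfg$smoothing_window), fr)
  vr <- central_diff(moving_average(-nrm$v[, "r_ankle"], cfg$smoothing_window), fr)
  stance_left <- abs(vl) <= abs(vr) # lower vertical ankle speed = stance foot
  ankle_u <- ifelse(stance_left, nrm$u[, "l_ankle"], nrm$u[, "r_ankle"])
  # hip-centre minus stance ankle, in hip-width units (hip centre is the
  # origin of the normalized frame, so the offset is just -ankle_u)
  o <- -ankle_u
  # lateral hip-centre velocity: pixel velocity scaled by the per-frame hip
  # distance (invariant to uniform scaling and translation of the pixels)
  cu <- (joint_col(bout, "u", "l_hip") + joint_col(bout, "u", "r_hip")) / 2
  hv <- central_diff(moving_average(cu, cfg$smoothing_window), fr) /
    ifelse(nrm$usable, nrm$hip_dist, NA_real_)
  d <- o + p$velocity_scale * hv
  n <- n_frames(bout)
  i0 <- max(1, round(st$time[1] * fr) + 1)
  i1 <- min(n, round(st$time[nrow(st)] * fr) + 1)
  win <- i0:i1
  avg_mos <- mean(abs(d[win]), na.rm = TRUE)
  mins <- vapply(seq_len(nrow(st) - 1), function(k) {
    a <- max(1, round(st$time[k] * fr) + 1)
    b <- min(n, round(st$time[k + 1] * fr) + 1)
    dk <- abs(d[a:b]) # closest approach of the XCoM to the boundary
    if (all(is.na(dk))) NA_real_ else min(dk, na.rm = TRUE)
  }, numeric(1))
  list(avg_mos = avg_mos, avg_min_mos = mean(mins, na.rm = TRUE), d = d)
}

#' Extract the eight 2D gait features of one bout
#'
#' Runs strike detection and computes, per bout: number of steps (strike
#' count), cadence (steps/min), symmetry index of step time (%), CV of step
#' time, average step width, CV of step width, and average / average-minimum
#' margin of stability (hip-width units). Features whose preconditions fail
#' (e.g. one side has no steps) are `NA`, not errors; the caller is expected
#' to have excluded bouts failing [qc_bout()].
#'
#' @param bout A 2D [walking_bout()].
#' @param cfg A [step_config()].
#' @param p An [xcom_params()].
#' @param strikes Optional precomputed [foot_strikes]; detected if `NULL`.
#' @return One-row `data.frame`: `bout_id`, `participant_id`, then
#'   `steps_of_walk, cadence, si_step_time, cv_step_time, avg_step_width,
#'   avg_mos, avg_min_mos, cv_step_width`.
#' @export
extract_features_2d <- function(bout, cfg = step_config(), p = xcom_params(),
                                strikes = NULL) {
  stopifnot(bout$dim == "2d")
  if (is.null(strikes)) strikes <- detect_foot_strikes(bout, cfg)
  stt <- strikes$step_times
  sts <- strikes$step_sides
  si <- if (sum(sts == "left") >= 1 && sum(sts == "right") >= 1) {
    symmetry_index(stt[sts == "left"], stt[sts == "right"])
  } else {
    NA_real_
  }
  widths <- step_width_series(bout, strikes, cfg$max_gap)
  mos <- margin_of_stability(bout, strikes, p, cfg)
  data.frame(
    bout_id = bout$bout_id, participant_id = bout$participant_id,
    steps_of_walk = nrow(strikes$strikes),
    cadence = cadence(strikes),
    si_step_time = si,
    cv_step_time = coefficient_of_variation(stt),
    avg_step_width = if (length(widths) > 0) mean(widths, na.rm = TRUE) else NA_real_,
    avg_mos = mos$avg_mos,
    avg_min_mos = mos$avg_min_mos,
    cv_step_width = coefficient_of_variation(widths),
    stringsAsFactors = FALSE
  )
}

#' @rdname extract_features_2d
#' @export
features_2d_names <- function() {
  c(
    "steps_of_walk", "cadence", "si_step_time", "cv_step_time",
    "avg_step_width", "avg_mos", "avg_min_mos", "cv_step_width"
  )
}
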