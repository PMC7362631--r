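#' Walking-direction frame of a 3D bout
#'
#' The anterior-posterior (AP) axis is estimated per bout as the first
#' principal axis of the horizontal sacrum (`spine_base`) path, oriented
#' along the net displacement; medio-lateral (ML) is its horizontal
#' perpendicular. Estimating the frame from the data makes all 3D features
#' invariant to rigid translation and to rotation about the vertical axis.
#'
#' @param bout A 3D [walking_bout()].
#' @return List with unit vectors `ap`, `ml` (in the horizontal x-z plane)
#'   and functions of no arguments returning per-frame `ap_pos` and `ml_pos`
#'   of any horizontal point via `project(px, pz)`.
#' @keywords internal
walking_frame <- function(bout) {
  sx <- joint_col(bout, "x", "spine_base")
  sz <- joint_col(bout, "z", "spine_base")
  ok <- !is.na(sx) & !is.na(sz)
  if (sum(ok) < 3) stop("walking_frame: spine_base present on < 3 frames")
  m <- cbind(sx[ok], sz[ok])
  cc <- colMeans(m)
  cv <- stats::cov(m)
  if (!all(is.finite(cv))) cv <- diag(2) * 0
  ev <- eigen(cv, symmetric = TRUE)
  ap <- ev$vectors[, 1]
  net <- m[nrow(m), ] - m[1, ]
  if (sum(net * ap) < 0) ap <- -ap
  ml <- c(-ap[2], ap[1])
  list(
    ap = ap, ml = ml,
    project = function(px, pz) {
      list(
        ap = (px - cc[1]) * ap[1] + (pz - cc[2]) * ap[2],
        ml = (px - cc[1]) * ml[1] + (pz - cc[2]) * ml[2]
      )
    }
  )
}

#' Spatiotemporal 3D gait features
#'
#' From the strike series and the sacrum trajectory: step length (AP sacrum
#' displacement between consecutive contralateral strikes, m), step time
#' (inter-strike interval, s), step width (ML ankle separation at the strike
#' frame, m), walking speed (net AP sacrum displacement over the
#' first-to-last-strike window, m/s), cadence (steps/min), and the CV of the
#' step length/time/width series. Per-side means are also returned for the
#' symmetry angles.
#'
#' @param bout A 3D [walking_bout()].
#' @param strikes A [foot_strikes] object (>= 3 strikes for defined output).
#' @return List of scalars and per-side summaries; `NA`s when undefined
#'   (fewer than 2 strikes, or no net AP displacement for speed).
#' @export
spatiotemporal_3d <- function(bout, strikes) {
  st <- strikes$strikes
  empty <- list(
    walking_speed = NA_real_, step_length = NA_real_, step_time = NA_real_,
    step_width = NA_real_, cadence = NA_real_,
    cv_step_length = NA_real_, cv_step_time = NA_real_, cv_step_width = NA_real_,
    lengths = numeric(0), times = numeric(0), widths = numeric(0),
    sides = character(0)
  )
  if (is.null(st) || nrow(st) < 2) return(empty)
  frm <- walking_frame(bout)
  t_all <- bout_times(bout)
  sac <- frm$project(joint_col(bout, "x", "spine_base"), joint_col(bout, "z", "spine_base"))
  ok <- !is.na(sac$ap)
  ap_at <- stats::approx(t_all[ok], sac$ap[ok], xout = st$time, rule = 2)$y
  lengths <- abs(diff(ap_at))
  times <- diff(st$time)
  sides <- st$side[-1] # step attributed to the foot striking at its end
  la <- frm$project(joint_col(bout, "x", "l_ankle"), joint_col(bout, "z", "l_ankle"))
  ra <- frm$project(joint_col(bout, "x", "r_ankle"), joint_col(bout, "z", "r_ankle"))
  idx <- pmin(pmax(round(st$time * bout$frame_rate) + 1, 1), n_frames(bout))
  widths <- abs(la$ml[idx] - ra$ml[idx])
  disp <- abs(ap_at[length(ap_at)] - ap_at[1])
  span <- st$time[nrow(st)] - st$time[1]
  speed <- if (disp < 1e-9 || span <= 0) NA_real_ else disp / span
  list(
    walking_speed = speed,
    step_length = mean(lengths, na.rm = TRUE),
    step_time = mean(times),
    step_width = mean(widths, na.rm = TRUE),
    cadence = cadence(strikes),
    cv_step_length = coefficient_of_variation(lengths),
    cv_step_time = coefficient_of_variation(times),
    cv_step_width = coefficient_of_variation(widths),
    lengths = lengths, times = times, widths = widths,
    width_sides = st$side, sides = sides
  )
}

#' Symmetry angle
#'
#' Bilateral asymmetry of a gait variable following the symmetry-angle
#' convention: `SA = (45 - atan(left/right) * 180/pi) / 90 * 100`. Zero for
#' perfect symmetry, sign flips under a left/right swap, undefined when both
#' sides are zero.
#'
#' @param left_mean,right_mean Per-side mean values.
#' @return Symmetry angle (degrees-based, normalized by 90).
#' @export
symmetry_angle <- function(left_mean, right_mean) {
  if (is.na(left_mean) || is.na(right_mean)) return(NA_real_)
  if (left_mean == 0 && right_mean == 0) return(NA_real_)
  ang <- atan2(left_mean, right_mean) * 180 / pi
  (45 - ang) / 90 * 100
}

#' Sacrum medio-lateral dynamics
#'
#' The sacrum's ML trajectory (perpendicular to the estimated walking
#' direction), detrended by the mean path: a linear drift term is estimated
#' jointly with the dominant sway oscillation (periodogram peak frequency,
#' one sine/cosine pair) and only the drift is subtracted. Estimating the
#' drift jointly keeps a finite stretch of periodic sway from biasing the
#' slope, which would otherwise inflate the range of motion. Returns the
#' standard deviation and range of motion (max - min) of the detrended ML
#' position (m) and the RMS of its time derivative (m/s).
#'
#' @param bout A 3D [walking_bout()].
#' @return List `rms_velocity`, `sd`, `rom`.
#' @export
sacrum_ml_dynamics <- function(bout) {
  frm <- walking_frame(bout)
  ml <- frm$project(joint_col(bout, "x", "spine_base"), joint_col(bout, "z", "spine_base"))$ml
  t <- bout_times(bout)
  ok <- !is.na(ml)
  if (sum(ok) < 3) return(list(rms_velocity = NA_real_, sd = NA_real_, rom = NA_real_))
  x <- ml[ok]
  tt <- t[ok]
  design <- cbind(1, tt)
  if (length(x) >= 16 && stats::sd(x) > 0) {
    # dominant oscillation from the raw periodogram (DC excluded)
    dm <- x - mean(x)
    pw <- Mod(stats::fft(dm))^2
    half <- 2:floor(length(x) / 2)
    k <- half[which.max(pw[half])]
    fhat <- (k - 1) * bout$frame_rate / length(x)
    design <- cbind(design, sin(2 * pi * fhat * tt), cos(2 * pi * fhat * tt))
  }
  fit <- stats::lm.fit(design, x)
  drift <- design[, 1:2, drop = FALSE] %*% fit$coefficients[1:2]
  res <- rep(NA_real_, length(ml))
  res[ok] <- x - drift
  vel <- central_diff(res, bout$frame_rate)
  list(
    rms_velocity = sqrt(mean(vel^2, na.rm = TRUE)),
    sd = stats::sd(res, na.rm = TRUE),
    rom = max(res, na.rm = TRUE) - min(res, na.rm = TRUE)
  )
}

#' Margin of stability (3D)
#'
#' Lateral margin of stability from the inverted-pendulum extrapolated
#' centre of mass: `XCoM = sacrum ML + (sacrum ML velocity) / omega0` with
#' `omega0 = sqrt(g / leg_length)`, `g = 9.81 m/s^2`. The per-frame MOS is
#' the distance from the XCoM to the lateral base-of-support boundary (the
#' stance ankle's ML position), signed positive when the XCoM lies medial of
#' the stance ankle. `avg_mos` is the mean magnitude over the strike-to-
#' strike window; `min_mos` is the minimum over steps of each step's minimum.
#' Reported in millimetres.
#'
#' @param bout A 3D [walking_bout()].
#' @param strikes A [foot_strikes] object.
#' @param leg_length Pendulum length in metres; when `NULL`, estimated as
#'   53% of stature, itself estimated from the skeleton's vertical span.
#' @param cfg A [step_config()] (smoothing window reused for velocities).
#' @return List `avg_mos`, `min_mos` (mm) and per-frame `mos` (m).
#' @export
margin_of_stability_3d <- function(bout, strikes, leg_length = NULL,
                                   cfg = step_config(
                                     min_peak_velocity = 0.05,
                                     velocity_smoothing = 3
                                   )) {
  st <- strikes$strikes
  if (is.null(st) || nrow(st) < 2) {
    return(list(avg_mos = NA_real_, min_mos = NA_real_, mos = NULL))
  }
  if (is.null(leg_length)) leg_length <- 0.53 * estimate_stature(bout)
  if (!is.finite(leg_length) || leg_length <= 0) {
    stop("margin_of_stability_3d: leg_length unavailable and not estimable")
  }
  omega0 <- sqrt(9.81 / leg_length)
  frm <- walking_frame(bout)
  fr <- bout$frame_rate
  sac <- frm$project(joint_col(bout, "x", "spine_base"), joint_col(bout, "z", "spine_base"))
  ml_s <- moving_average(sac$ml, cfg$smoothing_window)
  xcom <- ml_s + central_diff(ml_s, fr) / omega0
  vl <- central_diff(moving_average(joint_col(bout, "y", "l_ankle"), cfg$smoothing_window), fr)
  vr <- central_diff(moving_average(joint_col(bout, "y", "r_ankle"), cfg$smoothing_window), fr)
  stance_left <- abs(vl) <= abs(vr)
  la <- frm$project(joint_col(bout, "x", "l_ankle"), joint_col(bout, "z", "l_ankle"))$ml
  ra <- frm$project(joint_col(bout, "x", "r_ankle"), joint_col(bout, "z", "r_ankle"))$ml
  ankle_ml <- ifelse(stance_left, la, ra)
  outward <- sign(ankle_ml - sac$ml)
  outward[outward == 0] <- 1
  mos <- outward * (ankle_ml - xcom)
  n <- n_frames(bout)
  i0 <- max(1, round(st$time[1] * fr) + 1)
  i1 <- min(n, round(st$time[nrow(st)] * fr) + 1)
  avg <- mean(abs(mos[i0:i1]), na.rm = TRUE)
  mins <- vapply(seq_len(nrow(st) - 1), function(k) {
    a <- max(1, round(st$time[k] * fr) + 1)
    b <- min(n, round(st$time[k + 1] * fr) + 1)
    mk <- mos[a:b]
    if (all(is.na(mk))) NA_real_ else min(mk, na.rm = TRUE)
  }, numeric(1))
  list(
    avg_mos = 1000 * avg,
    min_mos = if (all(is.na(mins))) NA_real_ else 1000 * min(mins, na.rm = TRUE),
    mos = mos
  )
}

# stature from the skeleton: vertical span from the head joint down to the
# lower ankle, plus an offset for the head-joint-to-crown and ankle-to-sole
# distances
estimate_stature <- function(bout) {
  head_y <- mean(joint_col(bout, "y", "head"), na.rm = TRUE)
  ankle_y <- mean(pmin(
    joint_col(bout, "y", "l_ankle"), joint_col(bout, "y", "r_ankle")
  ), na.rm = TRUE)
  (head_y - ankle_y) + 0.12
}

#' Extract the sixteen 3D gait features of one bout
#'
#' Runs 3D strike detection and computes the full 3D feature set:
#' spatiotemporal (walking speed, step length/time/width, cadence), their
#' CVs, per-variable symmetry angles, sacrum ML dynamics (RMS velocity, SD,
#' ROM) and average/minimum margin of stability (mm). Undefined features are
#' `NA`.
#'
#' @param bout A 3D [walking_bout()].
#' @param cfg A [step_config()] (`min_peak_velocity` in m/s).
#' @param leg_length Optional pendulum length override (m).
#' @param strikes Optional precomputed [foot_strikes].
#' @return One-row `data.frame` with ids and 16 feature columns.
#' @export
extract_features_3d <- function(bout,
                                cfg = step_config(
                                  min_peak_velocity = 0.05,
                                  velocity_smoothing = 3
                                ),
                                leg_length = NULL, strikes = NULL) {
  stopifnot(bout$dim == "3d")
  if (is.null(strikes)) strikes <- detect_foot_strikes_3d(bout, cfg)
  sp <- spatiotemporal_3d(bout, strikes)
  sa_of <- function(vals, sides) {
    if (sum(sides == "left") >= 1 && sum(sides == "right") >= 1) {
      symmetry_angle(
        mean(vals[sides == "left"], na.rm = TRUE),
        mean(vals[sides == "right"], na.rm = TRUE)
      )
    } else {
      NA_real_
    }
  }
  sac <- sacrum_ml_dynamics(bout)
  mos <- margin_of_stability_3d(bout, strikes, leg_length, cfg)
  data.frame(
    bout_id = bout$bout_id, participant_id = bout$participant_id,
    walking_speed = sp$walking_speed,
    step_length = sp$step_length,
    step_time = sp$step_time,
    step_width = sp$step_width,
    cadence = sp$cadence,
    cv_step_length = sp$cv_step_length,
    cv_step_time = sp$cv_step_time,
    cv_step_width = sp$cv_step_width,
    sa_step_length = sa_of(sp$lengths, sp$sides),
    sa_step_time = sa_of(sp$times, sp$sides),
    sa_step_width = sa_of(sp$widths, sp$width_sides),
    rms_sacrum_ml_velocity = sac$rms_velocity,
    sd_sacrum_ml = sac$sd,
    rom_sacrum_ml = sac$rom,
    avg_mos = mos$avg_mos,
    min_mos = mos$min_mos,
    stringsAsFactors = FALSE
  )
}

#' @rdname extract_features_3d
#' @export
features_3d_names <- function() {
  c(
    "walking_speed", "step_length", "step_time", "step_width", "cadence",
    "cv_step_length", "cv_step_time", "cv_step_width",
    "sa_step_length", "sa_step_time", "sa_step_width",
    "rms_sacrum_ml_velocity", "sd_sacrum_ml", "rom_sacrum_ml",
    "avg_mos", "min_mos"
  )
}
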