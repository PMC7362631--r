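#' Gait parameters for the synthetic walker
#'
#' Kinematic ground-truth parameters of one simulated walking bout. The
#' walker advances along a hallway toward a ceiling-mounted camera at the
#' cadence/step length implied speed, with sinusoidal medio-lateral pelvis
#' sway phase-locked to the steps; each ankle alternates stance (fixed on
#' the ground) and swing (raised-cosine vertical lift, smooth horizontal
#' progression). Step timing is jittered multiplicatively by `step_time_cv`
#' and split left/right by `step_time_asymmetry` (fractional difference of
#' the side means).
#'
#' @param cadence Steps per minute.
#' @param step_length Metres per step.
#' @param step_width Lateral ankle-to-ankle distance (m).
#' @param step_time_cv Coefficient of variation of step time.
#' @param step_time_asymmetry Fractional left/right mean step-time
#'   difference, in `[0, 0.5]`.
#' @param step_length_asymmetry Fractional reduction of pelvis advance
#'   during left-ending steps (in `[0, 0.5]`): the affected side pushes off
#'   weakly, so its steps are shorter in distance even when longer in time.
#'   Zero keeps step length proportional to step time.
#' @param ml_sway_amplitude Pelvis ML sway amplitude (m).
#' @param keypoint_noise_sd Gaussian keypoint noise SD: hip-width units for
#'   2D output, metres for 3D output.
#' @param n_steps Number of foot strikes in the bout.
#' @param frame_rate Hz (study hardware: 30).
#' @param swing_fraction Swing duration as a fraction of the nominal stride
#'   time. Held fixed at its nominal value (not jittered per step) so that
#'   the constant detection offset of the 35% rule cancels in step
#'   intervals.
#' @param step_height Peak vertical ankle lift in swing (m).
#' @param stature,hip_width Body geometry (m).
#' @return List of class `gait_params`.
#' @export
gait_params <- function(cadence = 105, step_length = 0.6, step_width = 0.1,
                        step_time_cv = 0.03, step_time_asymmetry = 0.05,
                        step_length_asymmetry = 0,
                        ml_sway_amplitude = 0.04, keypoint_noise_sd = 0,
                        n_steps = 10, frame_rate = 30,
                        swing_fraction = 0.35, step_height = 0.08,
                        stature = 1.70, hip_width = 0.25) {
  stopifnot(
    cadence > 0, step_length > 0, step_width > 0, step_time_cv >= 0,
    step_time_asymmetry >= 0, step_time_asymmetry <= 0.5,
    step_length_asymmetry >= 0, step_length_asymmetry <= 0.5,
    ml_sway_amplitude >= 0, keypoint_noise_sd >= 0, n_steps >= 2,
    frame_rate > 0, swing_fraction > 0, swing_fraction < 1,
    step_height > 0, stature > 0, hip_width > 0
  )
  structure(as.list(environment()), class = "gait_params")
}

# raised-cosine swing lift: 0 at both ends, peak `a` mid-swing
swing_lift <- function(s, a) a / 2 * (1 - cos(2 * pi * s))

# smoothstep for horizontal foot progression during swing
smoothstep <- function(s) s * s * (3 - 2 * s)

#' Simulate one walking bout with ground truth
#'
#' Builds the strike schedule (alternating sides, jittered step times, first
#' strike after a short lead-in), the 3D joint trajectories of a
#' Kinect-style 25-joint skeleton, and — for 2D output — projects the
#' MPII-style 14-joint subset through a perspective camera mounted ahead of
#' and above the walker (1920x1080, the walker approaching the camera), then
#' adds Gaussian keypoint noise. Deterministic given `seed`.
#'
#' @param params A [gait_params()].
#' @param dim `"2d"` or `"3d"`.
#' @param seed Integer seed.
#' @param bout_id,participant_id,date Identifiers stamped on the bout.
#' @return List with `bout` (a [walking_bout()]) and `truth` (list:
#'   `strike_times`, `strike_sides`, `params`, plus the camera used for 2D).
#' @export
simulate_bout <- function(params, dim = c("3d", "2d"), seed = 1,
                          bout_id = "sim", participant_id = "p1", date = NA) {
  dim <- match.arg(dim)
  stopifnot(inherits(params, "gait_params"))
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    simulate_bout_impl(params, dim, bout_id, participant_id, date)
  })
}

simulate_bout_impl <- function(p, dim, bout_id, participant_id, date) {
  fr <- p$frame_rate
  t_mean <- 60 / p$cadence
  t_side <- c(
    left = t_mean * (1 + p$step_time_asymmetry / 2),
    right = t_mean * (1 - p$step_time_asymmetry / 2)
  )
  sides <- rep(c("left", "right"), length.out = p$n_steps)
  jit <- pmax(0.5, 1 + p$step_time_cv * stats::rnorm(p$n_steps))
  intervals <- unname(t_side[sides]) * jit
  lead_in <- 0.8
  strike_times <- lead_in + cumsum(c(0, intervals[-1]))
  if (any(diff(strike_times) <= 0)) stop("simulate_bout: overlapping strikes")
  duration <- min(strike_times[p$n_steps] + 0.7, 30)
  n <- ceiling(duration * fr)
  t <- (seq_len(n) - 1) / fr
  speed <- p$step_length / t_mean
  stride_t <- 2 * t_mean
  t_swing <- p$swing_fraction * stride_t

  # pelvis path: piecewise-constant forward speed per step (slower while the
  # affected left side is the one stepping, when step_length_asymmetry > 0),
  # sinusoidal ML sway phase-locked to the nominal step frequency, walking
  # along -z (toward a camera at z = 0)
  a_len <- p$step_length_asymmetry
  mult <- ifelse(sides == "left", 1 - a_len / 2, 1 + a_len / 2)
  z0 <- speed * duration + 2.5
  knot_t <- c(0, strike_times, duration + 1 / fr)
  seg_v <- speed * c(1, mult[-1], 1) # lead-in and run-out at nominal speed
  knot_pos <- z0 - cumsum(c(0, seg_v * diff(knot_t)))
  pelvis_ap_at <- stats::approxfun(knot_t, knot_pos, rule = 2)
  pel_z <- pelvis_ap_at(t)
  pel_x <- p$ml_sway_amplitude * sin(2 * pi * (t - lead_in + t_mean / 2) / stride_t)
  pel_y <- rep(0.55 * p$stature, n)

  # per-foot landing schedule: foot placed half a step ahead of the pelvis
  # at its strike, held during stance, advanced during swing
  half_w <- p$step_width / 2
  foot_traj <- function(side) {
    sgn <- if (side == "left") 1 else -1
    idx <- which(sides == side)
    times_s <- strike_times[idx]
    land_z <- pelvis_ap_at(times_s) - p$step_length / 2
    # start in steady-state gait: the foot stands where its previous (virtual,
    # pre-recording) strike would have placed it, one stride behind the first
    # landing, so the first recorded swing matches all later ones
    pre_z <- land_z[1] + 2 * p$step_length
    xs <- rep(sgn * half_w, n)
    ys <- numeric(n)
    zs <- numeric(n)
    ankle_h <- 0.08 # ankle-joint height above ground in stance
    for (i in seq_len(n)) {
      ti <- t[i]
      k <- findInterval(ti, times_s) # last strike of this foot at/before ti
      if (k >= length(times_s)) { # after last landing: stance forever
        zs[i] <- land_z[length(times_s)]
        ys[i] <- ankle_h
        next
      }
      nxt <- times_s[k + 1]
      cur_z <- if (k == 0) pre_z else land_z[k]
      sw_start <- nxt - t_swing
      if (ti < sw_start) {
        zs[i] <- cur_z
        ys[i] <- ankle_h
      } else {
        s <- (ti - sw_start) / t_swing
        zs[i] <- cur_z + (land_z[k + 1] - cur_z) * smoothstep(s)
        ys[i] <- ankle_h + swing_lift(s, p$step_height)
      }
    }
    list(x = xs, y = ys, z = zs)
  }
  lf <- foot_traj("left")
  rf <- foot_traj("right")

  hw <- p$hip_width / 2
  sh_y <- 0.82 * p$stature
  joints3 <- list(
    spine_base = list(x = pel_x, y = pel_y, z = pel_z),
    spine_mid = list(x = pel_x, y = pel_y + 0.15 * p$stature, z = pel_z),
    spine_shoulder = list(x = pel_x, y = sh_y, z = pel_z),
    neck = list(x = pel_x, y = sh_y + 0.03, z = pel_z),
    head = list(x = pel_x, y = 0.93 * p$stature, z = pel_z),
    l_shoulder = list(x = pel_x + 0.20, y = sh_y, z = pel_z),
    r_shoulder = list(x = pel_x - 0.20, y = sh_y, z = pel_z),
    l_elbow = list(x = pel_x + 0.23, y = sh_y - 0.18, z = pel_z),
    r_elbow = list(x = pel_x - 0.23, y = sh_y - 0.18, z = pel_z),
    l_wrist = list(x = pel_x + 0.24, y = sh_y - 0.40, z = pel_z),
    r_wrist = list(x = pel_x - 0.24, y = sh_y - 0.40, z = pel_z),
    l_hand = list(x = pel_x + 0.24, y = sh_y - 0.46, z = pel_z),
    r_hand = list(x = pel_x - 0.24, y = sh_y - 0.46, z = pel_z),
    l_hand_tip = list(x = pel_x + 0.24, y = sh_y - 0.50, z = pel_z),
    r_hand_tip = list(x = pel_x - 0.24, y = sh_y - 0.50, z = pel_z),
    l_thumb = list(x = pel_x + 0.22, y = sh_y - 0.44, z = pel_z),
    r_thumb = list(x = pel_x - 0.22, y = sh_y - 0.44, z = pel_z),
    l_hip = list(x = pel_x + hw, y = pel_y, z = pel_z),
    r_hip = list(x = pel_x - hw, y = pel_y, z = pel_z),
    l_knee = list(
      x = (pel_x + hw + lf$x) / 2, y = (pel_y + lf$y) / 2 + 0.02,
      z = (pel_z + lf$z) / 2
    ),
    r_knee = list(
      x = (pel_x - hw + rf$x) / 2, y = (pel_y + rf$y) / 2 + 0.02,
      z = (pel_z + rf$z) / 2
    ),
    l_ankle = lf,
    r_ankle = rf,
    l_foot = list(x = lf$x, y = lf$y - 0.04, z = lf$z - 0.12),
    r_foot = list(x = rf$x, y = rf$y - 0.04, z = rf$z - 0.12)
  )

  truth <- list(
    strike_times = strike_times, strike_sides = sides,
    params = p, speed = speed, duration = n / fr
  )

  rep_n <- function(a) rep(a, length.out = n)
  if (dim == "3d") {
    jn <- kinect_joints()
    x <- vapply(jn, function(j) rep_n(joints3[[j]]$x), numeric(n))
    y <- vapply(jn, function(j) rep_n(joints3[[j]]$y), numeric(n))
    z <- vapply(jn, function(j) rep_n(joints3[[j]]$z), numeric(n))
    if (p$keypoint_noise_sd > 0) {
      x <- x + stats::rnorm(length(x), 0, p$keypoint_noise_sd)
      y <- y + stats::rnorm(length(y), 0, p$keypoint_noise_sd)
      z <- z + stats::rnorm(length(z), 0, p$keypoint_noise_sd)
    }
    bout <- walking_bout(
      bout_id = bout_id, participant_id = participant_id, date = date,
      frame_rate = fr, x = x, y = y, z = z, joints = jn
    )
    return(list(bout = bout, truth = truth))
  }

  # 2D: perspective projection through a ceiling-mounted camera at z = 0
  # looking down the hallway (the walker approaches the camera)
  cam <- list(h = 2.3, pitch = 12 * pi / 180, f = 1050, cx = 960, cy = 540)
  project <- function(j) {
    X <- rep_n(j$x)
    Y <- rep_n(j$y) - cam$h
    Z <- rep_n(j$z)
    cp <- cos(cam$pitch); sp <- sin(cam$pitch)
    zc <- cp * Z - sp * Y # forward
    yd <- -(cp * Y + sp * Z) # image-down component
    list(u = cam$cx + cam$f * X / zc, v = cam$cy + cam$f * yd / zc)
  }
  jn <- mpii_joints()
  u <- vapply(jn, function(j) project(joints3[[j]])$u, numeric(n))
  v <- vapply(jn, function(j) project(joints3[[j]])$v, numeric(n))
  if (p$keypoint_noise_sd > 0) {
    hip_px <- sqrt((u[, "l_hip"] - u[, "r_hip"])^2 + (v[, "l_hip"] - v[, "r_hip"])^2)
    u <- u + stats::rnorm(length(u), 0, p$keypoint_noise_sd) * hip_px
    v <- v + stats::rnorm(length(v), 0, p$keypoint_noise_sd) * hip_px
  }
  truth$camera <- cam
  bout <- walking_bout(
    bout_id = bout_id, participant_id = participant_id, date = date,
    frame_rate = fr, u = u, v = v,
    conf = matrix(1, n, length(jn)), joints = jn
  )
  list(bout = bout, truth = truth)
}

#' Severity model mapping latent parkinsonism to gait and scores
#'
#' The generative twin of the analysis: a latent severity scalar in `[0, 4]`
#' drives the gait parameters monotonically (lower cadence and step length,
#' higher timing variability and asymmetry, narrower steps, more ML sway
#' with increasing severity), and ordinal clinical scores are drawn from a
#' proportional-odds model `logit P(score <= j) = theta_j - slope * severity`
#' with cutpoints at the category midpoints.
#'
#' @param effect_map Function severity -> [gait_params()].
#' @param slope Discrimination of the ordinal score model.
#' @param cutpoint_centers Severity values at the category boundaries.
#' @return List of class `severity_model` with `effect_map`, `slope`,
#'   `cutpoints`.
#' @export
severity_model <- function(effect_map = NULL, slope = 2.2,
                           cutpoint_centers = c(0.5, 1.5, 2.5, 3.5)) {
  if (is.null(effect_map)) {
    effect_map <- function(s, noise_2d = 0.02, noise_3d = 0.005, dim = "3d") {
      gait_params(
        cadence = 108 - 10 * s,
        step_length = max(0.64 - 0.09 * s, 0.15),
        step_width = max(0.13 - 0.015 * s, 0.05),
        step_time_cv = 0.025 + 0.02 * s,
        step_time_asymmetry = min(0.02 + 0.035 * s, 0.5),
        step_length_asymmetry = min(0.03 + 0.06 * s, 0.5),
        ml_sway_amplitude = 0.035 + 0.012 * s,
        keypoint_noise_sd = if (dim == "2d") noise_2d else noise_3d,
        n_steps = max(4, round(6 / max(0.64 - 0.09 * s, 0.15)))
      )
    }
  }
  structure(
    list(
      effect_map = effect_map, slope = slope,
      cutpoints = slope * cutpoint_centers
    ),
    class = "severity_model"
  )
}

#' Ordinal score probabilities implied by a severity model
#'
#' @param model A [severity_model()].
#' @param severity Latent severity value(s).
#' @return Matrix (length(severity) x 5) of category probabilities.
#' @export
score_probabilities <- function(model, severity) {
  eta <- model$slope * severity
  cum <- vapply(model$cutpoints, function(th) stats::plogis(th - eta),
    numeric(length(eta))
  )
  cum <- matrix(cum, nrow = length(eta))
  pr <- cbind(cum, 1) - cbind(0, cum)
  colnames(pr) <- as.character(0:4)
  pr
}

draw_score <- function(model, severity) {
  pr <- score_probabilities(model, severity)
  vapply(seq_len(nrow(pr)), function(i) {
    sample(0:4, 1, prob = pr[i, ])
  }, numeric(1))
}

#' Simulate a longitudinal cohort of walking bouts
#'
#' Emulates the study design: `n_participants` older adults (age drawn from
#' a truncated normal matching the study cohort, 57% male) each contribute
#' `bouts_per_participant` bouts over consecutive days. Per-bout latent
#' severity is the participant's baseline plus a piecewise-linear temporal
#' drift (medication-change dynamics) plus noise, clamped to `[0, 4]`; gait
#' parameters follow the model's effect map and UPDRS-gait / SAS-gait scores
#' are drawn from its ordinal model. All ground truth is returned.
#'
#' @param n_participants,bouts_per_participant Cohort dimensions (study
#'   scale: 14 participants, ~28 bouts each).
#' @param model A [severity_model()].
#' @param dim `"2d"` or `"3d"` bouts.
#' @param seed Integer seed (drives everything).
#' @param noise_2d,noise_3d Keypoint noise SDs passed to the effect map.
#' @return List `bouts` (list of [walking_bout()]), `meta` (metadata
#'   data.frame), `truth` (per-bout severities, strike schedules, params).
#' @export
simulate_cohort <- function(n_participants = 14, bouts_per_participant = 28,
                            model = severity_model(), dim = c("3d", "2d"),
                            seed = 1, noise_2d = 0.02, noise_3d = 0.005) {
  dim <- match.arg(dim)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    bouts <- list()
    truth <- list()
    meta <- list()
    for (i in seq_len(n_participants)) {
      pid <- sprintf("p%02d", i)
      age <- round(min(max(stats::rnorm(1, 76.2, 8.7), 60), 95))
      sex <- if (stats::runif(1) < 0.571) "male" else "female"
      base <- min(max(stats::rnorm(1, 1.7, 1.1), 0), 3.6)
      # piecewise-linear drift: one random breakpoint, two random slopes
      brk <- stats::runif(1, 0.3, 0.7)
      sl <- stats::rnorm(2, 0, 1.2)
      for (b in seq_len(bouts_per_participant)) {
        frac <- (b - 1) / max(bouts_per_participant - 1, 1)
        drift <- if (frac <= brk) sl[1] * frac else sl[1] * brk + sl[2] * (frac - brk)
        sev <- min(max(base + drift + stats::rnorm(1, 0, 0.25), 0), 4)
        par_b <- model$effect_map(sev, noise_2d = noise_2d, noise_3d = noise_3d, dim = dim)
        bid <- sprintf("%s_b%03d", pid, b)
        sim <- simulate_bout_impl(par_b, dim, bid, pid, as.Date("2020-01-01") + b)
        scores <- draw_score(model, c(sev, sev))
        bouts[[bid]] <- sim$bout
        truth[[bid]] <- list(
          severity = sev, params = par_b,
          strike_times = sim$truth$strike_times,
          strike_sides = sim$truth$strike_sides
        )
        meta[[bid]] <- data.frame(
          bout_id = bid, participant_id = pid,
          date = as.Date("2020-01-01") + b, age = age, sex = sex,
          updrs_gait = scores[1], sas_gait = scores[2],
          frame_rate = par_b$frame_rate, severity = sev,
          stringsAsFactors = FALSE
        )
      }
    }
    list(bouts = bouts, meta = do.call(rbind, c(meta, make.row.names = FALSE)), truth = truth)
  })
}
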