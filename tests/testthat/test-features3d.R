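test_that("symmetry angle matches its formula, is zero at symmetry, antisymmetric under swap", {
  expect_equal(symmetry_angle(0.7, 0.7), 0)
  expect_equal(symmetry_angle(1.3, 1.3), 0)
  direct <- (45 - atan(0.6 / 0.5) * 180 / pi) / 90 * 100
  expect_equal(symmetry_angle(0.6, 0.5), direct)
  for (i in 1:5) {
    l <- stats::runif(1, 0.1, 1)
    r <- stats::runif(1, 0.1, 1)
    expect_equal(symmetry_angle(l, r), -symmetry_angle(r, l), tolerance = 1e-12)
  }
  expect_true(is.na(symmetry_angle(0, 0)))
})

test_that("sacrum ML dynamics match analytic sine values and degenerate cases", {
  fr <- 30
  n <- 301 # 10 s
  t <- (seq_len(n) - 1) / fr
  A <- 0.03
  f <- 0.9
  jn <- kinect_joints()
  mk <- function(x, y, z) {
    xm <- matrix(rep(x, length(jn)), n, dimnames = list(NULL, jn))
    ym <- matrix(rep(y, length(jn)), n, dimnames = list(NULL, jn))
    zm <- matrix(rep(z, length(jn)), n, dimnames = list(NULL, jn))
    ym[, "head"] <- 1.6
    ym[, c("l_ankle", "r_ankle")] <- 0.1
    walking_bout(
      bout_id = "sine", participant_id = "p", frame_rate = fr,
      x = xm, y = ym, z = zm
    )
  }
  b <- mk(A * sin(2 * pi * f * t), rep(1, n), 1.2 * t)
  out <- sacrum_ml_dynamics(b)
  expect_equal(out$rom, 2 * A, tolerance = 0.02)
  expect_equal(out$sd, A / sqrt(2), tolerance = 0.02)
  expect_equal(out$rms_velocity, 2 * pi * f * A / sqrt(2), tolerance = 0.02)
  # straight-line walk, no sway: all zero
  b0 <- mk(rep(0, n), rep(1, n), 1.2 * t)
  out0 <- sacrum_ml_dynamics(b0)
  expect_equal(out0$rom, 0, tolerance = 1e-10)
  expect_equal(out0$sd, 0, tolerance = 1e-10)
  expect_equal(out0$rms_velocity, 0, tolerance = 1e-10)
})

test_that("3D spatiotemporal features recover generator speed, length, time and cadence", {
  for (seed in 1:4) {
    par <- gait_params(
      cadence = 100 + 4 * seed, step_length = 0.6, n_steps = 10,
      step_time_cv = 0.02, step_time_asymmetry = 0.04
    )
    sim <- simulate_bout(par, "3d", seed = seed)
    f <- extract_features_3d(sim$bout)
    expect_lt(abs(f$walking_speed - sim$truth$speed), 0.02)
    expect_lt(abs(f$step_length - par$step_length), 0.02)
    expect_lt(abs(f$step_width - par$step_width) / par$step_width, 0.1)
    # internal consistency: mean step time x cadence/60 ~ 1
    expect_equal(f$step_time * f$cadence / 60, 1, tolerance = 0.02)
  }
})

test_that("stationary skeleton leaves spatiotemporal features undefined, sway features ~0", {
  sim <- simulate_bout(gait_params(n_steps = 6), "3d", seed = 2)
  b <- sim$bout
  for (m in c("x", "y", "z")) {
    b[[m]] <- matrix(rep(b[[m]][1, ], each = nrow(b[[m]])),
      nrow = nrow(b[[m]]), dimnames = dimnames(b[[m]])
    )
  }
  f <- extract_features_3d(b)
  expect_true(is.na(f$walking_speed))
  expect_true(is.na(f$step_length))
  expect_lt(abs(f$sd_sacrum_ml), 1e-10)
  expect_lt(abs(f$rom_sacrum_ml), 1e-10)
})

test_that("3D margin of stability honours units and matches a brute-force oracle", {
  # static balanced stance: XCoM at the ankle -> 0; constant offset -> 1000|c|
  fr <- 30
  n <- 120
  jn <- kinect_joints()
  zeros <- matrix(0, n, length(jn), dimnames = list(NULL, jn))
  ym <- zeros
  ym[, ] <- 1
  ym[, "head"] <- 1.6
  ym[, c("l_ankle", "r_ankle")] <- 0.1
  zm <- zeros
  zm[] <- rep(1.2 * (seq_len(n) - 1) / fr, length(jn)) # forward drift sets AP axis
  xm <- zeros
  cc <- 0.07
  xm[, c("l_ankle", "l_knee", "l_hip")] <- cc
  xm[, c("r_ankle", "r_knee", "r_hip")] <- cc
  b <- walking_bout(
    bout_id = "s", participant_id = "p", frame_rate = fr,
    x = xm, y = ym, z = zm
  )
  st <- make_strikes(c(0.5, 1.5, 2.5))
  m <- margin_of_stability_3d(b, st, leg_length = 0.9)
  expect_equal(m$avg_mos, 1000 * cc, tolerance = 1e-9)

  # oracle agreement on synthetic walks
  cfg <- step_config(min_peak_velocity = 0.05, velocity_smoothing = 3)
  for (seed in 1:6) {
    sim <- simulate_bout(gait_params(n_steps = 8), "3d", seed = seed)
    bout <- sim$bout
    st <- detect_foot_strikes_3d(bout, cfg)
    leg <- 0.9
    got <- margin_of_stability_3d(bout, st, leg_length = leg, cfg = cfg)

    frm <- gaitscore:::walking_frame(bout)
    nfr <- n_frames(bout)
    sm <- function(x, w) as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
    dv <- function(x) {
      out <- rep(NA_real_, nfr)
      out[2:(nfr - 1)] <- (x[3:nfr] - x[1:(nfr - 2)]) * fr / 2
      out
    }
    sac <- frm$project(bout$x[, "spine_base"], bout$z[, "spine_base"])
    ml_s <- sm(sac$ml, cfg$smoothing_window)
    xcom <- ml_s + dv(ml_s) / sqrt(9.81 / leg)
    vl <- dv(sm(bout$y[, "l_ankle"], cfg$smoothing_window))
    vr <- dv(sm(bout$y[, "r_ankle"], cfg$smoothing_window))
    la <- frm$project(bout$x[, "l_ankle"], bout$z[, "l_ankle"])$ml
    ra <- frm$project(bout$x[, "r_ankle"], bout$z[, "r_ankle"])$ml
    mos <- rep(NA_real_, nfr)
    for (i in seq_len(nfr)) {
      if (is.na(vl[i]) || is.na(vr[i])) next
      aml <- if (abs(vl[i]) <= abs(vr[i])) la[i] else ra[i]
      sgn <- sign(aml - sac$ml[i])
      if (sgn == 0) sgn <- 1
      mos[i] <- sgn * (aml - xcom[i])
    }
    i0 <- max(1, round(st$strikes$time[1] * fr) + 1)
    i1 <- min(nfr, round(st$strikes$time[nrow(st$strikes)] * fr) + 1)
    expect_equal(got$avg_mos, 1000 * mean(abs(mos[i0:i1]), na.rm = TRUE),
      tolerance = 1e-8
    )
  }
})

test_that("all sixteen 3D features are defined on a clean walk and rigid-motion invariant", {
  sim <- simulate_bout(
    gait_params(n_steps = 10, step_time_asymmetry = 0.05, step_length_asymmetry = 0.08),
    "3d",
    seed = 13
  )
  f1 <- extract_features_3d(sim$bout)
  expect_true(all(!is.na(as.numeric(f1[, features_3d_names()]))))
  f2 <- extract_features_3d(transform_bout(sim$bout, shift = c(3, 0.2, -8), angle = 1.1))
  v1 <- as.numeric(f1[, features_3d_names()])
  v2 <- as.numeric(f2[, features_3d_names()])
  expect_lt(max(abs(v1 - v2) / pmax(abs(v1), 1e-9)), 1e-8)
})

test_that("asymmetric timing and length produce the expected symmetry-angle signs", {
  sim <- simulate_bout(
    gait_params(
      n_steps = 14, step_time_cv = 0.01,
      step_time_asymmetry = 0.08, step_length_asymmetry = 0.15
    ),
    "3d",
    seed = 3
  )
  f <- extract_features_3d(sim$bout)
  # left steps longer in time -> atan(L/R) > 45 deg -> negative SA
  expect_lt(f$sa_step_time, 0)
  # left steps shorter in distance -> positive SA
  expect_gt(f$sa_step_length, 0)
})
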