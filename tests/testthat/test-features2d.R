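test_that("hip normalization is the identity at unit hip distance and cancels uniform scaling", {
  b <- make_flat_bout_2d(n = 20, hip_sep = 1, l_ankle_u = -0.3, r_ankle_u = 0.4)
  nrm <- normalize_by_hip_distance(b)
  # distances between joints survive unchanged when hip distance is 1 px
  expect_equal(
    nrm$u[1, "l_ankle"] - nrm$u[1, "r_ankle"],
    b$u[1, "l_ankle"] - b$u[1, "r_ankle"]
  )
  big <- transform_bout(b, scale = 2, shift = c(100, 50))
  nrm2 <- normalize_by_hip_distance(big)
  expect_equal(nrm$u, nrm2$u, tolerance = 1e-12)
  expect_equal(nrm$v, nrm2$v, tolerance = 1e-12)
})

test_that("coincident hips mark the frame unusable", {
  b <- make_flat_bout_2d(n = 20)
  b$u[5, "l_hip"] <- b$u[5, "r_hip"] <- 0
  b$v[5, "l_hip"] <- b$v[5, "r_hip"] <- 0
  nrm <- normalize_by_hip_distance(b)
  expect_false(nrm$usable[5])
  expect_true(all(is.na(nrm$u[5, ])))
  expect_true(nrm$usable[4])
})

test_that("cadence follows steps per minute and is missing below 2 strikes", {
  st <- make_strikes(seq(0, 6, length.out = 11)) # 10 intervals spanning 6 s
  expect_equal(cadence(st), 100)
  expect_true(is.na(cadence(make_strikes(1.5))))
})

test_that("symmetry index matches its formula and basic properties", {
  expect_equal(symmetry_index(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(symmetry_index(0.5, 0.6), abs(0.5 - 0.6) / 0.55 * 100)
  expect_equal(symmetry_index(0.5, 0.6), 18.181818, tolerance = 1e-6)
  expect_equal(symmetry_index(c(0.4, 0.6), c(0.7)), symmetry_index(0.7, c(0.6, 0.4)))
  expect_gte(symmetry_index(stats::runif(5), stats::runif(5)), 0)
  expect_error(symmetry_index(numeric(0), 1), "at least one")
})

test_that("coefficient of variation matches sample SD over mean", {
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  expect_equal(coefficient_of_variation(rep(2, 5)), 0)
  expect_true(is.na(coefficient_of_variation(3)))
  x <- stats::rexp(20) + 0.1
  expect_equal(coefficient_of_variation(3 * x), coefficient_of_variation(x))
})

test_that("step widths equal the constant normalized ankle separation", {
  b <- make_flat_bout_2d(n = 90, l_ankle_u = 0.35, r_ankle_u = -0.35, hip_sep = 2)
  st <- make_strikes(c(0.5, 1.0, 1.5, 2.0))
  w <- step_width_series(b, st)
  expect_equal(length(w), 4)
  expect_equal(unname(w), rep(0.7 / 2, 4)) # 0.7 px separation / 2 px hips
  expect_equal(length(step_width_series(b, make_strikes(1))), 0)
})

test_that("margin of stability reproduces forced static cases", {
  # hip centre directly above the stance ankle, zero velocity -> 0
  b0 <- make_flat_bout_2d(n = 90, l_ankle_u = 0, r_ankle_u = 0)
  st <- make_strikes(c(0.5, 1.2, 1.9, 2.6))
  m0 <- margin_of_stability(b0, st, xcom_params(0.3))
  expect_equal(m0$avg_mos, 0, tolerance = 1e-12)

  # constant lateral offset c, zero velocity -> avg |c|, per-step min |c|
  cc <- 0.25
  bc <- make_flat_bout_2d(n = 90, l_ankle_u = -cc, r_ankle_u = -cc)
  mc <- margin_of_stability(bc, st, xcom_params(0.3))
  expect_equal(mc$avg_mos, cc, tolerance = 1e-12)
  expect_equal(mc$avg_min_mos, cc, tolerance = 1e-12)
})

test_that("margin of stability agrees with a brute-force per-frame oracle", {
  cfg <- step_config()
  p <- xcom_params(0.3)
  for (seed in 1:8) {
    sim <- simulate_bout(
      gait_params(n_steps = 8, keypoint_noise_sd = 0.02), "2d",
      seed = seed
    )
    bout <- sim$bout
    st <- detect_foot_strikes(bout, cfg)
    got <- margin_of_stability(bout, st, p, cfg)

    # oracle: plain per-frame loop from raw pixels
    bi <- interpolate_gaps(bout, cfg$max_gap)
    fr <- bout$frame_rate
    n <- n_frames(bi)
    hd <- sqrt((bi$u[, "l_hip"] - bi$u[, "r_hip"])^2 +
      (bi$v[, "l_hip"] - bi$v[, "r_hip"])^2)
    cu <- (bi$u[, "l_hip"] + bi$u[, "r_hip"]) / 2
    cv <- (bi$v[, "l_hip"] + bi$v[, "r_hip"]) / 2
    sm <- function(x, w) as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
    dv <- function(x) {
      out <- rep(NA_real_, n)
      out[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fr / 2
      out
    }
    hl <- sm(-(bi$v[, "l_ankle"] - cv) / hd, cfg$smoothing_window)
    hr <- sm(-(bi$v[, "r_ankle"] - cv) / hd, cfg$smoothing_window)
    vl <- dv(hl)
    vr <- dv(hr)
    hv <- dv(sm(cu, cfg$smoothing_window)) / hd
    d_frame <- rep(NA_real_, n)
    for (i in 1:n) {
      stance <- if (!is.na(vl[i]) && !is.na(vr[i]) && abs(vl[i]) <= abs(vr[i])) "l_ankle" else "r_ankle"
      o <- (cu[i] - bi$u[i, stance]) / hd[i]
      d_frame[i] <- o + p$velocity_scale * hv[i]
    }
    i0 <- max(1, round(st$strikes$time[1] * fr) + 1)
    i1 <- min(n, round(st$strikes$time[nrow(st$strikes)] * fr) + 1)
    expect_equal(got$avg_mos, mean(abs(d_frame[i0:i1]), na.rm = TRUE), tolerance = 1e-10)
    mins <- sapply(seq_len(nrow(st$strikes) - 1), function(k) {
      a <- max(1, round(st$strikes$time[k] * fr) + 1)
      b2 <- min(n, round(st$strikes$time[k + 1] * fr) + 1)
      min(abs(d_frame[a:b2]), na.rm = TRUE)
    })
    expect_equal(got$avg_min_mos, mean(mins), tolerance = 1e-10)
  }
})

test_that("all eight 2D features are invariant to uniform scale and translation", {
  for (seed in 1:5) {
    sim <- simulate_bout(
      gait_params(n_steps = 9, keypoint_noise_sd = 0.02), "2d",
      seed = seed
    )
    f1 <- extract_features_2d(sim$bout)
    f2 <- extract_features_2d(transform_bout(sim$bout, scale = 2.5, shift = c(-310, 77)))
    v1 <- as.numeric(f1[, features_2d_names()])
    v2 <- as.numeric(f2[, features_2d_names()])
    expect_lt(max(abs(v1 - v2) / pmax(abs(v1), 1e-12)), 1e-9)
  }
})

test_that("extracted step count equals the generated step count on clean walks", {
  sim <- simulate_bout(gait_params(n_steps = 8, step_time_cv = 0, step_time_asymmetry = 0),
    "2d",
    seed = 21
  )
  f <- extract_features_2d(sim$bout)
  expect_equal(f$steps_of_walk, 8)
  expect_true(all(!is.na(as.numeric(f[, features_2d_names()]))))
})

test_that("generator cadence, step-time CV and SI are recovered on clean long walks", {
  for (seed in 1:4) {
    sim <- simulate_bout(
      gait_params(
        cadence = 102 + 3 * seed, n_steps = 12,
        step_time_cv = 0.03, step_time_asymmetry = 0.06
      ),
      "2d",
      seed = seed
    )
    tt <- sim$truth$strike_times
    iv <- diff(tt)
    sides <- sim$truth$strike_sides[-1]
    cad_true <- (length(tt) - 1) / (tt[length(tt)] - tt[1]) * 60
    cv_true <- stats::sd(iv) / mean(iv)
    si_true <- symmetry_index(iv[sides == "left"], iv[sides == "right"])
    f <- extract_features_2d(sim$bout)
    expect_lt(abs(f$cadence - cad_true) / cad_true, 0.05)
    expect_lt(abs(f$cv_step_time - cv_true) / cv_true, 0.05)
    expect_lt(abs(f$si_step_time - si_true), 1)
  }
})
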