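#' Step-detection configuration
#'
#' Parameters of the foot-strike detector. Strikes are found per foot from
#' the vertical velocity of the ankle: swing cycles are delimited by
#' prominent peaks of the *downward* velocity (the descent of the foot in
#' late swing), and within each cycle the strike is the first time the
#' descent velocity falls back below `peak_fraction` of that cycle's peak —
#' i.e. the moment the descending foot decelerates into ground contact.
#'
#' @param peak_fraction Fraction of the per-cycle peak descent velocity whose
#'   downward crossing marks the strike (study value 0.35).
#' @param smoothing_window Moving-average window (frames) applied to the
#'   ankle height signal before differentiation; 1 disables smoothing.
#' @param velocity_smoothing Moving-average window (frames) applied to the
#'   differentiated signal. Differentiation amplifies keypoint noise, and
#'   pixel keypoints are much noisier than metric skeleton joints: the 2D
#'   default is 9 frames, while the 3D detector defaults to 3.
#' @param min_step_interval Physiological floor (s) between consecutive
#'   strikes of opposite feet; closer pairs are thinned by prominence.
#' @param min_cycle_interval Minimum spacing (s) between descent peaks of the
#'   same foot (same-foot cycles are stride-separated).
#' @param min_peak_velocity Absolute floor on the descent-peak height, in
#'   signal units per second (hip-widths/s for 2D, m/s for 3D); rejects the
#'   noise peaks of a stationary pose.
#' @param prominence_fraction A candidate peak is kept when its topographic
#'   prominence is at least this fraction of the median candidate-peak height.
#' @param max_gap Longest tracking gap (frames) filled by interpolation
#'   before detection (see [interpolate_gaps()]).
#' @return A list of class `step_config`.
#' @export
step_config <- function(peak_fraction = 0.35, smoothing_window = 5,
                        velocity_smoothing = 9,
                        min_step_interval = 0.2, min_cycle_interval = 0.4,
                        min_peak_velocity = 0.2, prominence_fraction = 0.5,
                        max_gap = 5) {
  stopifnot(
    peak_fraction > 0, peak_fraction < 1,
    smoothing_window >= 1, min_step_interval > 0
  )
  structure(
    list(
      peak_fraction = peak_fraction, smoothing_window = smoothing_window,
      velocity_smoothing = velocity_smoothing,
      min_step_interval = min_step_interval,
      min_cycle_interval = min_cycle_interval,
      min_peak_velocity = min_peak_velocity,
      prominence_fraction = prominence_fraction, max_gap = max_gap
    ),
    class = "step_config"
  )
}

# centred moving average preserving length; NA at ends shorter than the window
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
}

# central-difference derivative; endpoints are left NA (one-sided differences
# are only first-order accurate and would distort edge cycles)
central_diff <- function(x, fr) {
  n <- length(x)
  v <- rep(NA_real_, n)
  if (n >= 3) v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fr / 2
  v
}

# indices of strict local maxima of x (NA treated as -Inf)
local_maxima <- function(x) {
  x[is.na(x)] <- -Inf
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1] & is.finite(x[i])]
}

# topographic prominence of each peak: height above the higher of the two
# saddle minima separating it from higher ground (or the signal edge)
peak_prominence <- function(x, peaks) {
  x[is.na(x)] <- -Inf
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1)]
    higher_l <- which(left > h)
    lo_l <- if (length(higher_l) > 0) {
      min(left[(max(higher_l) + 1):(p - 1)])
    } else {
      min(left)
    }
    right <- x[(p + 1):length(x)]
    higher_r <- which(right > h)
    lo_r <- if (length(higher_r) > 0) {
      min(right[seq_len(min(higher_r) - 1)])
    } else {
      min(right)
    }
    h - max(lo_l, lo_r, -Inf)
  }, numeric(1))
}

no_strikes <- function() {
  data.frame(time = numeric(0), peak = numeric(0), prominence = numeric(0))
}

# strike detection on one foot's height signal (any units, seconds time base).
# The signal is spline-upsampled before filtering so the discrete moving
# averages approximate their continuous kernels: at 30 Hz the grid phase of
# each swing relative to the frames otherwise shifts the detected event by a
# visible fraction of a frame. Returns data.frame(time, peak, prominence).
detect_strikes_signal <- function(height, fr, cfg, upsample = 4L) {
  n <- length(height)
  ok <- !is.na(height)
  if (sum(ok) < 4) return(no_strikes())
  ti <- seq_len(n)
  td <- seq(1, n, by = 1 / upsample)
  hd <- stats::spline(ti[ok], height[ok], xout = td, method = "fmm")$y
  hd[!ok[round(td)]] <- NA_real_ # dense points inside tracking gaps stay missing
  frd <- fr * upsample
  h <- moving_average(hd, cfg$smoothing_window * upsample)
  # smooth the derivative as well: differentiation amplifies keypoint noise
  descent <- moving_average(-central_diff(h, frd), cfg$velocity_smoothing * upsample)
  cand <- local_maxima(descent)
  # absolute floor plus a relative one: genuine swing cycles have peaks of
  # comparable height, noise peaks sit far below the strongest cycles
  floor_h <- max(cfg$min_peak_velocity, 0.35 * max(descent, na.rm = TRUE))
  cand <- cand[descent[cand] >= floor_h]
  if (length(cand) == 0) return(no_strikes())
  prom <- peak_prominence(descent, cand)
  med_h <- stats::median(descent[cand])
  keep <- prom >= cfg$prominence_fraction * med_h
  cand <- cand[keep]
  prom <- prom[keep]
  # same-foot cycles are stride-separated: thin peaks closer than
  # min_cycle_interval, keeping the higher one
  if (length(cand) > 1) {
    ord <- order(descent[cand], decreasing = TRUE)
    kept <- integer(0)
    for (i in ord) {
      if (all(abs(cand[i] - cand[kept]) / frd >= cfg$min_cycle_interval)) {
        kept <- c(kept, i)
      }
    }
    cand <- sort(cand[kept])
    prom <- peak_prominence(descent, cand)
  }
  out <- lapply(seq_along(cand), function(ci) {
    p <- cand[ci]
    upper <- if (ci < length(cand)) cand[ci + 1] else length(descent)
    thr <- cfg$peak_fraction * descent[p]
    k <- p + 1
    while (k <= upper) {
      if (is.na(descent[k])) return(NULL) # gap before landing: no event
      # sustained crossing: the signal must stay at/below threshold for a
      # full original frame, so a single noise dip does not fire early
      nxt <- descent[seq(k, min(k + upsample, upper))]
      if (!anyNA(nxt) && all(nxt <= thr)) break
      k <- k + 1
    }
    if (k > upper || is.na(descent[k]) || descent[k] > thr) return(NULL)
    frac <- if (k == 1) 0 else (descent[k - 1] - thr) / (descent[k - 1] - descent[k])
    data.frame(
      time = (td[k] - 1 - (1 - frac) / upsample) / fr,
      peak = descent[p], prominence = prom[ci]
    )
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) no_strikes() else out
}

# merge left/right strike series, repair alternation and enforce the
# minimum inter-strike interval (drop the less prominent of a violating pair).
# Same-side neighbours are only treated as duplicates when they fall within
# one swing of each other; a same-side pair a full stride apart means the
# contralateral strike was missed, and dropping a good strike would compound
# the miss.
merge_strikes <- function(left, right, cfg) {
  left$side <- rep("left", nrow(left))
  right$side <- rep("right", nrow(right))
  s <- rbind(left, right)
  s <- s[order(s$time), , drop = FALSE]
  dup_window <- 2 * cfg$min_step_interval
  repeat {
    drop <- integer(0)
    if (nrow(s) >= 2) {
      for (i in seq_len(nrow(s) - 1)) {
        gap <- s$time[i + 1] - s$time[i]
        same_dup <- s$side[i] == s$side[i + 1] && gap < dup_window
        close <- gap < cfg$min_step_interval
        if (same_dup || close) {
          drop <- if (s$prominence[i] < s$prominence[i + 1]) i else i + 1
          break
        }
      }
    }
    if (length(drop) == 0) break
    s <- s[-drop, , drop = FALSE]
  }
  rownames(s) <- NULL
  s[, c("time", "side", "peak", "prominence")]
}

# assemble the foot_strikes object from a merged strike table
as_foot_strikes <- function(s) {
  structure(
    list(
      strikes = s,
      step_times = if (nrow(s) >= 2) diff(s$time) else numeric(0),
      step_sides = if (nrow(s) >= 2) s$side[-1] else character(0)
    ),
    class = "foot_strikes"
  )
}

#' @export
print.foot_strikes <- function(x, ...) {
  cat(sprintf(
    "<foot_strikes> %d strikes (%d left, %d right), %d step intervals\n",
    nrow(x$strikes), sum(x$strikes$side == "left"),
    sum(x$strikes$side == "right"), length(x$step_times)
  ))
  invisible(x)
}

#' Vertical ankle velocity (2D)
#'
#' The smoothed, hip-normalized vertical position of one ankle (relative to
#' the hip centre, up-positive) differentiated with respect to time by
#' central differences. Units: hip-widths per second. Endpoints and frames
#' inside unfilled tracking gaps are `NA`.
#'
#' @param bout A 2D [walking_bout()].
#' @param side `"left"` or `"right"`.
#' @param cfg A [step_config()].
#' @return Numeric vector, one value per frame.
#' @export
ankle_vertical_velocity <- function(bout, side = c("left", "right"),
                                    cfg = step_config()) {
  side <- match.arg(side)
  stopifnot(bout$dim == "2d")
  bout <- interpolate_gaps(bout, cfg$max_gap)
  nrm <- normalize_by_hip_distance(bout)
  h <- -nrm$v[, if (side == "left") "l_ankle" else "r_ankle"]
  if (sum(!is.na(h)) < 2) stop("ankle_vertical_velocity: fewer than 2 usable frames")
  central_diff(moving_average(h, cfg$smoothing_window), bout$frame_rate)
}

#' Detect foot strikes from 2D keypoints
#'
#' Applies the 35%-of-cycle-peak rule to each ankle's hip-normalized vertical
#' velocity (see [step_config()] for the rule), then merges the two sides
#' into a single time-ordered strike series with left/right alternation
#' repair. An empty series is returned when no prominent swing cycle exists
#' (e.g. a stationary pose); quality control excludes such bouts.
#'
#' @param bout A 2D [walking_bout()].
#' @param cfg A [step_config()].
#' @return An object of class `foot_strikes`: `$strikes` (data.frame of
#'   `time`, `side`, `peak`, `prominence`), `$step_times` (inter-strike
#'   intervals, s) and `$step_sides` (side striking at the end of each step).
#' @export
detect_foot_strikes <- function(bout, cfg = step_config()) {
  stopifnot(bout$dim == "2d")
  bout <- interpolate_gaps(bout, cfg$max_gap)
  nrm <- normalize_by_hip_distance(bout)
  fr <- bout$frame_rate
  one <- function(joint) {
    h <- -nrm$v[, joint]
    if (sum(!is.na(h)) < 3) {
      return(data.frame(time = numeric(0), peak = numeric(0), prominence = numeric(0)))
    }
    detect_strikes_signal(h, fr, cfg)
  }
  as_foot_strikes(merge_strikes(one("l_ankle"), one("r_ankle"), cfg))
}

#' Detect foot strikes from 3D joint trajectories
#'
#' The same per-cycle velocity-threshold rule as [detect_foot_strikes()],
#' applied to the metric vertical ankle trajectories (no hip normalization;
#' units m/s). The default absolute peak floor is scaled to metres.
#'
#' @param bout A 3D [walking_bout()].
#' @param cfg A [step_config()]; `min_peak_velocity` defaults to 0.05 m/s
#'   and `velocity_smoothing` to 3 frames (metric skeletons are far less
#'   noisy than differentiated pixel keypoints).
#' @return A `foot_strikes` object.
#' @export
detect_foot_strikes_3d <- function(bout,
                                   cfg = step_config(
                                     min_peak_velocity = 0.05,
                                     velocity_smoothing = 3
                                   )) {
  stopifnot(bout$dim == "3d")
  bout <- interpolate_gaps(bout, cfg$max_gap)
  fr <- bout$frame_rate
  one <- function(joint) {
    if (!joint %in% bout$joints) {
      return(data.frame(time = numeric(0), peak = numeric(0), prominence = numeric(0)))
    }
    h <- bout$y[, joint]
    if (sum(!is.na(h)) < 3) {
      return(data.frame(time = numeric(0), peak = numeric(0), prominence = numeric(0)))
    }
    detect_strikes_signal(h, fr, cfg)
  }
  as_foot_strikes(merge_strikes(one("l_ankle"), one("r_ankle"), cfg))
}
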