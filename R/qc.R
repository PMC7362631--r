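#' Bout quality control
#'
#' Mirrors the study's two exclusion rules: bouts in which the person could
#' not be tracked by the pose estimator, and bouts with fewer than
#' `min_steps` tracked steps (study value 3). A bout counts as tracked when
#' at least `tracked_floor` of its frames contain both ankles and both hips
#' (the joints every downstream feature needs); the step count is the number
#' of detected foot strikes.
#'
#' @param bout A [walking_bout()].
#' @param strikes A [foot_strikes] series for the bout (may be empty).
#' @param min_steps Minimum tracked steps for inclusion.
#' @param tracked_floor Minimum fraction of frames with ankles and hips.
#' @return A one-row `data.frame`: `bout_id, tracked, n_steps, included,
#'   reason` with `reason` one of `"ok"`, `"too_short"`, `"untracked"`.
#' @export
qc_bout <- function(bout, strikes, min_steps = 3, tracked_floor = 0.5) {
  key <- if (bout$dim == "2d") c("l_ankle", "r_ankle", "l_hip", "r_hip") else {
    c("l_ankle", "r_ankle", "spine_base")
  }
  key <- intersect(key, bout$joints)
  cm <- if (bout$dim == "2d") bout$u else bout$x
  ok <- rowSums(is.na(cm[, key, drop = FALSE])) == 0
  frac <- mean(ok)
  tracked <- length(key) >= (if (bout$dim == "2d") 4 else 3) && frac >= tracked_floor
  n_steps <- if (is.null(strikes)) 0L else nrow(strikes$strikes)
  included <- tracked && n_steps >= min_steps
  reason <- if (!tracked) "untracked" else if (n_steps < min_steps) "too_short" else "ok"
  data.frame(
    bout_id = bout$bout_id, tracked = tracked, tracked_fraction = frac,
    n_steps = n_steps, included = included, reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Keep one bout per participant-day
#'
#' When a participant recorded several bouts on one day, retains a single
#' uniformly random bout for that day (walks recorded in close succession are
#' expected to share the same clinical score, so keeping them all would bias
#' the cohort). Deterministic for a fixed seed.
#'
#' @param bouts List of [walking_bout()]s carrying `participant_id` and `date`.
#' @param seed Integer seed for the random choice.
#' @return Sub-list of `bouts`, one per distinct (participant, date) pair, in
#'   the original order.
#' @export
subsample_one_per_day <- function(bouts, seed = 1) {
  if (length(bouts) == 0) return(bouts)
  key <- vapply(
    bouts,
    function(b) paste(b$participant_id, as.character(b$date), sep = "@"),
    character(1)
  )
  keep <- withr::with_seed(seed, {
    vapply(split(seq_along(bouts), key), function(ix) {
      if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
    }, integer(1))
  })
  bouts[sort(unname(keep))]
}
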