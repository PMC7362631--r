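# shared fixtures and small oracles, all built in code at test time

# minimal hand-built 2D bout: hips fixed at unit distance, ankles configurable
make_flat_bout_2d <- function(n = 60, fr = 30,
                              l_ankle_u = -0.2, r_ankle_u = 0.2,
                              ankle_v = 2, hip_sep = 1,
                              l_ankle_v = NULL, r_ankle_v = NULL) {
  joints <- mpii_joints()
  u <- matrix(0, n, length(joints), dimnames = list(NULL, joints))
  v <- matrix(0, n, length(joints), dimnames = list(NULL, joints))
  u[, "l_hip"] <- hip_sep / 2
  u[, "r_hip"] <- -hip_sep / 2
  u[, "l_ankle"] <- l_ankle_u
  u[, "r_ankle"] <- r_ankle_u
  v[, "l_ankle"] <- if (is.null(l_ankle_v)) ankle_v else l_ankle_v
  v[, "r_ankle"] <- if (is.null(r_ankle_v)) ankle_v else r_ankle_v
  v[, "head"] <- -3
  walking_bout(
    bout_id = "flat", participant_id = "px", frame_rate = fr,
    u = u, v = v
  )
}

# hand-built strike series at given times/sides
make_strikes <- function(times, sides = rep(c("left", "right"), length.out = length(times))) {
  s <- data.frame(
    time = times, side = sides,
    peak = rep(1, length(times)), prominence = rep(1, length(times))
  )
  gaitscore:::as_foot_strikes(s)
}

# strike-timing F1 at a frame tolerance, greedy one-to-one matching
strike_f1 <- function(detected, truth, fr = 30, tol_frames = 2) {
  tol <- tol_frames / fr
  used <- rep(FALSE, length(detected))
  tp <- 0
  for (tt in truth) {
    d <- abs(detected - tt)
    d[used] <- Inf
    if (length(d) > 0 && min(d) <= tol) {
      tp <- tp + 1
      used[which.min(d)] <- TRUE
    }
  }
  prec <- if (length(detected) > 0) tp / length(detected) else 0
  rec <- if (length(truth) > 0) tp / length(truth) else 0
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# draw (x, y) from a proportional-odds model: logit P(y <= j) = theta_j - x.beta
draw_ordinal <- function(n, beta, theta, x = NULL) {
  p <- length(beta)
  if (is.null(x)) x <- matrix(stats::rnorm(n * p), n, p)
  colnames(x) <- paste0("x", seq_len(p))
  eta <- if (p > 0) drop(x %*% beta) else rep(0, n)
  cum <- vapply(theta, function(th) stats::plogis(th - eta), numeric(n))
  y <- rowSums(matrix(stats::runif(n), n, length(theta)) > cum)
  list(x = x, y = y)
}

# independent naive log-likelihood of the proportional-odds model (loop form,
# deliberately different from the package's vectorised implementation)
naive_po_loglik <- function(beta, theta, x, y) {
  lev <- sort(unique(y))
  total <- 0
  for (i in seq_along(y)) {
    k <- match(y[i], lev)
    eta <- sum(x[i, ] * beta)
    up <- if (k == length(lev)) 1 else stats::plogis(theta[k] - eta)
    lo <- if (k == 1) 0 else stats::plogis(theta[k - 1] - eta)
    total <- total + log(max(up - lo, 1e-300))
  }
  total
}

# brute-force MLE oracle: random multi-start + Nelder-Mead polish on the
# naive likelihood, independent of the package's BFGS route
brute_force_po_mle <- function(x, y, n_starts = 30) {
  p <- ncol(x)
  K <- length(unique(y))
  obj <- function(par) {
    theta <- par[p + seq_len(K - 1)]
    if (is.unsorted(theta, strictly = TRUE)) return(1e9)
    -naive_po_loglik(par[seq_len(p)], theta, x, y)
  }
  cum <- cumsum(tabulate(match(y, sort(unique(y))), K))[seq_len(K - 1)] / length(y)
  base <- c(rep(0, p), stats::qlogis(pmin(pmax(cum, 0.01), 0.99)))
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- base + stats::rnorm(length(base), 0, if (s == 1) 0 else 0.8)
    start[p + seq_len(K - 1)] <- sort(start[p + seq_len(K - 1)])
    o <- stats::optim(start, obj,
      method = "Nelder-Mead",
      control = list(maxit = 5000, reltol = 1e-12)
    )
    o <- stats::optim(o$par, obj,
      method = "Nelder-Mead",
      control = list(maxit = 5000, reltol = 1e-14)
    )
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(log_likelihood = -best$value, par = best$par)
}
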