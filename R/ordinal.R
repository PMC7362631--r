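#' Proportional-odds ordinal logistic regression
#'
#' Maximum-likelihood fit of the cumulative-logit proportional-odds model
#' under the convention `logit P(y <= j) = theta_j - x . beta`, so a positive
#' coefficient means higher severity with larger predictor values. Cutpoints
#' are estimated only between the outcome categories actually observed.
#' Standard errors come from the observed information (inverse Hessian at
#' the MLE); `t = coef/SE` and two-sided p-values use the normal
#' approximation. Monotonicity of the cutpoints is enforced through a
#' log-difference reparameterisation during optimisation.
#'
#' @param x Numeric predictor matrix (n x p; p may be 0 for an
#'   intercepts-only fit) or data.frame of numeric columns.
#' @param y Ordinal outcome: integer scores (e.g. 0-4) or an ordered factor.
#' @param start Optional start values `c(beta, theta)` on the natural scale.
#' @param reltol Convergence tolerance passed to [stats::optim()].
#' @return Object of class `ordinal_fit` with elements `coefficients`,
#'   `cutpoints` (named `"0|1"`, ... after the observed category labels),
#'   `std_errors`, `t_values`, `p_values` (each covering coefficients then
#'   cutpoints), `log_likelihood`, `n_obs`, `levels`, `vcov`, `converged`,
#'   and a `flags` character vector (e.g. `"possible_separation"`).
#' @export
fit_proportional_odds <- function(x, y, start = NULL, reltol = 1e-12) {
  if (is.null(x)) x <- matrix(numeric(0), nrow = length(y), ncol = 0)
  x <- as.matrix(x)
  if (is.null(colnames(x)) && ncol(x) > 0) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  storage.mode(x) <- "double"
  keep <- stats::complete.cases(x) & !is.na(y)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  lev <- if (is.factor(y)) levels(droplevels(factor(y))) else sort(unique(y))
  K <- length(lev)
  if (K < 2) stop("fit_proportional_odds: need >= 2 observed outcome categories")
  yi <- match(as.character(y), as.character(lev))
  n <- length(yi)
  p <- ncol(x)
  if (n <= p + K - 1) stop("fit_proportional_odds: too few observations for parameters")

  nll_natural <- function(par) {
    beta <- par[seq_len(p)]
    theta <- par[p + seq_len(K - 1)]
    if (is.unsorted(theta, strictly = TRUE)) return(1e10)
    eta <- if (p > 0) drop(x %*% beta) else rep(0, n)
    up <- c(theta, Inf)[yi] - eta
    lo <- c(-Inf, theta)[yi] - eta
    pr <- stats::plogis(up) - stats::plogis(lo)
    -sum(log(pmax(pr, 1e-300)))
  }
  # optimisation scale: theta_1, log-differences for the rest
  to_nat <- function(w) {
    beta <- w[seq_len(p)]
    zeta <- w[p + seq_len(K - 1)]
    c(beta, cumsum(c(zeta[1], exp(zeta[-1]))))
  }
  to_work <- function(par) {
    theta <- par[p + seq_len(K - 1)]
    c(par[seq_len(p)], theta[1], log(pmax(diff(theta), 1e-8)))
  }
  nll_work <- function(w) nll_natural(to_nat(w))

  if (is.null(start)) {
    cum <- cumsum(tabulate(yi, K))[seq_len(K - 1)] / n
    start <- c(rep(0, p), stats::qlogis(pmin(pmax(cum, 1e-3), 1 - 1e-3)))
  }
  opt <- stats::optim(
    to_work(start), nll_work,
    method = "BFGS",
    control = list(maxit = 1000, reltol = reltol)
  )
  par <- to_nat(opt$par)
  flags <- character(0)
  H <- try(stats::optimHess(par, nll_natural), silent = TRUE)
  vc <- NULL
  se <- rep(NA_real_, length(par))
  if (!inherits(H, "try-error")) {
    vc <- try(solve(H), silent = TRUE)
    if (!inherits(vc, "try-error") && all(diag(vc) > 0)) {
      se <- sqrt(diag(vc))
    } else {
      vc <- NULL
      flags <- c(flags, "singular_information")
    }
  } else {
    flags <- c(flags, "hessian_failed")
  }
  converged <- opt$convergence == 0 && !"singular_information" %in% flags
  # separation heuristic on the standardized scale: a slope of > 20 latent
  # units per predictor SD means near-perfect category separation
  sdx <- if (p > 0) apply(x, 2, stats::sd) else numeric(0)
  if (p > 0 && any(abs(par[seq_len(p)]) * sdx > 20 | se[seq_len(p)] * sdx > 1e3,
    na.rm = TRUE
  )) {
    flags <- c(flags, "possible_separation")
    warning("fit_proportional_odds: possible complete separation; coefficients unreliable")
  }
  nm <- c(
    colnames(x),
    paste(lev[-K], lev[-1], sep = "|")
  )
  tv <- par / se
  structure(
    list(
      coefficients = stats::setNames(par[seq_len(p)], colnames(x)),
      cutpoints = stats::setNames(par[p + seq_len(K - 1)], nm[p + seq_len(K - 1)]),
      std_errors = stats::setNames(se, nm),
      t_values = stats::setNames(tv, nm),
      p_values = stats::setNames(2 * stats::pnorm(-abs(tv)), nm),
      log_likelihood = -opt$value,
      n_obs = n, levels = lev, vcov = vc,
      converged = converged, flags = flags
    ),
    class = "ordinal_fit"
  )
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf(
    "<ordinal_fit> n = %d, logLik = %.3f, %d categories%s\n",
    x$n_obs, x$log_likelihood, length(x$levels),
    if (x$converged) "" else " [NOT CONVERGED]"
  ))
  print(as.data.frame(x), digits = 3)
  invisible(x)
}

#' Tabulate an ordinal fit
#'
#' Lays the fit out as the usual ordinal-regression report: one row per
#' predictor coefficient followed by the labelled cutpoint intercepts, with
#' columns `term, coefficient, std_error, t_value, p_value`.
#'
#' @param x An `ordinal_fit`.
#' @param ... Unused.
#' @export
as.data.frame.ordinal_fit <- function(x, ...) {
  est <- c(x$coefficients, x$cutpoints)
  data.frame(
    term = names(x$std_errors),
    type = rep(c("coefficient", "intercept"),
      c(length(x$coefficients), length(x$cutpoints))
    ),
    coefficient = unname(est),
    std_error = unname(x$std_errors),
    t_value = unname(x$t_values),
    p_value = unname(x$p_values),
    stringsAsFactors = FALSE
  )
}

#' Predict ordinal category probabilities and scores
#'
#' Category probabilities are adjacent differences of the logistic CDF at
#' the cutpoints; the predicted score is the highest-probability observed
#' category. Prediction is restricted to the categories observed when
#' fitting.
#'
#' @param fit An `ordinal_fit`.
#' @param newdata Matrix or data.frame holding the fit's predictor columns.
#' @return List with `probabilities` (n x K matrix, rows summing to 1) and
#'   `predicted` (numeric scores when the levels are numeric, otherwise
#'   labels).
#' @export
predict_category <- function(fit, newdata) {
  p <- length(fit$coefficients)
  if (p > 0) {
    newdata <- as.matrix(as.data.frame(newdata)[, names(fit$coefficients), drop = FALSE])
    if (anyNA(newdata)) stop("predict_category: missing predictor value")
    eta <- drop(newdata %*% fit$coefficients)
  } else {
    eta <- rep(0, if (is.matrix(newdata)) nrow(newdata) else 1)
  }
  K <- length(fit$levels)
  cum <- vapply(fit$cutpoints, function(th) stats::plogis(th - eta), numeric(length(eta)))
  cum <- matrix(cum, nrow = length(eta))
  pr <- cbind(cum, 1) - cbind(0, cum)
  colnames(pr) <- as.character(fit$levels)
  pred_idx <- max.col(pr, ties.method = "first")
  pred <- fit$levels[pred_idx]
  if (is.character(pred) && !anyNA(suppressWarnings(as.numeric(pred)))) {
    pred <- as.numeric(pred)
  }
  list(probabilities = pr, predicted = pred)
}
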