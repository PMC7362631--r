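# small synthetic cohort table with controllable feature-outcome structure
make_cohort <- function(n = 300, seed = 1) {
  withr::with_seed(seed, {
    sev <- stats::runif(n, 0, 4)
    cum <- vapply(
      2.2 * c(0.5, 1.5, 2.5, 3.5),
      function(th) stats::plogis(th - 2.2 * sev), numeric(n)
    )
    y <- rowSums(matrix(stats::runif(n), n, 4) > cum)
    tbl <- data.frame(
      bout_id = sprintf("b%03d", seq_len(n)),
      participant_id = sample(sprintf("p%02d", 1:10), n, replace = TRUE),
      age = round(stats::rnorm(n, 76, 8)),
      sex = sample(c("male", "female"), n, replace = TRUE),
      updrs_gait = y, sas_gait = y,
      cadence = 108 - 10 * sev + stats::rnorm(n, 0, 4),
      noise_a = stats::rnorm(n),
      noise_b = stats::rnorm(n)
    )
  })
  attr(tbl, "feature_names") <- c("cadence", "noise_a", "noise_b")
  tbl
}

test_that("cohort construction drops rows with missing outcomes or features, with reasons", {
  feats <- data.frame(
    bout_id = c("a", "b", "c"), participant_id = "p1",
    cadence = c(100, NA, 95)
  )
  meta <- data.frame(
    bout_id = c("a", "b", "c"), participant_id = "p1",
    age = 80, sex = "male",
    updrs_gait = c(1, 2, NA), sas_gait = c(1, 2, NA)
  )
  tbl <- build_cohort_table(feats, meta, feature_names = "cadence")
  expect_equal(tbl$bout_id, "a")
  dropped <- attr(tbl, "dropped")
  expect_setequal(dropped$reason, c("missing_outcome", "missing_feature"))
})

test_that("univariate screen selects informative features, not noise; alpha = 0 selects nothing", {
  tbl <- make_cohort(400, seed = 3)
  rep <- univariate_screen(tbl, "updrs_gait", alpha = 0.05)
  expect_true("cadence" %in% rep$selected_by_p)
  expect_lt(rep$univariate$p_value[rep$univariate$feature == "cadence"], 0.001)
  rep0 <- univariate_screen(tbl, "updrs_gait", alpha = 1e-300)
  expect_equal(length(rep0$selected_by_p), 0)
})

test_that("the screen's null selection rate is near alpha", {
  hits <- 0
  reps <- 60
  withr::with_seed(99, {
    for (i in seq_len(reps)) {
      n <- 300
      y <- sample(0:4, n, replace = TRUE)
      tbl <- data.frame(x = stats::rnorm(n), updrs_gait = y, sas_gait = y)
      attr(tbl, "feature_names") <- "x"
      out <- univariate_screen(tbl, "updrs_gait", features = "x", alpha = 0.05)
      hits <- hits + length(out$selected_by_p)
    }
  })
  # 95% binomial band around 0.05 for 60 replicates: 0 to ~8 hits
  expect_lte(hits, stats::qbinom(0.995, reps, 0.05))
})

test_that("correlation pruning follows the larger-outcome-correlation rule with cascade", {
  withr::with_seed(11, {
    n <- 500
    base <- stats::rnorm(n)
    a <- base + stats::rnorm(n, 0, 0.3) # r(a,b) high
    b <- base + stats::rnorm(n, 0, 0.45)
    c_ <- 0.6 * b + stats::rnorm(n, 0, 0.75) # r(b,c) moderate, r(a,c) low-ish
    y <- pmin(pmax(round(1.5 * base + 1.5 + stats::rnorm(n, 0, 0.8)), 0), 4)
    tbl <- data.frame(A = a, B = b, C = c_, updrs_gait = y)
  })
  out <- prune_correlated(tbl, c("A", "B", "C"), "updrs_gait", r_threshold = 0.5)
  # brute-force re-application of the documented rule
  cm <- stats::cor(tbl[, c("A", "B", "C")])
  r_out <- sapply(c("A", "B", "C"), function(f) stats::cor(tbl[[f]], as.numeric(y <- tbl$updrs_gait)))
  pairs <- which(upper.tri(cm) & abs(cm) > 0.5, arr.ind = TRUE)
  pairs <- pairs[order(abs(cm[pairs]), decreasing = TRUE), , drop = FALSE]
  dropped <- character(0)
  nm <- c("A", "B", "C")
  for (k in seq_len(nrow(pairs))) {
    f1 <- nm[pairs[k, 1]]
    f2 <- nm[pairs[k, 2]]
    if (f1 %in% dropped || f2 %in% dropped) next
    dropped <- c(dropped, if (abs(r_out[f1]) >= abs(r_out[f2])) f2 else f1)
  }
  expect_setequal(out$final_features, setdiff(nm, dropped))
  # invariant: no retained pair above the threshold
  if (length(out$final_features) >= 2) {
    expect_true(all(abs(cm[out$final_features, out$final_features][
      upper.tri(diag(length(out$final_features)))
    ]) <= 0.5))
  }
})

test_that("near-orthogonal candidates pass untouched; duplicated columns keep one copy", {
  withr::with_seed(21, {
    tbl <- data.frame(
      A = stats::rnorm(300), B = stats::rnorm(300), C = stats::rnorm(300),
      updrs_gait = sample(0:4, 300, replace = TRUE)
    )
  })
  out <- prune_correlated(tbl, c("A", "B", "C"), "updrs_gait")
  expect_equal(out$final_features, c("A", "B", "C"))

  tbl$A2 <- tbl$A
  out2 <- prune_correlated(tbl, c("A", "A2", "B"), "updrs_gait")
  expect_true(xor("A" %in% out2$final_features, "A2" %in% out2$final_features))
  # exact tie in |r| to outcome: earlier column retained
  expect_true("A" %in% out2$final_features)

  tbl$const <- 1
  out3 <- prune_correlated(tbl, c("A", "const"), "updrs_gait")
  expect_equal(out3$dropped_degenerate, "const")
  expect_false("const" %in% out3$final_features)
})

test_that("multivariate fit flags the informative feature and is deterministic", {
  tbl <- make_cohort(400, seed = 6)
  fit <- fit_multivariate(tbl, c("cadence", "noise_a"), "updrs_gait")
  expect_lt(fit$p_values[["cadence"]], 0.05)
  expect_gt(fit$p_values[["noise_a"]], 0.05)
  expect_equal(names(fit$cutpoints), c("0|1", "1|2", "2|3", "3|4"))
  fit2 <- fit_multivariate(tbl, c("cadence", "noise_a"), "updrs_gait")
  expect_identical(fit$coefficients, fit2$coefficients)
})

test_that("permuted outcomes leave gait coefficients non-significant most of the time", {
  tbl <- make_cohort(250, seed = 8)
  sig <- 0
  reps <- 20
  withr::with_seed(123, {
    for (i in seq_len(reps)) {
      tbl$updrs_gait <- sample(tbl$updrs_gait)
      fit <- suppressWarnings(fit_multivariate(tbl, "cadence", "updrs_gait"))
      if (!is.na(fit$p_values[["cadence"]]) && fit$p_values[["cadence"]] < 0.05) sig <- sig + 1
    }
  })
  expect_lte(sig / reps, 0.25)
})

test_that("evaluation identities hold: perfect predictor, majority vote, weighted accuracy", {
  tbl <- make_cohort(300, seed = 9)
  fit <- fit_multivariate(tbl, "cadence", "updrs_gait")
  ev <- evaluate_model(tbl, fit, "updrs_gait")
  expect_equal(sum(ev$confusion), nrow(tbl))
  expect_equal(dim(ev$confusion), c(5, 5))
  expect_equal(
    ev$accuracy,
    sum(diag(ev$confusion)) / sum(ev$confusion)
  )
  # per-participant accuracies weighted by bout counts average to overall
  pp <- ev$per_participant
  expect_equal(sum(pp$accuracy * pp$n_bouts) / sum(pp$n_bouts), ev$accuracy)
  expect_equal(sum(pp$pct_walks), 100)
  # degenerate "perfect" check: predicting the annotation itself
  ideal <- ev
  ideal$confusion[] <- 0
  for (k in 0:4) ideal$confusion[k + 1, k + 1] <- sum(tbl$updrs_gait == k)
  expect_equal(sum(diag(ideal$confusion)) / sum(ideal$confusion), 1)
})
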