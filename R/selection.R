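#' Build a bout-level cohort table
#'
#' Joins per-bout feature rows to bout metadata (age, sex, ordinal scores)
#' on `bout_id`, producing the table the statistical procedure operates on.
#' Rows with a missing outcome or any missing feature are dropped, with the
#' reason recorded in the `dropped` attribute.
#'
#' @param features Feature `data.frame` (one row per bout; from
#'   [extract_features_2d()] or [extract_features_3d()]).
#' @param meta Metadata `data.frame` (see [read_bout_metadata()]).
#' @param feature_names Feature columns to require; defaults to every
#'   feature column present.
#' @return `data.frame` with ids, `age`, `sex`, outcomes and features;
#'   attribute `dropped` is a data.frame of `bout_id, reason`.
#' @export
build_cohort_table <- function(features, meta, feature_names = NULL) {
  if (is.null(feature_names)) {
    feature_names <- setdiff(names(features), c("bout_id", "participant_id"))
  }
  tbl <- merge(features, meta[, setdiff(names(meta), "participant_id"), drop = FALSE],
    by = "bout_id"
  )
  dropped <- data.frame(bout_id = character(0), reason = character(0))
  no_outcome <- is.na(tbl$updrs_gait) & is.na(tbl$sas_gait)
  if (any(no_outcome)) {
    dropped <- rbind(dropped, data.frame(
      bout_id = tbl$bout_id[no_outcome], reason = "missing_outcome"
    ))
    tbl <- tbl[!no_outcome, , drop = FALSE]
  }
  incomplete <- rowSums(is.na(tbl[, feature_names, drop = FALSE])) > 0
  if (any(incomplete)) {
    dropped <- rbind(dropped, data.frame(
      bout_id = tbl$bout_id[incomplete], reason = "missing_feature"
    ))
    tbl <- tbl[!incomplete, , drop = FALSE]
  }
  rownames(tbl) <- NULL
  attr(tbl, "feature_names") <- feature_names
  attr(tbl, "dropped") <- dropped
  tbl
}

#' Univariate ordinal screen
#'
#' One single-predictor proportional-odds fit per gait feature against the
#' ordinal outcome, at significance threshold `alpha` with *no* multiplicity
#' adjustment: the screen's purpose is candidate selection for the
#' multivariate model, and correcting here would prematurely discard truly
#' associated features.
#'
#' @param table Cohort table from [build_cohort_table()].
#' @param outcome `"updrs_gait"` or `"sas_gait"`.
#' @param features Feature columns to screen; default from the table.
#' @param alpha Significance threshold (study value 0.05).
#' @param min_obs Minimum complete observations per feature.
#' @return List of class `selection_report` with `univariate` (data.frame:
#'   `feature, coefficient, std_error, t_value, p_value, n, note`),
#'   `selected_by_p`, `alpha`, `outcome`.
#' @export
univariate_screen <- function(table, outcome = c("updrs_gait", "sas_gait"),
                              features = NULL, alpha = 0.05, min_obs = 20) {
  outcome <- match.arg(outcome)
  if (is.null(features)) features <- attr(table, "feature_names")
  y <- table[[outcome]]
  rows <- lapply(features, function(f) {
    xi <- table[[f]]
    ok <- !is.na(xi) & !is.na(y)
    out <- data.frame(
      feature = f, coefficient = NA_real_, std_error = NA_real_,
      t_value = NA_real_, p_value = NA_real_, n = sum(ok), note = "",
      stringsAsFactors = FALSE
    )
    if (sum(ok) < min_obs) {
      out$note <- "too_few_obs"
      return(out)
    }
    fit <- try(
      fit_proportional_odds(matrix(xi[ok], dimnames = list(NULL, f)), y[ok]),
      silent = TRUE
    )
    if (inherits(fit, "try-error")) {
      out$note <- "fit_failed"
      return(out)
    }
    out$coefficient <- fit$coefficients[[f]]
    out$std_error <- fit$std_errors[[f]]
    out$t_value <- fit$t_values[[f]]
    out$p_value <- fit$p_values[[f]]
    if (length(fit$flags) > 0) out$note <- paste(fit$flags, collapse = ";")
    out
  })
  uni <- do.call(rbind, rows)
  selected <- uni$feature[!is.na(uni$p_value) & uni$p_value < alpha]
  structure(
    list(
      univariate = uni, selected_by_p = selected,
      alpha = alpha, outcome = outcome
    ),
    class = "selection_report"
  )
}

#' Collinearity pruning of screened features
#'
#' Pairwise Pearson correlations are computed among the candidate features;
#' for every pair with `|r| > r_threshold` the feature with the
#' smaller-magnitude Pearson correlation to the (numeric) outcome is
#' dropped. Pairs are processed in descending `|r|` order and drops cascade:
#' a feature already dropped triggers no further drops. The retained set
#' therefore never contains a pair above the threshold. Zero-variance
#' candidates (undefined r) are dropped up front.
#'
#' @param table Cohort table.
#' @param candidates Feature names surviving the univariate screen.
#' @param outcome Outcome column name.
#' @param r_threshold Correlation-magnitude threshold (study value 0.5).
#' @return List: `final_features`, `dropped_by_correlation` (data.frame
#'   `kept, dropped, r`), `dropped_degenerate`, `outcome_correlations`.
#' @export
prune_correlated <- function(table, candidates, outcome, r_threshold = 0.5) {
  y <- as.numeric(table[[outcome]])
  degenerate <- candidates[vapply(
    candidates,
    function(f) stats::sd(table[[f]], na.rm = TRUE) == 0 || all(is.na(table[[f]])),
    logical(1)
  )]
  cand <- setdiff(candidates, degenerate)
  r_out <- vapply(
    cand,
    function(f) stats::cor(table[[f]], y, use = "complete.obs"),
    numeric(1)
  )
  pairs <- data.frame(kept = character(0), dropped = character(0), r = numeric(0))
  if (length(cand) >= 2) {
    cm <- stats::cor(table[, cand, drop = FALSE], use = "pairwise.complete.obs")
    ij <- which(upper.tri(cm) & abs(cm) > r_threshold, arr.ind = TRUE)
    if (nrow(ij) > 0) {
      ord <- order(abs(cm[ij]), decreasing = TRUE)
      ij <- ij[ord, , drop = FALSE]
      dropped <- character(0)
      for (k in seq_len(nrow(ij))) {
        a <- cand[ij[k, 1]]
        b <- cand[ij[k, 2]]
        if (a %in% dropped || b %in% dropped) next
        # keep the larger-magnitude outcome correlation; ties keep the
        # earlier column
        if (abs(r_out[[a]]) >= abs(r_out[[b]])) {
          keep <- a; drp <- b
        } else {
          keep <- b; drp <- a
        }
        dropped <- c(dropped, drp)
        pairs <- rbind(pairs, data.frame(kept = keep, dropped = drp, r = cm[ij[k, 1], ij[k, 2]]))
      }
      cand <- setdiff(cand, dropped)
    }
  }
  list(
    final_features = cand,
    dropped_by_correlation = pairs,
    dropped_degenerate = degenerate,
    outcome_correlations = r_out
  )
}

#' Multivariate proportional-odds model with demographics
#'
#' Fits the final model on age, sex (coded male = 1), and the pruned gait
#' features, in the ordinal-report layout of [as.data.frame.ordinal_fit()].
#'
#' @param table Cohort table (must carry `age` and `sex`).
#' @param final_features Feature names from [prune_correlated()].
#' @param outcome Outcome column name.
#' @return An `ordinal_fit`; the design columns are
#'   `age, sex_male, <features>`.
#' @export
fit_multivariate <- function(table, final_features, outcome) {
  x <- cbind(
    age = table$age,
    sex_male = as.numeric(table$sex == "male"),
    as.matrix(table[, final_features, drop = FALSE])
  )
  fit_proportional_odds(x, table[[outcome]])
}

#' Evaluate an ordinal model on a cohort
#'
#' In-sample evaluation matching the study design: a 5x5 confusion matrix
#' (annotated x predicted over the full 0-4 scale), overall accuracy,
#' adjacent-agreement rate (|predicted - annotated| <= 1), and accuracy per
#' participant over that participant's bouts.
#'
#' @param table Cohort table whose rows carry the outcome and predictors.
#' @param fit An `ordinal_fit` (e.g. from [fit_multivariate()]).
#' @param outcome Outcome column name.
#' @return List `confusion` (matrix), `accuracy`, `adjacent_agreement`,
#'   `per_participant` (data.frame `participant_id, n_bouts, accuracy,
#'   pct_walks`), `predicted`.
#' @export
evaluate_model <- function(table, fit, outcome) {
  need <- names(fit$coefficients)
  design <- table
  if ("sex_male" %in% need && !"sex_male" %in% names(design)) {
    design$sex_male <- as.numeric(design$sex == "male")
  }
  pred <- predict_category(fit, design[, need, drop = FALSE])$predicted
  truth <- as.numeric(table[[outcome]])
  lev <- 0:4
  confusion <- table(
    factor(truth, levels = lev),
    factor(pred, levels = lev),
    dnn = c("annotated", "predicted")
  )
  acc <- mean(pred == truth)
  adj <- mean(abs(pred - truth) <= 1)
  pp <- do.call(rbind, lapply(split(seq_along(pred), table$participant_id), function(ix) {
    data.frame(
      participant_id = table$participant_id[ix[1]],
      n_bouts = length(ix),
      accuracy = mean(pred[ix] == truth[ix]),
      pct_walks = length(ix) / length(pred) * 100,
      stringsAsFactors = FALSE
    )
  }))
  rownames(pp) <- NULL
  list(
    confusion = unclass(confusion), accuracy = acc, adjacent_agreement = adj,
    per_participant = pp, predicted = pred
  )
}

#' Plot a confusion matrix
#'
#' Tile plot of an annotated-by-predicted score confusion matrix, counts
#' printed per cell.
#'
#' @param confusion 5x5 matrix as returned by [evaluate_model()].
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_confusion <- function(confusion, title = "Confusion matrix") {
  d <- as.data.frame(as.table(confusion))
  names(d) <- c("annotated", "predicted", "count")
  ggplot2::ggplot(d, ggplot2::aes(x = predicted, y = annotated, fill = count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = count)) +
    ggplot2::scale_y_discrete(limits = rev(levels(d$annotated))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = title, x = "Predicted score", y = "Annotated score") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("predicted", "annotated", "count"))
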