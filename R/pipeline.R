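#' Pipeline run configuration
#'
#' Assembles (and validates) the configuration of a full analysis run:
#' read/simulate -> gap-fill -> strike detection -> QC -> one-bout-per-day
#' subsampling -> feature extraction -> univariate screen -> collinearity
#' pruning -> multivariate proportional-odds fit -> evaluation. Accepts a
#' YAML file path or named arguments; arguments override file values.
#'
#' @param path Optional YAML file with any of the fields below.
#' @param dim `"2d"` or `"3d"`.
#' @param outcome `"updrs_gait"`, `"sas_gait"`, or `"both"`.
#' @param alpha Univariate significance threshold.
#' @param r_threshold Pearson correlation-magnitude pruning threshold.
#' @param seed Integer seed routed to every stochastic stage.
#' @param simulate If `TRUE`, input comes from [simulate_cohort()];
#'   otherwise from `input_dir` (keypoint files + `metadata.csv`).
#' @param input_dir,output_dir Directories (output optional).
#' @param n_participants,bouts_per_participant Cohort size when simulating.
#' @param min_steps QC step floor.
#' @param subsample_daily Apply the one-bout-per-day rule.
#' @param step Arguments forwarded to [step_config()] (list).
#' @param xcom Arguments forwarded to [xcom_params()] (list).
#' @return List of class `run_config`.
#' @export
run_config <- function(path = NULL, dim = "2d", outcome = "both",
                       alpha = 0.05, r_threshold = 0.5, seed = 1,
                       simulate = TRUE, input_dir = NULL, output_dir = NULL,
                       n_participants = 14, bouts_per_participant = 28,
                       min_steps = 3, subsample_daily = TRUE,
                       step = list(), xcom = list()) {
  cfg <- as.list(environment())
  cfg$path <- NULL
  if (!is.null(path)) {
    fromfile <- yaml::read_yaml(path)
    supplied <- names(as.list(match.call()))[-1]
    for (nm in setdiff(names(fromfile), supplied)) cfg[[nm]] <- fromfile[[nm]]
  }
  stopifnot(
    cfg$dim %in% c("2d", "3d"),
    cfg$outcome %in% c("updrs_gait", "sas_gait", "both"),
    cfg$alpha > 0, cfg$alpha < 1, cfg$r_threshold > 0, cfg$r_threshold < 1
  )
  if (cfg$dim == "3d" && is.null(cfg$step$min_peak_velocity)) {
    cfg$step$min_peak_velocity <- 0.05
  }
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg[order(names(cfg))], f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full gait-to-severity pipeline
#'
#' Executes every stage defined by a [run_config()] and (optionally) writes
#' the run artifacts: the per-bout feature CSV, QC log with exclusion
#' accounting (total = included + untracked + too-short), univariate
#' screening table, pruning report, multivariate coefficient table with
#' labelled cutpoint intercepts, confusion matrix, and per-participant
#' accuracies. Every artifact is stamped with the config hash and seed.
#'
#' @param cfg A [run_config()].
#' @return List of class `run_report`: `config`, `config_hash`, `qc`,
#'   `qc_counts`, `features`, and per-outcome `models` (each with
#'   `screen`, `pruning`, `fit`, `evaluation`).
#' @export
run_pipeline <- function(cfg = run_config()) {
  step_cfg <- do.call(step_config, cfg$step)
  xcom <- do.call(xcom_params, cfg$xcom)

  if (isTRUE(cfg$simulate)) {
    sim <- simulate_cohort(
      n_participants = cfg$n_participants,
      bouts_per_participant = cfg$bouts_per_participant,
      dim = cfg$dim, seed = cfg$seed
    )
    bouts <- sim$bouts
    meta <- sim$meta
  } else {
    meta <- read_bout_metadata(file.path(cfg$input_dir, "metadata.csv"))
    bouts <- lapply(seq_len(nrow(meta)), function(i) {
      row <- meta[i, ]
      base <- file.path(cfg$input_dir, row$bout_id)
      fr <- if ("frame_rate" %in% names(row)) row$frame_rate else 30
      if (cfg$dim == "2d") {
        pth <- if (file.exists(paste0(base, ".json"))) paste0(base, ".json") else paste0(base, ".csv")
        read_keypoints_2d(pth,
          frame_rate = fr, bout_id = row$bout_id,
          participant_id = row$participant_id, date = row$date
        )
      } else {
        read_keypoints_3d(paste0(base, ".csv"),
          frame_rate = fr, bout_id = row$bout_id,
          participant_id = row$participant_id, date = row$date
        )
      }
    })
    names(bouts) <- meta$bout_id
  }

  if (isTRUE(cfg$subsample_daily)) {
    bouts <- subsample_one_per_day(bouts, seed = cfg$seed)
  }

  detect <- function(b) {
    if (cfg$dim == "2d") detect_foot_strikes(b, step_cfg) else detect_foot_strikes_3d(b, step_cfg)
  }
  strikes <- lapply(bouts, detect)
  qc <- do.call(rbind, Map(
    function(b, s) qc_bout(b, s, min_steps = cfg$min_steps),
    bouts, strikes
  ))
  rownames(qc) <- NULL
  qc_counts <- c(
    total = nrow(qc),
    included = sum(qc$reason == "ok"),
    too_short = sum(qc$reason == "too_short"),
    untracked = sum(qc$reason == "untracked")
  )
  keep <- qc$included
  if (!any(keep)) stop("run_pipeline: no bout passed quality control")
  features <- do.call(rbind, Map(
    function(b, s) {
      if (cfg$dim == "2d") {
        extract_features_2d(b, step_cfg, xcom, strikes = s)
      } else {
        extract_features_3d(b, step_cfg, strikes = s)
      }
    },
    bouts[keep], strikes[keep]
  ))
  rownames(features) <- NULL

  fnames <- if (cfg$dim == "2d") features_2d_names() else features_3d_names()
  tbl <- build_cohort_table(features, meta, feature_names = fnames)
  outcomes <- if (cfg$outcome == "both") c("updrs_gait", "sas_gait") else cfg$outcome
  models <- lapply(stats::setNames(outcomes, outcomes), function(oc) {
    screen <- univariate_screen(tbl, oc, features = fnames, alpha = cfg$alpha)
    pruning <- prune_correlated(tbl, screen$selected_by_p, oc, cfg$r_threshold)
    fit <- fit_multivariate(tbl, pruning$final_features, oc)
    evaluation <- evaluate_model(tbl, fit, oc)
    list(screen = screen, pruning = pruning, fit = fit, evaluation = evaluation)
  })

  report <- structure(
    list(
      config = cfg, config_hash = config_hash(cfg), seed = cfg$seed,
      qc = qc, qc_counts = qc_counts, features = features,
      cohort = tbl, models = models
    ),
    class = "run_report"
  )
  if (!is.null(cfg$output_dir)) write_run_report(report, cfg$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "<run_report %s> %s, seed %d | bouts: %d total, %d included (%d too short, %d untracked)\n",
    substr(x$config_hash, 1, 8), x$config$dim, x$config$seed,
    x$qc_counts["total"], x$qc_counts["included"],
    x$qc_counts["too_short"], x$qc_counts["untracked"]
  ))
  for (oc in names(x$models)) {
    m <- x$models[[oc]]
    cat(sprintf(
      "  %s: %d/%d features selected -> %d after pruning; accuracy %.1f%%, adjacent %.1f%%\n",
      oc, length(m$screen$selected_by_p), nrow(m$screen$univariate),
      length(m$pruning$final_features),
      100 * m$evaluation$accuracy, 100 * m$evaluation$adjacent_agreement
    ))
  }
  invisible(x)
}

#' Write a run report's artifacts to a directory
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf(
    "# config_hash: %s seed: %d\n", report$config_hash, report$seed
  )
  wcsv <- function(d, name) {
    f <- file.path(dir, name)
    con <- file(f, "w")
    writeLines(sub("\n$", "", stamp), con)
    utils::write.csv(d, con, row.names = FALSE)
    close(con)
  }
  wcsv(report$qc, "qc_log.csv")
  wcsv(report$features, "features.csv")
  for (oc in names(report$models)) {
    m <- report$models[[oc]]
    wcsv(m$screen$univariate, sprintf("univariate_%s.csv", oc))
    wcsv(as.data.frame(m$fit), sprintf("multivariate_%s.csv", oc))
    wcsv(as.data.frame(m$evaluation$confusion), sprintf("confusion_%s.csv", oc))
    wcsv(m$evaluation$per_participant, sprintf("per_participant_%s.csv", oc))
    gg <- plot_confusion(
      m$evaluation$confusion,
      sprintf("%s (%s features)", oc, report$config$dim)
    )
    try(
      ggplot2::ggsave(
        file.path(dir, sprintf("confusion_%s.png", oc)), gg,
        width = 5, height = 4, dpi = 120
      ),
      silent = TRUE
    )
  }
  jsonlite::write_json(
    list(
      config = unclass(report$config), config_hash = report$config_hash,
      qc_counts = as.list(report$qc_counts)
    ),
    file.path(dir, "run.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE, null = "null"
  )
  invisible(dir)
}
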