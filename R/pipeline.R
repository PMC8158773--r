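# ---- configuration ----------------------------------------------------------

#' Pipeline configuration
#'
#' One validated object holding every stage's parameters: cohort generation,
#' quality gating, aggregation, feature selection / model fit, the
#' train/evaluation split, and the evaluation layer. The effective
#' configuration is written beside a run's outputs so every run is
#' auditable and exactly repeatable from its directory.
#'
#' @param n,duration_s,fs,seed Cohort size, record duration (s), sampling
#'   rate (Hz), base seed.
#' @param cohort Named list of overrides passed to
#'   \code{\link{cohort_params}}.
#' @param quality_threshold Quality-gate threshold.
#' @param min_beats Minimum accepted beats per record.
#' @param train_fraction Fraction of subjects used for calibration; the
#'   complement is the evaluation set. 1 evaluates in-sample.
#' @param max_features,cv_folds Selection settings.
#' @param out_dir Output directory (created if needed).
#' @param make_plots Write Bland-Altman and error-grid figures.
#' @return Object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(n = 200, duration_s = 180, fs = 1000, seed = 1L,
                            cohort = list(), quality_threshold = 0.9,
                            min_beats = 10, train_fraction = 0.5,
                            max_features = 8, cv_folds = 5,
                            out_dir = "results/run", make_plots = FALSE) {
  cfg <- as.list(environment())
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (!is.numeric(cfg$n) || cfg$n < 1)
    stop("config validation error: n must be at least 1")
  if (cfg$fs < 100) stop("config validation error: fs must be >= 100 Hz")
  if (cfg$duration_s <= 0) stop("config validation error: duration_s <= 0")
  if (cfg$train_fraction <= 0 || cfg$train_fraction > 1)
    stop("config validation error: train_fraction must be in (0, 1]")
  if (cfg$quality_threshold < 0 || cfg$quality_threshold > 1)
    stop("config validation error: quality_threshold must be in [0, 1]")
  invisible(cfg)
}

# ---- orchestration ----------------------------------------------------------

#' Run the full simulate-extract-calibrate-evaluate pipeline
#'
#' End to end: generate the synthetic cohort, extract record-level features
#' from every recording (records whose quality gate or fiducial detection
#' fails are logged and skipped), split subjects into calibration and
#' evaluation sets, fit the systolic and diastolic linear models, predict on
#' the evaluation set, and run the full agreement analysis against the cuff
#' references. All artifacts (feature and cuff tables, models, predictions,
#' report JSON, effective config, log) are written under
#' \code{config$out_dir}. The same seed and config reproduce the report
#' byte for byte.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, a list with the report, models, tables and paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.txt")
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  cargs <- utils::modifyList(
    list(n = config$n, duration_s = config$duration_s, fs = config$fs,
         seed = config$seed),
    config$cohort)
  cp <- do.call(cohort_params, cargs)
  say("stage simulate: generating %d subjects (%g s @ %g Hz, seed %d)",
      cp$n, cp$duration_s, cp$fs, cp$seed)
  cohort <- generate_cohort(cp)

  say("stage extract: features from %d recordings", cp$n)
  feat_rows <- list()
  for (i in seq_len(cp$n)) {
    fx <- tryCatch(
      extract_features(cohort$recordings[[i]],
                       quality_threshold = config$quality_threshold,
                       min_beats = config$min_beats),
      error = function(e) {
        say("stage extract: record %d skipped (%s)", i, conditionMessage(e))
        NULL
      })
    if (!is.null(fx)) feat_rows[[length(feat_rows) + 1]] <- fx$features
  }
  if (!length(feat_rows))
    stop("stage extract: every record failed feature extraction")
  features <- do.call(rbind, feat_rows)
  features$subject <- as.integer(features$subject)

  tab <- merge(features, cohort$cuff, by = "subject")
  set.seed(config$seed + 104729L)  # split substream, offset by a fixed prime
  n_ok <- nrow(tab)
  n_train <- max(2, round(config$train_fraction * n_ok))
  train_idx <- sort(sample(n_ok, n_train))
  eval_idx <- if (config$train_fraction >= 1) seq_len(n_ok)
              else setdiff(seq_len(n_ok), train_idx)
  say("stage fit: %d calibration / %d evaluation subjects",
      n_train, length(eval_idx))

  fcols <- intersect(feature_names, names(tab))
  models <- list()
  for (tg in c("sbp", "dbp")) {
    models[[tg]] <- fit_bp_model(tab[train_idx, fcols],
                                 tab[[paste0(tg, "_cuff")]][train_idx],
                                 target_name = tg, seed = config$seed,
                                 max_features = config$max_features,
                                 k = config$cv_folds)
    say("stage fit: %s model uses [%s], residual sd %.2f mmHg", tg,
        paste(models[[tg]]$features, collapse = ", "),
        models[[tg]]$diagnostics$residual_sd)
  }

  pairs <- data.frame(
    subject = tab$subject[eval_idx],
    sbp_ref = tab$sbp_cuff[eval_idx], dbp_ref = tab$dbp_cuff[eval_idx],
    sbp_pred = predict(models$sbp, tab[eval_idx, fcols]),
    dbp_pred = predict(models$dbp, tab[eval_idx, fcols]))

  say("stage evaluate: %d paired subjects", nrow(pairs))
  report <- evaluate_predictions(pairs)
  report$models <- lapply(models, function(m)
    list(target = m$target, intercept = m$intercept,
         coefficients = as.list(m$coefficients),
         residual_sd = m$diagnostics$residual_sd, n = m$diagnostics$n))
  report$config <- config[c("n", "duration_s", "fs", "seed",
                            "quality_threshold", "min_beats",
                            "train_fraction")]

  paths <- list(
    report = file.path(config$out_dir, "report.json"),
    features = file.path(config$out_dir, "features.csv"),
    cuff = file.path(config$out_dir, "cuff.csv"),
    predictions = file.path(config$out_dir, "predictions.csv"),
    config = file.path(config$out_dir, "config.json"))
  write_report(report, paths$report,
               csv_path = file.path(config$out_dir, "zones.csv"))
  utils::write.csv(features, paths$features, row.names = FALSE)
  utils::write.csv(cohort$cuff, paths$cuff, row.names = FALSE)
  utils::write.csv(pairs, paths$predictions, row.names = FALSE)
  jsonlite::write_json(unclass(config)[setdiff(names(config), "cohort")],
                       paths$config, auto_unbox = TRUE, digits = NA)
  for (tg in c("sbp", "dbp"))
    write_bp_model(models[[tg]],
                   file.path(config$out_dir, paste0("model_", tg, ".json")))
  if (isTRUE(config$make_plots)) {
    for (tg in c("sbp", "dbp")) {
      ggplot2::ggsave(file.path(config$out_dir,
                                paste0("bland_altman_", tg, ".png")),
                      plot_bland_altman(pairs, tg), width = 6, height = 4,
                      dpi = 120)
      ggplot2::ggsave(file.path(config$out_dir,
                                paste0("error_grid_", tg, ".png")),
                      plot_error_grid(pairs, tg), width = 6, height = 5,
                      dpi = 120)
    }
  }
  writeLines(log_lines, log_path)
  invisible(list(report = report, models = models, features = features,
                 pairs = pairs, cohort_truth = cohort$truth, paths = paths))
}
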