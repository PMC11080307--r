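#' Drop subjects with any missing value
#'
#' Rows with a missing time, event indicator or covariate are removed
#' (complete-case analysis); the dropped subject ids are logged.  Idempotent.
#'
#' @param cohort a [survival_cohort()].
#' @return List with `cohort` (complete rows) and `dropped` (subject ids of
#'   removed rows, possibly empty).
#' @export
drop_incomplete <- function(cohort) {
  cohort <- as_survival_cohort(cohort)
  keep <- complete.cases(as.data.frame(cohort))
  if (!any(keep)) abort_data("all rows have missing values")
  list(cohort = survival_cohort(cohort[keep, , drop = FALSE]),
       dropped = cohort$subject_id[!keep])
}

#' Encode tumour grade as two indicator columns
#'
#' Grade is categorical with levels 1/2/3, so only two indicators enter a
#' regression: `grade2` and `grade3`, with grade 1 the reference (a grade-1
#' subject is coded (0, 0)).
#'
#' @param cohort a [survival_cohort()] with a `grade` column in \{1, 2, 3\}.
#' @return The cohort with `grade2`/`grade3` columns appended.
#' @export
encode_grade <- function(cohort) {
  cohort <- as_survival_cohort(cohort)
  if (!("grade" %in% names(cohort))) abort_data("no grade column")
  g <- cohort$grade
  bad <- stats::na.omit(unique(g[!(g %in% c(1, 2, 3))]))
  if (length(bad) > 0)
    abort_data(paste0("unseen grade level(s): ", paste(bad, collapse = ", ")))
  cohort$grade2 <- as.integer(g == 2)
  cohort$grade3 <- as.integer(g == 3)
  survival_cohort(cohort)
}

#' Z-score numeric columns with training-set statistics
#'
#' Means and standard deviations (n-1 denominator) are computed on the
#' training cohort only and applied to both cohorts, so the test set is
#' normalized on the training scale (no information leaks from test to
#' train).  After the transform each training column has mean 0 and sd 1.
#'
#' @param train training [survival_cohort()].
#' @param test optional test cohort transformed with the *training*
#'   statistics (a constant test column is fine).
#' @param columns numeric columns to scale.
#' @return List with `train`, `test` (or `NULL`), and `stats` (data.frame
#'   `column`, `mean`, `sd`).
#' @export
zscore_normalize <- function(train, test = NULL, columns) {
  train <- as_survival_cohort(train)
  missing_cols <- setdiff(columns, names(train))
  if (length(missing_cols) > 0)
    abort_data(paste0("column(s) not in training cohort: ",
                      paste(missing_cols, collapse = ", ")))
  mu <- vapply(columns, function(cn) mean(train[[cn]]), numeric(1))
  sdv <- vapply(columns, function(cn) sd(train[[cn]]), numeric(1))
  zero <- columns[!is.finite(sdv) | sdv == 0]
  if (length(zero) > 0)
    abort_data(paste0("zero-variance training column(s): ",
                      paste(zero, collapse = ", ")))
  for (j in seq_along(columns))
    train[[columns[j]]] <- (train[[columns[j]]] - mu[j]) / sdv[j]
  if (!is.null(test)) {
    test <- as_survival_cohort(test)
    for (j in seq_along(columns))
      test[[columns[j]]] <- (test[[columns[j]]] - mu[j]) / sdv[j]
  }
  list(train = survival_cohort(train),
       test = if (is.null(test)) NULL else survival_cohort(test),
       stats = data.frame(column = columns, mean = unname(mu),
                          sd = unname(sdv), row.names = NULL))
}

#' Configuration for the end-to-end analysis pipeline
#'
#' Either file mode (`train_path`/`test_path` pointing at cohort CSVs) or
#' simulation mode (a [cohort_spec()] plus a `test_fraction` used to carve
#' off the test set).
#'
#' @param train_path,test_path cohort CSV paths (file mode).
#' @param spec a [cohort_spec()] (simulation mode); ignored when paths are
#'   given.
#' @param test_fraction test-set fraction in simulation mode.
#' @param covariates covariate names before encoding; `"grade"` expands to
#'   `grade2` + `grade3`.
#' @param conf_level confidence level for effect intervals.
#' @param n_grid,grid_probs,g_floor metric grid settings, see
#'   [default_time_grid()].
#' @param bootstrap_B bootstrap replicates for metric bands (0 disables).
#' @param sim_seed seed for simulation-mode generation and the train/test
#'   split.
#' @param boot_seed seed for bootstrap resampling.
#' @param out_dir optional output directory for report artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(train_path = NULL, test_path = NULL, spec = NULL,
                            test_fraction = 80 / 491,
                            covariates = c("age", "grade", "rad_1", "rad_2",
                                           "rad_3"),
                            conf_level = 0.95, n_grid = 20,
                            grid_probs = c(0.05, 0.95), g_floor = 0.1,
                            bootstrap_B = 10, sim_seed = 1, boot_seed = 1,
                            out_dir = NULL) {
  if (length(covariates) == 0) abort_config("covariate list must be non-empty")
  if (is.null(train_path) && is.null(spec))
    abort_config("either train_path or a cohort spec is required")
  structure(list(train_path = train_path, test_path = test_path, spec = spec,
                 test_fraction = test_fraction, covariates = covariates,
                 conf_level = conf_level, n_grid = n_grid,
                 grid_probs = grid_probs, g_floor = g_floor,
                 bootstrap_B = bootstrap_B, sim_seed = sim_seed,
                 boot_seed = boot_seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [pipeline_config()], with an optional
#'   nested `spec` block passed to [cohort_spec()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("no such config file: ", path))
  lst <- yaml::read_yaml(path)
  if (!is.null(lst$spec)) lst$spec <- do.call(cohort_spec, lst$spec)
  if (!is.null(lst$covariates)) lst$covariates <- unlist(lst$covariates)
  do.call(pipeline_config, lst)
}

# Table-2-style effect table combining the two models; attributes carry the
# Weibull shape/scale header block.
effects_table <- function(wfit, cfit, conf_level) {
  covs <- wfit$covariate_names
  rows <- lapply(covs, function(cn) {
    hr <- hazard_ratio(wfit, cn, conf_level)
    etr <- event_time_ratio(wfit, cn, conf_level)
    chr_se <- sqrt(cfit$covariance[cn, cn])
    z <- z_crit(conf_level)
    data.frame(predictor = cn,
               weibull_coef = unname(wfit$beta[cn]),
               weibull_hr = hr$estimate, weibull_hr_low = hr$ci_low,
               weibull_hr_high = hr$ci_high,
               weibull_etr = etr$estimate, weibull_etr_low = etr$ci_low,
               weibull_etr_high = etr$ci_high,
               cph_coef = unname(cfit$beta[cn]),
               cph_hr = exp(unname(cfit$beta[cn])),
               cph_hr_low = exp(cfit$beta[cn] - z * chr_se),
               cph_hr_high = exp(cfit$beta[cn] + z * chr_se),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "gamma") <- wfit$gamma
  attr(out, "lambda") <- wfit$lambda
  out
}

#' Run the end-to-end parametric survival analysis
#'
#' Executes the full pipeline: load or simulate train/test cohorts, drop
#' incomplete rows, encode grade, z-score the numeric covariates with
#' training statistics, fit the Cox model with Schoenfeld and martingale
#' diagnostics, fit the Weibull model with effect estimates (HR and ETR per
#' covariate) and the cumulative-hazard goodness-of-fit check, assess the
#' death-time distribution on the uncensored deaths, and compute IPCW Brier
#' and time-dependent AUC curves for both models (plus the null-model Brier
#' reference) on the training and test sets, with bootstrap bands on the
#' training set.  Fully deterministic given the seeds in the config.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @return An `analysis_report`: nested list with elements `effects`
#'   (Table-2-style data.frame), `shape`, `scale`, `ph_test`, `distfit`,
#'   `metrics` (tidy data.frame of all curves), `check_dist` (max
#'   cumulative-hazard discrepancy), `counts`, `normalization`, and
#'   `provenance` (seeds, package version, config hash).  Written to
#'   `config$out_dir` as `report.json`, `effects.csv`, `metrics.csv` and a
#'   `diagnostics/` folder when an output directory is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    abort_config("config must be a pipeline_config or a YAML path")

  # --- ingest -------------------------------------------------------------
  if (!is.null(config$train_path)) {
    train <- read_cohort(config$train_path)
    test <- if (!is.null(config$test_path)) read_cohort(config$test_path)
            else NULL
  } else {
    full <- generate_cohort(config$spec)
    parts <- split_cohort(full, config$test_fraction, config$sim_seed)
    train <- parts$train
    test <- parts$test
  }
  if (is.null(test)) abort_config("a test cohort is required")

  # --- clean / encode / normalize ----------------------------------------
  dtr <- drop_incomplete(train)
  dte <- drop_incomplete(test)
  train <- encode_grade(dtr$cohort)
  test <- encode_grade(dte$cohort)
  model_covs <- unlist(lapply(config$covariates, function(cn)
    if (cn == "grade") c("grade2", "grade3") else cn))
  numeric_covs <- setdiff(config$covariates, "grade")
  zs <- zscore_normalize(train, test, numeric_covs)
  train <- zs$train
  test <- zs$test

  # --- models and diagnostics --------------------------------------------
  cfit <- fit_cox(train, model_covs)
  wfit <- fit_weibull_aft(train, model_covs, conf_level = config$conf_level)
  phres <- ph_test(cfit)
  schoen <- schoenfeld_residuals(cfit, train)
  mart <- martingale_residuals(cfit, train)
  cd <- check_distribution(wfit, train)

  deaths <- train$time[train$event == 1]
  distfit <- do.call(rbind, lapply(
    c("weibull", "lognormal", "loglogistic"), function(fam) {
      f <- fit_univariate(deaths, fam)
      ks <- ks_statistic(deaths, f)
      data.frame(family = fam, param1 = unname(f$params[1]),
                 param2 = unname(f$params[2]),
                 param_names = paste(names(f$params), collapse = "/"),
                 loglik = f$loglik, ks_D = ks$D, ks_p = ks$p_value,
                 row.names = NULL)
    }))

  # --- predictive accuracy ------------------------------------------------
  grid <- default_time_grid(train, config$n_grid, config$grid_probs,
                            config$g_floor)
  curves <- list()
  for (set in c("train", "test")) {
    ch <- if (set == "train") train else test
    sw <- survival_matrix_weibull(wfit, ch, grid)
    sc <- survival_matrix_cox(cfit, ch, grid)
    curves[[paste0(set, "_weibull_brier")]] <-
      cbind(dataset = set, brier_curve(sw, ch, grid, "weibull"))
    curves[[paste0(set, "_cox_brier")]] <-
      cbind(dataset = set, brier_curve(sc, ch, grid, "cox"))
    curves[[paste0(set, "_null_brier")]] <-
      cbind(dataset = set, null_model_curve(ch, grid, "brier"))
    curves[[paste0(set, "_weibull_auc")]] <-
      cbind(dataset = set, auc_curve(1 - sw, ch, grid, "weibull"))
    curves[[paste0(set, "_cox_auc")]] <-
      cbind(dataset = set, auc_curve(1 - sc, ch, grid, "cox"))
  }
  if (config$bootstrap_B > 0) {
    refit_w <- function(boot, times) {
      f <- fit_weibull_aft(boot, model_covs)
      survival_matrix_weibull(f, boot, times)
    }
    refit_c <- function(boot, times) {
      f <- fit_cox(boot, model_covs)
      survival_matrix_cox(f, boot, times)
    }
    curves$boot_weibull_brier <- cbind(dataset = "train_bootstrap",
      bootstrap_curves(refit_w, train, grid, "brier", config$bootstrap_B,
                       config$boot_seed, "weibull"))
    curves$boot_cox_brier <- cbind(dataset = "train_bootstrap",
      bootstrap_curves(refit_c, train, grid, "brier", config$bootstrap_B,
                       config$boot_seed, "cox"))
  }
  metrics <- do.call(rbind, lapply(curves, as.data.frame))
  rownames(metrics) <- NULL

  eff <- effects_table(wfit, cfit, config$conf_level)
  report <- structure(list(
    effects = eff, shape = wfit$gamma, scale = wfit$lambda,
    weibull_loglik = wfit$loglik, cox_loglik = cfit$loglik,
    ph_test = as.data.frame(phres), ph_transform = attr(phres, "transform"),
    distfit = distfit,
    check_dist_max_discrepancy = attr(cd, "max_discrepancy"),
    metrics = metrics,
    counts = list(n_train = nrow(train), n_test = nrow(test),
                  events_train = sum(train$event),
                  events_test = sum(test$event),
                  dropped_train = length(dtr$dropped),
                  dropped_test = length(dte$dropped),
                  deaths_for_distfit = length(deaths)),
    normalization = zs$stats,
    diagnostics = list(schoenfeld = schoen, martingale = mart,
                       check_dist = as.data.frame(cd)),
    provenance = list(package_version = as.character(
                        utils::packageVersion("parasurv")),
                      sim_seed = config$sim_seed,
                      boot_seed = config$boot_seed,
                      covariates = model_covs,
                      conf_level = config$conf_level,
                      config_hash = rlang::hash(
                        unclass(config)[setdiff(names(config), "out_dir")]))),
    class = "analysis_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write an analysis report to disk
#'
#' Emits `report.json` (everything except the bulky residual matrices),
#' `effects.csv` (Table-2 layout: one row per predictor with Weibull
#' coefficient/HR/ETR and Cox coefficient/HR; shape and scale repeated as
#' header columns), `metrics.csv` (tidy: dataset, model, metric, time,
#' value, lower, upper) and a `diagnostics/` folder with the residual
#' matrices and cumulative-hazard check as CSV.  No timestamps are written,
#' so a rerun with identical config and seeds is byte-identical.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "diagnostics"), showWarnings = FALSE)
  eff <- cbind(report$effects, shape = report$shape, scale = report$scale)
  write.csv(eff, file.path(dir, "effects.csv"), row.names = FALSE)
  write.csv(report$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  d <- report$diagnostics
  write.csv(data.frame(time = d$schoenfeld$time, d$schoenfeld$residuals),
            file.path(dir, "diagnostics", "schoenfeld.csv"),
            row.names = FALSE)
  write.csv(data.frame(time = d$schoenfeld$time, d$schoenfeld$scaled),
            file.path(dir, "diagnostics", "schoenfeld_scaled.csv"),
            row.names = FALSE)
  write.csv(data.frame(martingale = d$martingale),
            file.path(dir, "diagnostics", "martingale.csv"),
            row.names = FALSE)
  write.csv(d$check_dist, file.path(dir, "diagnostics", "cumhaz_check.csv"),
            row.names = FALSE)
  json <- report[c("effects", "shape", "scale", "weibull_loglik",
                   "cox_loglik", "ph_test", "ph_transform", "distfit",
                   "check_dist_max_discrepancy", "counts", "normalization",
                   "provenance")]
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf(
    "Analysis report: n_train = %d (%d events), n_test = %d (%d events)\n",
    x$counts$n_train, x$counts$events_train, x$counts$n_test,
    x$counts$events_test))
  cat(sprintf("Weibull shape %.4f, scale %.4g per day^shape\n",
              x$shape, x$scale))
  cat("\nEffect estimates:\n")
  print(data.frame(predictor = x$effects$predictor,
                   round(x$effects[, c("weibull_coef", "weibull_hr",
                                       "weibull_etr", "cph_coef", "cph_hr")],
                         4)))
  cat(sprintf("\nPH global test p = %.4g (%s transform)\n",
              x$ph_test$p[x$ph_test$covariate == "GLOBAL"], x$ph_transform))
  invisible(x)
}
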