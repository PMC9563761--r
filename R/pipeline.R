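#' Pipeline configuration
#'
#' Collects every constant of the end-to-end analysis in one object: cohort
#' generation, non-wear detection, valid-day and bout thresholds,
#' cross-validation settings, eligibility bounds and the master seed.
#' Defaults reproduce the study conditions: 276 participants, a 240-min
#' non-wear window with two spurious minutes of up to 2 steps, a 600-wear-min
#' valid day with edge days excluded, short/long walking bouts at < 40 / >=
#' 300 steps, long sedentary bouts at >= 30 min, fragmentation bouts at >= 5
#' min, 10-fold cross-validation replicated 100 times, and SBP eligibility
#' 90--170 mmHg.
#'
#' @param n_participants cohort size.
#' @param seed master seed; per-stage seeds are split from it.
#' @param coef_map planted standardized effects, see [cohort_config()].
#' @param nonwear_window,spurious_allowance,spurious_max_steps non-wear rule.
#' @param min_wear_minutes,exclude_edge_days,min_days valid-day rule.
#' @param short_bout_steps,long_bout_steps,long_sed_minutes,frag_min_minutes
#'   bout thresholds.
#' @param cv_folds,cv_replicates,grid_size,grid_min_ratio lasso CV settings.
#' @param sbp_min,sbp_max eligibility bounds (mmHg).
#' @param write_labels write the labeled minute CSV during [run_pipeline()]
#'   (default `TRUE`; the file is large for big cohorts).
#' @param ... further arguments passed to [cohort_config()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_participants = 276L, seed = 1L,
                            coef_map = c(avg_bout_cadence = -0.2,
                                         avg_long_sedentary_bouts_per_day = 0.2,
                                         age = 0.22, gender = -0.12,
                                         race_black = 0.165),
                            nonwear_window = 240L, spurious_allowance = 2L,
                            spurious_max_steps = 2L,
                            min_wear_minutes = 600L, exclude_edge_days = TRUE,
                            min_days = 3L,
                            short_bout_steps = 40, long_bout_steps = 300,
                            long_sed_minutes = 30L, frag_min_minutes = 5L,
                            cv_folds = 10L, cv_replicates = 100L,
                            grid_size = 100L, grid_min_ratio = 1e-4,
                            sbp_min = 90, sbp_max = 170,
                            write_labels = TRUE, ...) {
  thresholds <- c(nonwear_window = nonwear_window,
                  min_wear_minutes = min_wear_minutes,
                  short_bout_steps = short_bout_steps,
                  long_bout_steps = long_bout_steps,
                  long_sed_minutes = long_sed_minutes,
                  frag_min_minutes = frag_min_minutes,
                  cv_folds = cv_folds, cv_replicates = cv_replicates,
                  grid_size = grid_size)
  if (any(thresholds <= 0)) {
    stop("all thresholds must be positive; offending: ",
         paste(names(thresholds)[thresholds <= 0], collapse = ", "))
  }
  structure(
    list(n_participants = as.integer(n_participants), seed = seed,
         coef_map = coef_map,
         nonwear = nonwear_params(nonwear_window, spurious_allowance,
                                  spurious_max_steps),
         min_wear_minutes = as.integer(min_wear_minutes),
         exclude_edge_days = exclude_edge_days, min_days = as.integer(min_days),
         short_bout_steps = short_bout_steps, long_bout_steps = long_bout_steps,
         long_sed_minutes = as.integer(long_sed_minutes),
         frag_min_minutes = as.integer(frag_min_minutes),
         cv_folds = as.integer(cv_folds),
         cv_replicates = as.integer(cv_replicates),
         grid_size = as.integer(grid_size), grid_min_ratio = grid_min_ratio,
         sbp_min = sbp_min, sbp_max = sbp_max,
         write_labels = isTRUE(write_labels),
         cohort_args = list(...)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys correspond to [pipeline_config()] arguments; `coef_map` is
#' given as a mapping of predictor name to standardized effect size.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$coef_map)) cfg$coef_map <- unlist(cfg$coef_map)
  do.call(pipeline_config, cfg)
}

#' Run the full pipeline
#'
#' Executes simulate -> process -> metrics -> select -> regress on a
#' synthetic cohort and writes every stage's output plus a reproducibility
#' manifest to `out_dir`: `steps.csv` (minute epochs for all participants),
#' `cohort.csv`, `labeled_minutes.csv` (optional), `day_summary.csv`,
#' `measures.csv`, `selection.json`, `model.json`, `summary.txt`,
#' `manifest.json`. Re-running with an identical configuration reproduces
#' byte-identical measure and selection outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `measures`, `selection`, `model`, `eligibility`, `paths`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$n_participants < 1L) stop("pipeline requires at least one participant")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- split_seed(config$seed, 3L)   # cohort, selection CV, spare

  message("stage 1/5: simulate cohort (n = ", config$n_participants, ")")
  gen <- do.call(generate_cohort, c(
    list(cfg = do.call(cohort_config, c(
      list(n_participants = config$n_participants,
           coef_map = config$coef_map, seed = seeds[[1L]]),
      config$cohort_args)),
      keep_series = TRUE, nonwear = config$nonwear,
      min_wear_minutes = config$min_wear_minutes,
      exclude_edge_days = config$exclude_edge_days)))
  steps_path <- file.path(out_dir, "steps.csv")
  all_series <- do.call(rbind, gen$series)
  write_step_series(all_series, steps_path)
  cohort_path <- file.path(out_dir, "cohort.csv")
  utils::write.csv(gen$cohort, cohort_path, row.names = FALSE)

  message("stage 2/5: minute processing")
  labeled <- vector("list", length(gen$series))
  day_rows <- vector("list", length(gen$series))
  valid_sets <- vector("list", length(gen$series))
  for (i in seq_along(gen$series)) {
    s <- gen$series[[i]]
    lab <- classify_minutes(s, config$nonwear)
    vd <- determine_valid_days(s, lab, config$min_wear_minutes,
                               config$exclude_edge_days, config$min_days)
    valid_sets[[i]] <- vd
    labeled[[i]] <- cbind(s, label = lab, stringsAsFactors = FALSE)
    wear <- tapply(lab != "nonwear", s$day, sum)
    day_rows[[i]] <- data.frame(
      participant_id = s$participant_id[1L],
      day = as.integer(names(wear)),
      wear_minutes = as.integer(wear),
      valid = as.integer(names(wear)) %in% vd$valid_days,
      stringsAsFactors = FALSE
    )
  }
  if (config$write_labels) {
    lab_path <- file.path(out_dir, "labeled_minutes.csv")
    out <- do.call(rbind, labeled)
    names(out)[names(out) == "minute"] <- "minute_of_day"
    utils::write.csv(out, lab_path, row.names = FALSE)
  }
  utils::write.csv(do.call(rbind, day_rows),
                   file.path(out_dir, "day_summary.csv"), row.names = FALSE)

  message("stage 3/5: activity measures")
  meas <- vector("list", length(gen$series))
  for (i in seq_along(gen$series)) {
    if (valid_sets[[i]]$below_minimum) {
      stop("stage 3 (metrics) failed: participant ",
           gen$series[[i]]$participant_id[1L], " has fewer than ",
           config$min_days, " valid days")
    }
    meas[[i]] <- activity_measures(
      gen$series[[i]], labeled[[i]]$label, valid_sets[[i]],
      short_bout_steps = config$short_bout_steps,
      long_bout_steps = config$long_bout_steps,
      long_sed_minutes = config$long_sed_minutes,
      frag_min_minutes = config$frag_min_minutes)
  }
  measures <- do.call(rbind, meas)
  measures_path <- file.path(out_dir, "measures.csv")
  utils::write.csv(measures, measures_path, row.names = FALSE)

  message("stage 4/5: variable selection")
  elig <- filter_eligibility(gen$cohort, config$sbp_min, config$sbp_max)
  analysis <- merge(elig$cohort, measures, by = "participant_id", sort = FALSE)
  sel <- select_activity_measures(
    analysis[measure_names()], analysis$sbp_mmhg,
    folds = config$cv_folds, replicates = config$cv_replicates,
    grid_size = config$grid_size, grid_min_ratio = config$grid_min_ratio,
    seed = seeds[[2L]])
  sel_json <- list(
    lambda_grid = sel$cv$lambda_grid,
    cv_mse = sel$cv$cv_mse,
    optimal_lambda = sel$cv$optimal_lambda,
    sets = sel$selection[c("lasso", "aic", "adj_r2", "rss")],
    intersection = sel$selected
  )
  jsonlite::write_json(sel_json, file.path(out_dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(sel$enumeration$table,
                   file.path(out_dir, "subset_enumeration.csv"),
                   row.names = FALSE)

  message("stage 5/5: sequential regression")
  reg_data <- prepare_regression_data(elig$cohort, measures)
  blocks <- list(
    covariates = c("age", "gender", "race_black", "race_other",
                   "months_since_stroke"),
    walking_capacity = "sixmwt_m",
    activity_measures = sel$selected
  )
  if (length(sel$selected) == 0L) blocks$activity_measures <- NULL
  model <- fit_sequential(reg_data, blocks)
  jsonlite::write_json(
    list(blocks = model$blocks, coefficients = model$coefficients,
         r2 = model$r2, n = model$n),
    file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  summary_path <- file.path(out_dir, "summary.txt")
  sink(summary_path); print(sel); cat("\n"); print(model); sink()

  manifest <- list(
    package_version = as.character(utils::packageVersion("walkbp")),
    master_seed = config$seed,
    stage_seeds = unlist(seeds),
    n_participants = config$n_participants,
    n_eligible = nrow(elig$cohort),
    n_excluded = nrow(elig$exclusions),
    rows = list(steps = nrow(all_series), measures = nrow(measures)),
    measures_md5 = unname(tools::md5sum(measures_path)),
    config = config[setdiff(names(config), "nonwear")],
    nonwear = unclass(config$nonwear)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(cohort = gen$cohort, measures = measures, selection = sel,
                 model = model, eligibility = elig,
                 truth = gen$truth,
                 paths = list(out_dir = out_dir, steps = steps_path,
                              cohort = cohort_path, measures = measures_path)))
}
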