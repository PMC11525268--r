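# File interchange: CSV data tables, YAML run configuration, JSON reports.
# All tabular interchange is UTF-8 CSV with a header row.

#' Write a simulated dataset to a directory
#'
#' Writes `participants.csv`, `trials_block1.csv`, `trials_block2.csv`,
#' `exclusions.csv` and a `manifest.yaml` echoing the configuration, the
#' master seed and the MD5 content hash of each data file.
#'
#' @param dataset an `sr_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sr_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(
    participants = dataset$participants,
    trials_block1 = dataset$trials_block1,
    trials_block2 = dataset$trials_block2,
    exclusions = dplyr::filter(dataset$participants, .data$excluded) |>
      dplyr::select("id", "age", "exclusion_reason")
  )
  paths <- file.path(dir, paste0(names(files), ".csv"))
  purrr::walk2(files, paths, readr::write_csv)
  cfg <- dataset$config
  manifest <- list(
    package = "srmotion",
    seed = dataset$seed,
    n_recruited = cfg$n_recruited,
    n_kept = sum(!dataset$participants$excluded),
    config = list(
      age_mean = cfg$age_mean, age_sd = cfg$age_sd,
      age_bounds = cfg$age_bounds,
      noise_intercept = cfg$noise_intercept,
      noise_slope = cfg$noise_slope,
      heterogeneity_sd = cfg$heterogeneity_sd,
      p_100 = cfg$p_100,
      observer = unclass(cfg$observer)
    ),
    file_md5 = as.list(setNames(unname(tools::md5sum(paths)),
                                basename(paths)))
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing the CSV files.
#' @return list with tibbles `participants`, `trials_block1`,
#'   `trials_block2` and the parsed `manifest`.
#' @export
read_dataset <- function(dir) {
  read1 <- function(name, col_types) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) stop_domain("missing file: %s", path)
    readr::read_csv(path, col_types = col_types, progress = FALSE)
  }
  list(
    participants = read1("participants", readr::cols(
      id = "d", age = "d", group_dots = "i", sigma_int = "d",
      threshold_pct = "d", reversals_last40 = "i", staircase_trials = "i",
      block2_accuracy = "d", exclusion_reason = "c", excluded = "l"
    )),
    trials_block1 = read1("trials_block1", readr::cols(
      participant_id = "d", trial = "i", coherence_pct = "d",
      correct = "l", is_reversal = "l", step_pct = "d"
    )),
    trials_block2 = read1("trials_block2", readr::cols(
      participant_id = "d", trial = "i", n_dots = "i", coherence_pct = "d",
      target_interval = "i", response_interval = "i", correct = "l"
    )),
    manifest = yaml::read_yaml(file.path(dir, "manifest.yaml"))
  )
}

#' Simulate a cohort and write it to disk
#'
#' End-to-end convenience wrapper: [generate_dataset()] then
#' [write_dataset()].
#'
#' @param config a [cohort_config()].
#' @param dir output directory.
#' @param seed master seed.
#' @param target_kept optional kept-sample target (see
#'   [generate_dataset()]).
#' @return the `sr_dataset`, invisibly.
#' @export
sr_simulate <- function(config = cohort_config(), dir, seed = 1,
                        target_kept = NULL) {
  dataset <- generate_dataset(config, seed = seed, target_kept = target_kept)
  write_dataset(dataset, dir)
  invisible(dataset)
}

#' Run the full analysis stage
#'
#' Given participant and trial tables (in memory or a directory written by
#' [sr_simulate()]), fits the log-threshold linear model, compares the four
#' polynomial GLMMs by AICc, runs Type III Wald tests, marginal and part
#' R-squared, peak extraction at reference ages, the dichotomised-age
#' variant, and the simulated-residual KS check.
#'
#' @param participants kept-participant tibble, or a directory path.
#' @param trials block-2 trial tibble with `age` joined (ignored when
#'   `participants` is a directory).
#' @param degrees polynomial degrees to compare.
#' @param nodes quadrature nodes.
#' @param peak_ages ages at which to report predicted accuracy peaks.
#' @param seed seed for the residual simulation.
#' @return list of class `sr_analysis` with elements `threshold_lm`,
#'   `selection`, `wald`, `marginal_r2`, `part_r2`, `peaks`,
#'   `group_fit`, `group_wald`, `residual_ks`.
#' @export
sr_analyze <- function(participants, trials = NULL, degrees = 1:4,
                       nodes = 15, peak_ages = c(20, 50, 80), seed = 1) {
  if (is.character(participants)) {
    data <- read_dataset(participants)
    keep <- dplyr::filter(data$participants, !.data$excluded)
    trials <- data$trials_block2 |>
      dplyr::semi_join(keep, by = c(participant_id = "id")) |>
      dplyr::left_join(dplyr::select(keep, "id", "age"),
                       by = c(participant_id = "id"))
    participants <- keep
  }
  thr_lm <- fit_threshold_lm(participants)
  selection <- compare_sr_models(trials, degrees = degrees, nodes = nodes)
  best <- best_model(selection)
  wald <- wald_type3(best)
  pr2 <- purrr::map_dbl(
    setNames(, c("dots", "age", "dots:age")),
    function(tm) part_r2(best, tm)
  )
  peaks <- purrr::map_dfr(peak_ages, function(a) peak_location(best, a))
  group_fit <- fit_logistic_glmm(
    trials, degree = best$design$degree, age_mode = "group", nodes = nodes
  )
  structure(
    list(
      threshold_lm = thr_lm,
      selection = selection,
      wald = wald,
      marginal_r2 = marginal_r2(best),
      part_r2 = pr2,
      peaks = peaks,
      group_fit = group_fit,
      group_wald = wald_type3(group_fit),
      residual_ks = simulated_residual_ks(best, seed = seed)
    ),
    class = "sr_analysis"
  )
}

#' @export
print.sr_analysis <- function(x, ...) {
  cat("<sr_analysis>\n\n-- log-threshold linear model --\n")
  print(x$threshold_lm)
  cat("\n-- GLMM model selection --\n")
  print(tibble::as_tibble(x$selection$table))
  cat("\n-- Type III Wald tests (best model) --\n")
  print(x$wald)
  cat(sprintf("\nmarginal R2: %.4f\n", x$marginal_r2))
  cat("part R2:", paste(sprintf("%s=%.4f", names(x$part_r2), x$part_r2),
                        collapse = ", "), "\n")
  cat("\n-- accuracy peaks --\n")
  print(x$peaks)
  cat(sprintf("\nresidual KS: D = %.4f, p = %.4g\n",
              x$residual_ks$statistic, x$residual_ks$p.value))
  invisible(x)
}

#' Write an analysis report
#'
#' Serialises an `sr_analysis` to `report.json` plus a Table-1-shaped
#' `selection_table.csv` (Model, K, AICc, Delta_AICc, AICcWt, Cum_Wt, LL).
#'
#' @param analysis an `sr_analysis`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tbl <- analysis$selection$table
  readr::write_csv(
    tibble::tibble(
      Model = tbl$model, K = tbl$K, AICc = tbl$AICc,
      Delta_AICc = tbl$delta_AICc, AICcWt = tbl$weight,
      Cum_Wt = tbl$cum_weight, LL = tbl$loglik
    ),
    file.path(dir, "selection_table.csv")
  )
  report <- list(
    threshold_lm = list(
      coefficients = as.list(analysis$threshold_lm$coefficients),
      anova = analysis$threshold_lm$anova,
      marginal_means = analysis$threshold_lm$marginal_means
    ),
    selection = tbl,
    wald = analysis$wald,
    marginal_r2 = analysis$marginal_r2,
    part_r2 = as.list(analysis$part_r2),
    peaks = analysis$peaks,
    group_wald = analysis$group_wald,
    residual_ks = analysis$residual_ks[c("statistic", "p.value")]
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
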