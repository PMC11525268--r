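# Experiment orchestration: thresholding block, constant-stimuli block,
# group assignment and the three exclusion rules.

#' Assign participants to staircase-density subgroups
#'
#' Seeded independent assignment to the 100-dot or 400-dot thresholding
#' subgroup. The default probability reproduces the observed 118:96 split.
#'
#' @param n number of participants.
#' @param p_100 probability of the 100-dot subgroup.
#' @param seed integer seed.
#' @return integer vector of 100s and 400s.
#' @export
assign_group <- function(n, p_100 = 118 / 214, seed = NULL) {
  with_seed(seed, {
    ifelse(runif(n) < p_100, 100L, 400L)
  })
}

#' Run the adaptive thresholding block for one observer
#'
#' Drives the 1-up-2-down staircase with stochastic 2IFC responses from the
#' observer at a fixed dot numerosity.
#'
#' @param observer an [observer_params()].
#' @param group_dots staircase dot numerosity, 100 or 400.
#' @param config a [staircase_config()].
#' @param seed integer seed.
#' @return a list with elements `threshold_pct`, `state` (the completed
#'   staircase), and `log` (tibble from [staircase_log()]).
#' @export
run_thresholding_block <- function(observer, group_dots,
                                   config = staircase_config(),
                                   seed = NULL) {
  stopifnot(group_dots %in% c(100, 400))
  state <- with_seed(seed, {
    respond <- function(coherence_pct) {
      simulate_trials(observer, coherence_pct / 100, group_dots, 1)
    }
    staircase_run(respond, config)
  })
  list(
    threshold_pct = threshold_estimate(state, config),
    state = state,
    log = staircase_log(state)
  )
}

#' Pseudorandomised constant-stimuli schedule
#'
#' 20 trials at each of the 14 dot-numerosity levels (280 trials), in a
#' seeded random order constrained so no level occupies more than
#' `max_run` consecutive trials. Target intervals are balanced 140:140 and
#' shuffled independently.
#'
#' @param seed integer seed.
#' @param levels dot-numerosity levels.
#' @param trials_per_level trials at each level.
#' @param max_run maximum consecutive trials at one level.
#' @return tibble with columns `trial`, `n_dots`, `target_interval`.
#' @export
build_block2_schedule <- function(seed = NULL, levels = sr_dot_levels(),
                                  trials_per_level = 20, max_run = 3) {
  n <- length(levels) * trials_per_level
  with_seed(seed, {
    pool <- rep(levels, each = trials_per_level)
    repeat {
      ord <- sample(pool)
      runs <- rle(ord)
      if (max(runs$lengths) <= max_run) break
    }
    target <- sample(rep(c(1L, 2L), length.out = n))
    tibble::tibble(
      trial = seq_len(n),
      n_dots = as.integer(ord),
      target_interval = target
    )
  })
}

#' Run the constant-stimuli block for one observer
#'
#' Coherence is fixed at the threshold estimated in the first block; dot
#' numerosity follows the pseudorandomised 14-level schedule.
#'
#' @param observer an [observer_params()].
#' @param threshold_pct coherence from the thresholding block, percent.
#' @param seed integer seed.
#' @param schedule optional precomputed schedule from
#'   [build_block2_schedule()] (by default one is built from `seed`).
#' @return a list with `trials` (tibble: `trial`, `n_dots`, `coherence_pct`,
#'   `target_interval`, `response_interval`, `correct`) and
#'   `accuracy_by_level` (tibble: `n_dots`, `n_trials`, `accuracy`).
#' @export
run_constant_block <- function(observer, threshold_pct, seed = NULL,
                               schedule = NULL) {
  if (is.null(schedule)) {
    schedule <- build_block2_schedule(seed)
  }
  coherence <- threshold_pct / 100
  trials <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
    curve <- accuracy_curve(observer, coherence, sort(unique(schedule$n_dots)))
    p <- curve$p_correct[match(schedule$n_dots, curve$n_dots)]
    correct <- runif(nrow(schedule)) < p
    schedule |>
      dplyr::mutate(
        coherence_pct = threshold_pct,
        correct = correct,
        response_interval = ifelse(
          correct, .data$target_interval, 3L - .data$target_interval
        )
      ) |>
      dplyr::select(
        "trial", "n_dots", "coherence_pct", "target_interval",
        "response_interval", "correct"
      )
  })
  accuracy <- trials |>
    dplyr::group_by(.data$n_dots) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      accuracy = mean(.data$correct),
      .groups = "drop"
    )
  list(trials = trials, accuracy_by_level = accuracy)
}

#' Apply the three exclusion criteria
#'
#' A participant is dropped by the first failing criterion, checked in
#' order: (1) staircase threshold strictly above 75%; (2) fewer than 6
#' reversals in the last 40 staircase trials; (3) mean constant-stimuli
#' accuracy strictly above 90%. The boundary cases (exactly 75%, exactly 6
#' reversals, exactly 90%) are all kept.
#'
#' @param records tibble with columns `id`, `threshold_pct`,
#'   `reversals_last40`, `block2_accuracy` (other columns pass through).
#' @return the input tibble with logical `excluded` and character
#'   `exclusion_reason` columns added (`"none"` for kept rows).
#' @export
apply_exclusions <- function(records) {
  needed <- c("threshold_pct", "reversals_last40", "block2_accuracy")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop_domain("records lack column(s): %s", paste(missing_cols, collapse = ", "))
  }
  bad <- !stats::complete.cases(records[needed])
  if (any(bad)) {
    stop_domain(
      "missing exclusion statistics for participant(s): %s",
      paste(records$id[bad], collapse = ", ")
    )
  }
  records |>
    dplyr::mutate(
      exclusion_reason = dplyr::case_when(
        .data$threshold_pct > 75 ~ "threshold_gt_75",
        .data$reversals_last40 < 6 ~ "reversals_lt_6_in_40",
        .data$block2_accuracy > 0.9 ~ "accuracy_gt_90",
        TRUE ~ "none"
      ),
      excluded = .data$exclusion_reason != "none"
    )
}
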