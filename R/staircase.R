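# One-up two-down (Levitt) transformed staircase on percent coherence.
#
# Rules: one incorrect response moves coherence up by the current step; two
# consecutive correct responses move it down (the two-correct counter resets
# after every move). A move opposite in direction to the previous move is a
# reversal; the reversal value recorded is the coherence at which the
# direction changed (the pre-move level), the step size advances through the
# schedule at that reversal, and the reversal-triggering move itself already
# uses the new step. The staircase converges to the stimulus level at which
# p(correct)^2 = 1/2, i.e. 70.7% correct.

#' Staircase configuration
#'
#' @param initial_coherence starting coherence, percent.
#' @param step_sequence step sizes in percentage points; the k-th entry is
#'   used after `k - 1` reversals (the last entry thereafter). Must be
#'   strictly decreasing and positive.
#' @param n_reversals_stop staircase completes at this many reversals.
#' @param n_reversals_discard initial reversals dropped by the threshold
#'   estimator.
#' @param bounds coherence clamp, percent.
#' @param max_trials hard cap; exceeding it is an error (diagnostic for a
#'   non-terminating response pattern).
#' @return an object of class `staircase_config`.
#' @export
staircase_config <- function(initial_coherence = 70,
                             step_sequence = c(10, 5, 3, 2, 1),
                             n_reversals_stop = 12,
                             n_reversals_discard = 4,
                             bounds = c(1, 100),
                             max_trials = 10000) {
  if (any(diff(step_sequence) >= 0) || any(step_sequence <= 0)) {
    stop_domain("step_sequence must be strictly decreasing and positive")
  }
  if (n_reversals_discard >= n_reversals_stop) {
    stop_domain("n_reversals_discard must be < n_reversals_stop")
  }
  structure(
    list(
      initial_coherence = initial_coherence,
      step_sequence = step_sequence,
      n_reversals_stop = as.integer(n_reversals_stop),
      n_reversals_discard = as.integer(n_reversals_discard),
      bounds = bounds,
      max_trials = as.integer(max_trials)
    ),
    class = "staircase_config"
  )
}

#' Fresh staircase state
#'
#' @param config a [staircase_config()].
#' @return an object of class `staircase_state`.
#' @export
staircase_init <- function(config = staircase_config()) {
  structure(
    list(
      coherence = config$initial_coherence,
      trial_index = 0L,
      consecutive_correct = 0L,
      last_move = "none",
      reversal_values = numeric(0),
      reversal_trials = integer(0),
      complete = FALSE,
      trial_log = list()
    ),
    class = "staircase_state"
  )
}

# Current step size: schedule position is min(#reversals, last) (0-based).
current_step <- function(state, config) {
  k <- min(length(state$reversal_values), length(config$step_sequence) - 1L)
  config$step_sequence[k + 1L]
}

#' Advance the staircase by one response
#'
#' @param state a `staircase_state` (not yet complete).
#' @param correct logical: was the response correct?
#' @param config the [staircase_config()].
#' @return the updated `staircase_state`.
#' @export
#' @examples
#' s <- staircase_init()
#' s <- staircase_step(s, TRUE)
#' s <- staircase_step(s, TRUE) # two correct: down to 60
#' s$coherence
staircase_step <- function(state, correct, config = staircase_config()) {
  stopifnot(inherits(state, "staircase_state"))
  if (state$complete) stop_domain("cannot step a complete staircase")
  state$trial_index <- state$trial_index + 1L
  level_now <- state$coherence
  move <- "none"
  if (!correct) {
    move <- "up"
    state$consecutive_correct <- 0L
  } else {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= 2L) {
      move <- "down"
      state$consecutive_correct <- 0L
    }
  }
  is_reversal <- FALSE
  if (move != "none") {
    if (state$last_move != "none" && move != state$last_move) {
      is_reversal <- TRUE
      state$reversal_values <- c(state$reversal_values, level_now)
      state$reversal_trials <- c(state$reversal_trials, state$trial_index)
    }
    step <- current_step(state, config) # reversal already counted: new step
    delta <- if (move == "up") step else -step
    state$coherence <- min(max(level_now + delta, config$bounds[1]),
                           config$bounds[2])
    state$last_move <- move
    if (length(state$reversal_values) >= config$n_reversals_stop) {
      state$complete <- TRUE
    }
  }
  state$trial_log[[state$trial_index]] <- list(
    trial = state$trial_index, coherence_pct = level_now,
    correct = correct, is_reversal = is_reversal,
    step_pct = current_step(state, config)
  )
  if (!state$complete && state$trial_index >= config$max_trials) {
    stop_domain(
      "staircase did not complete within %d trials", config$max_trials
    )
  }
  state
}

#' Run a staircase against a response generator
#'
#' @param respond function of one argument (coherence, percent) returning
#'   `TRUE`/`FALSE`.
#' @param config a [staircase_config()].
#' @return the completed `staircase_state`.
#' @export
staircase_run <- function(respond, config = staircase_config()) {
  state <- staircase_init(config)
  while (!state$complete) {
    state <- staircase_step(state, respond(state$coherence), config)
  }
  state
}

#' Threshold estimate from a completed staircase
#'
#' Arithmetic mean of the reversal values after discarding the initial
#' `n_reversals_discard` of them.
#'
#' @param state a complete `staircase_state`.
#' @param config the [staircase_config()].
#' @return threshold in percent coherence.
#' @export
threshold_estimate <- function(state, config = staircase_config()) {
  if (!state$complete) stop_domain("staircase is not complete")
  keep <- seq(config$n_reversals_discard + 1L, config$n_reversals_stop)
  mean(state$reversal_values[keep])
}

#' Reversals within the final trials
#'
#' Number of reversals falling in the last `window` trials of the run; used
#' by the exclusion rule requiring at least 6 reversals in the last 40
#' trials.
#'
#' @param state a complete `staircase_state`.
#' @param window number of final trials to inspect.
#' @return integer count.
#' @export
reversal_window_count <- function(state, window = 40) {
  if (!state$complete) stop_domain("staircase is not complete")
  sum(state$reversal_trials > state$trial_index - window)
}

#' Staircase trial log as a tibble
#'
#' @param state a `staircase_state`.
#' @return tibble with columns `trial`, `coherence_pct`, `correct`,
#'   `is_reversal`, `step_pct`.
#' @export
staircase_log <- function(state) {
  dplyr::bind_rows(lapply(state$trial_log, tibble::as_tibble))
}
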