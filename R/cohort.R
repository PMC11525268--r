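# Synthetic lifespan cohort.
#
# Ages are drawn from a normal distribution truncated to [18, 82]; internal
# noise rises linearly with age (age is the proxy for neural noise), with
# multiplicative lognormal heterogeneity between participants. The defaults
# place young adults in the sub-threshold regime where external noise helps
# (interior accuracy peak) and older adults in the supra-threshold regime
# where any added external noise hurts (flat-then-falling curve, peak at
# the lowest numerosity): rising thresholds, the inverted U, its flattening
# and the leftward peak shift are all emergent.

#' Cohort configuration
#'
#' @param n_recruited number of recruited participants before exclusions.
#' @param age_mean,age_sd parameters of the untruncated age distribution.
#' @param age_bounds truncation interval, years.
#' @param noise_map functional form of the age-to-internal-noise proxy:
#'   `"exponential"` (default) or `"linear"`. The exponential map spreads
#'   the transition from sub- to supra-threshold observers across the whole
#'   age range, which a linear map compresses into the youngest few years.
#' @param noise_intercept internal-noise SD at the lower age bound.
#' @param noise_slope yearly increase of internal noise: SD units per year
#'   for the linear map, exponential rate (1/years) for the exponential
#'   map.
#' @param heterogeneity_sd lognormal SD (log scale) of between-participant
#'   jitter on internal noise; pooling gain gets one third of it.
#' @param observer template [observer_params()] providing the non-noise
#'   parameters.
#' @param p_100 probability of assignment to the 100-dot staircase group.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_recruited = 286,
                          age_mean = 43.52,
                          age_sd = 19.61,
                          age_bounds = c(18, 82),
                          noise_map = c("exponential", "linear"),
                          noise_intercept = 0.12,
                          noise_slope = 0.0462,
                          heterogeneity_sd = 0.05,
                          observer = observer_params(),
                          p_100 = 118 / 214) {
  if (age_bounds[1] < 0 || age_bounds[2] > 120 || diff(age_bounds) <= 0) {
    stop_domain("age_bounds must be an increasing interval within [0, 120]")
  }
  if (age_sd < 0 || heterogeneity_sd < 0 || noise_intercept < 0) {
    stop_domain("SDs and noise_intercept must be >= 0")
  }
  noise_map <- match.arg(noise_map)
  structure(
    list(
      n_recruited = as.integer(n_recruited),
      age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
      noise_map = noise_map,
      noise_intercept = noise_intercept, noise_slope = noise_slope,
      heterogeneity_sd = heterogeneity_sd, observer = observer,
      p_100 = p_100
    ),
    class = "cohort_config"
  )
}

#' Sample ages from the truncated normal
#'
#' Inverse-CDF sampling of a normal distribution truncated to the cohort
#' age bounds.
#'
#' @param n number of draws.
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return numeric vector of ages within the bounds.
#' @export
sample_ages <- function(n, config = cohort_config(), seed = NULL) {
  lo <- pnorm(config$age_bounds[1], config$age_mean, config$age_sd)
  hi <- pnorm(config$age_bounds[2], config$age_mean, config$age_sd)
  with_seed(seed, {
    qnorm(runif(n, lo, hi), config$age_mean, config$age_sd)
  })
}

#' Mean of the truncated age distribution
#'
#' Closed form for the mean implied by the truncation; used as the
#' reference value in distributional checks.
#' @param config a [cohort_config()].
#' @return a number.
#' @export
truncated_age_mean <- function(config = cohort_config()) {
  a <- (config$age_bounds[1] - config$age_mean) / config$age_sd
  b <- (config$age_bounds[2] - config$age_mean) / config$age_sd
  config$age_mean +
    config$age_sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

#' Observer parameters for a given age
#'
#' Internal noise follows the configured age map - linear
#' `intercept + slope * (age - lower bound)` or exponential
#' `intercept * exp(slope * (age - lower bound))` - multiplied by lognormal
#' jitter `exp(N(0, heterogeneity_sd))`; pooling
#' gain receives milder jitter (one third of the SD). Other parameters come
#' from the template observer. Setting `heterogeneity_sd = 0` in the config
#' gives the deterministic (jitter-free) mapping.
#'
#' @param age age in years, within the cohort bounds.
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return an [observer_params()].
#' @export
observer_from_age <- function(age, config = cohort_config(), seed = NULL) {
  if (age < config$age_bounds[1] || age > config$age_bounds[2]) {
    stop_domain("age %.1f outside cohort bounds [%g, %g]", age,
                config$age_bounds[1], config$age_bounds[2])
  }
  base <- config$observer
  si <- age_to_sigma_int(age, config)
  with_seed(seed, {
    jit_si <- rlnorm(1, 0, config$heterogeneity_sd)
    jit_gain <- rlnorm(1, 0, config$heterogeneity_sd / 3)
    observer_params(
      theta = base$theta,
      sigma_int = si * jit_si,
      gain_a = base$gain_a * jit_gain,
      n_sat = base$n_sat,
      ext_b = base$ext_b,
      lapse = base$lapse
    )
  })
}

#' Internal noise implied by an age under a cohort configuration
#'
#' The deterministic (jitter-free) age-to-noise mapping.
#'
#' @param age age in years (vectorised).
#' @param config a [cohort_config()].
#' @return internal-noise SDs.
#' @export
age_to_sigma_int <- function(age, config = cohort_config()) {
  d <- age - config$age_bounds[1]
  switch(config$noise_map %||% "linear",
    linear = config$noise_intercept + config$noise_slope * d,
    exponential = config$noise_intercept * exp(config$noise_slope * d)
  )
}

#' Generate a full synthetic dataset
#'
#' Runs, for every recruited participant: group assignment, the adaptive
#' thresholding block, the constant-stimuli block at the estimated
#' threshold, and the exclusion rules. Sub-seeds for every stage derive
#' deterministically from `seed` via [derive_seed()].
#'
#' @param config a [cohort_config()].
#' @param seed master integer seed.
#' @param target_kept if not `NULL`, redraw participants until this many
#'   are kept (capped at 4x the recruited count), so demonstration runs can
#'   match a fixed analysable sample size.
#' @return a list of class `sr_dataset` with tibbles `participants`
#'   (`id`, `age`, `group_dots`, `sigma_int`, `threshold_pct`,
#'   `reversals_last40`, `staircase_trials`, `block2_accuracy`, `excluded`,
#'   `exclusion_reason`), `trials_block1` (staircase logs) and
#'   `trials_block2` (trial-level records), plus the `config` and `seed`.
#' @export
generate_dataset <- function(config = cohort_config(), seed = 1,
                             target_kept = NULL) {
  n_goal <- if (is.null(target_kept)) config$n_recruited else target_kept
  max_recruits <- if (is.null(target_kept)) {
    config$n_recruited
  } else {
    4L * config$n_recruited
  }
  ages <- sample_ages(max_recruits, config, seed = derive_seed(seed, "ages"))
  groups <- assign_group(max_recruits, config$p_100,
                         seed = derive_seed(seed, "groups"))
  participants <- list()
  block1 <- list()
  block2 <- list()
  kept <- 0L
  i <- 0L
  while (i < max_recruits) {
    i <- i + 1L
    if (!is.null(target_kept) && kept >= n_goal) break
    if (is.null(target_kept) && i > config$n_recruited) break
    obs <- observer_from_age(ages[i], config,
                             seed = derive_seed(seed, "observer", i))
    b1 <- run_thresholding_block(obs, groups[i],
                                 seed = derive_seed(seed, "staircase", i))
    b2 <- run_constant_block(obs, b1$threshold_pct,
                             seed = derive_seed(seed, "block2", i))
    participants[[i]] <- tibble::tibble(
      id = i,
      age = ages[i],
      group_dots = groups[i],
      sigma_int = obs$sigma_int,
      threshold_pct = b1$threshold_pct,
      reversals_last40 = reversal_window_count(b1$state),
      staircase_trials = b1$state$trial_index,
      block2_accuracy = mean(b2$trials$correct)
    )
    block1[[i]] <- dplyr::mutate(b1$log, participant_id = i, .before = 1)
    block2[[i]] <- dplyr::mutate(b2$trials, participant_id = i, .before = 1)
    reason <- apply_exclusions(participants[[i]])$exclusion_reason
    if (reason == "none") kept <- kept + 1L
  }
  participants <- apply_exclusions(dplyr::bind_rows(participants))
  structure(
    list(
      participants = participants,
      trials_block1 = dplyr::bind_rows(block1),
      trials_block2 = dplyr::bind_rows(block2),
      config = config,
      seed = seed
    ),
    class = "sr_dataset"
  )
}

#' @export
print.sr_dataset <- function(x, ...) {
  p <- x$participants
  cat(sprintf(
    "<sr_dataset> %d recruited, %d kept (%d excluded); %d block-2 trials\n",
    nrow(p), sum(!p$excluded), sum(p$excluded), nrow(x$trials_block2)
  ))
  drops <- table(p$exclusion_reason[p$excluded])
  if (length(drops)) {
    cat("  exclusions:",
        paste(sprintf("%s=%d", names(drops), drops), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Kept participants and their block-2 trials
#'
#' @param dataset an `sr_dataset`.
#' @return list with tibbles `participants` and `trials` restricted to
#'   non-excluded participants, with `age` joined onto the trials.
#' @export
kept_data <- function(dataset) {
  keep <- dataset$participants |> dplyr::filter(!.data$excluded)
  trials <- dataset$trials_block2 |>
    dplyr::semi_join(keep, by = c(participant_id = "id")) |>
    dplyr::left_join(
      dplyr::select(keep, "id", "age"),
      by = c(participant_id = "id")
    )
  list(participants = keep, trials = trials)
}
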