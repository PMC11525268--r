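# Reference generative experiments for recovery studies.
#
# Two purpose-built generators complement the full experiment pipeline:
#
# * a "reference quartic" cohort: binomial trial tables simulated from a
#   known degree-4 logit surface whose young and old anchor curves have the
#   canonical shapes (a deep inverted U for the young, a flat-then-falling
#   curve for the old). The generative fixed effects are obtained by
#   projecting that surface onto the exact orthogonal-polynomial design of
#   the simulated cohort, so the truth is quartic by construction and
#   parameter recovery can be scored coefficient by coefficient.
#
# * an age-banded observer cohort: three age bands with increasing internal
#   noise, responses drawn from the observer model at each participant's
#   analytic coherence threshold. The generative accuracy peak is known
#   exactly per participant, which makes the band experiment a ground-truth
#   test of fitted peak ordering.

# Anchor logit surface: smooth inverted-U young curve and flat-then-falling
# old curve on the probability scale, linearly blended in age; x is the
# scaled log dot numerosity.
reference_eta <- function(age, x) {
  p_young <- 0.52 + 0.27 * exp(-(x + 0.35)^2 / 2.2)
  p_old <- 0.75 - 0.21 * plogis(2 * (x - 0.3))
  w <- pmin(pmax((age - 20) / 60, 0), 1)
  qlogis((1 - w) * p_young + w * p_old)
}

# Expand aggregated binomial counts to trial-level rows.
expand_counts <- function(agg) {
  tidyr::uncount(agg, weights = .data$m, .id = "rep") |>
    dplyr::group_by(.data$participant_id, .data$n_dots) |>
    dplyr::mutate(correct = dplyr::row_number() <= .data$k) |>
    dplyr::ungroup() |>
    dplyr::select("participant_id", "age", "n_dots", "correct")
}

#' Simulate a cohort from a known quartic logit GLMM
#'
#' Draws ages from the lifespan distribution, projects the reference
#' accuracy surface onto the degree-4 orthogonal-polynomial design of the
#' realised cohort to obtain the generative fixed effects, adds Gaussian
#' random intercepts, and samples binomial responses.
#'
#' @param n_participants cohort size.
#' @param sigma_u2 random-intercept variance.
#' @param seed integer seed.
#' @param trials_per_level binomial size per participant and level.
#' @return list with `trials` (trial-level tibble), `beta` (the generative
#'   fixed effects, named as in the fitted design), `sigma_u2`.
#' @export
simulate_quartic_cohort <- function(n_participants = 214, sigma_u2 = 0.3,
                                    seed = 1, trials_per_level = 20) {
  lv <- sr_dot_levels()
  with_seed(seed, {
    ages <- pmin(pmax(rnorm(n_participants, 43.52, 19.61), 18), 82)
    agg <- tidyr::crossing(
      participant_id = seq_len(n_participants), n_dots = lv
    )
    agg$age <- ages[agg$participant_id]
    agg$m <- as.integer(trials_per_level)
    agg$k <- 0L # placeholder for design construction
    design <- build_glmm_design(agg, 4)
    x_scaled <- as.vector(scale(log(agg$n_dots)))
    beta <- qr.coef(qr(design$x), reference_eta(agg$age, x_scaled))
    u <- rnorm(n_participants, 0, sqrt(sigma_u2))
    p <- plogis(drop(design$x %*% beta) + u[agg$participant_id])
    agg$k <- rbinom(nrow(agg), agg$m, p)
    list(trials = expand_counts(agg), beta = beta, sigma_u2 = sigma_u2)
  })
}

#' Simulate an age-banded observer cohort at analytic thresholds
#'
#' Three (by default) age bands with increasing internal noise; every
#' participant responds at their analytic 70.7% coherence threshold, so
#' the generative accuracy curve - and hence the true peak - is known in
#' closed form. The youngest band sits in the sub-threshold regime
#' (interior accuracy peak), the oldest in the supra-threshold regime
#' (peak at the lowest numerosity).
#'
#' @param n_band participants per band.
#' @param bands list of age intervals.
#' @param config a [cohort_config()] (supplies the age-to-noise map and
#'   observer template).
#' @param seed integer seed.
#' @return trial-level tibble with columns `participant_id`, `age`,
#'   `n_dots`, `correct`.
#' @export
simulate_band_cohort <- function(n_band = 100,
                                 bands = list(c(18, 29), c(38, 46),
                                              c(56, 64)),
                                 config = cohort_config(), seed = 1) {
  lv <- sr_dot_levels()
  with_seed(seed, {
    rows <- list()
    id <- 0L
    for (b in bands) {
      for (j in seq_len(n_band)) {
        id <- id + 1L
        age <- runif(1, b[1], b[2])
        obs <- observer_from_age(age, config,
                                 seed = sample.int(2147483646, 1))
        th <- coherence_threshold(obs, 100)
        if (is.na(th)) next
        p <- accuracy_curve(obs, th, lv)$p_correct
        rows[[id]] <- tibble::tibble(
          participant_id = id, age = age, n_dots = lv,
          k = rbinom(14, 20L, p), m = 20L
        )
      }
    }
    expand_counts(dplyr::bind_rows(rows))
  })
}

#' Empirical convergence point of the staircase
#'
#' Runs many seeded staircases against an observer with a known
#' psychometric function and maps the mean threshold estimate back through
#' that function: the 1-up-2-down rule targets p^2 = 1/2, i.e. 70.7%
#' correct.
#'
#' @param n_runs number of staircase runs.
#' @param observer the simulated observer ([observer_params()]).
#' @param n_dots staircase dot numerosity.
#' @param seed integer seed.
#' @return list with `mean_threshold_pct` and `p_at_mean` (the accuracy the
#'   observer would produce at the mean threshold).
#' @export
staircase_convergence <- function(n_runs = 1000,
                                  observer = observer_params(),
                                  n_dots = 100, seed = 1) {
  ths <- with_seed(seed, {
    replicate(n_runs, {
      st <- staircase_run(function(co) {
        simulate_trials(observer, co / 100, n_dots, 1)
      })
      threshold_estimate(st)
    })
  })
  m <- mean(ths)
  mom <- evidence_moments(observer, m / 100, n_dots)
  list(
    mean_threshold_pct = m,
    p_at_mean = p_correct_2ifc(mom$mu, mom$sigma, observer$theta,
                               observer$lapse)
  )
}
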