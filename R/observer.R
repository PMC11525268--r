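# Threshold stochastic-resonance observer.
#
# The observer reduces each stimulus interval to a scalar evidence draw.
# The target interval yields X_t ~ N(mu, sigma^2) and the non-target
# interval X_n ~ N(0, sigma^2), where
#
#   mu    = gain_a * coherence * n_dots / (n_dots + n_sat)   (pooled signal)
#   sigma = sqrt(sigma_int^2 + ext_b^2 * n_dots)             (total noise)
#
# Evidence is passed through a hard threshold T(x) = x [x > theta], and the
# observer picks the interval with the larger rectified evidence, guessing
# on exact ties (both rectified to zero). This is the minimal classical
# threshold model of stochastic resonance: a sub-threshold signal
# (mu < theta) is undetectable without noise, an intermediate amount of
# noise lifts signal-plus-noise over the threshold more often in the target
# interval than noise alone does in the other, and excessive noise swamps
# the asymmetry. External noise enters through dot numerosity: per-dot
# correspondence errors are independent, so their pooled standard deviation
# grows as sqrt(n_dots).

#' Observer parameters
#'
#' @param theta detection threshold on the evidence scale (> 0).
#' @param sigma_int internal (neural) noise SD, evidence units (>= 0).
#' @param gain_a pooling gain (> 0): asymptotic evidence per unit coherence.
#' @param n_sat pooling saturation constant in dots (> 0). The default is
#'   far below the tested numerosity range, so pooled signal is effectively
#'   density-independent and the density effect is carried entirely by the
#'   external-noise channel.
#' @param ext_b external-noise coefficient, evidence units per sqrt(dot).
#' @param lapse lapse rate in `[0, 0.1]`: fraction of trials answered at
#'   random regardless of the stimulus.
#' @return an object of class `observer_params`.
#' @export
#' @examples
#' observer_params(sigma_int = 0.4)
observer_params <- function(theta = 1,
                            sigma_int = 0.12,
                            gain_a = 5.8,
                            n_sat = 0.01,
                            ext_b = 0.04,
                            lapse = 0.02) {
  if (theta <= 0) stop_domain("theta must be > 0")
  if (sigma_int < 0) stop_domain("sigma_int must be >= 0")
  if (gain_a <= 0) stop_domain("gain_a must be > 0")
  if (n_sat <= 0) stop_domain("n_sat must be > 0")
  if (ext_b < 0) stop_domain("ext_b must be >= 0")
  if (lapse < 0 || lapse > 0.1) stop_domain("lapse must be in [0, 0.1]")
  structure(
    list(
      theta = theta, sigma_int = sigma_int, gain_a = gain_a,
      n_sat = n_sat, ext_b = ext_b, lapse = lapse
    ),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "<observer_params> theta=%g sigma_int=%g gain_a=%g n_sat=%g ext_b=%g lapse=%g\n",
    x$theta, x$sigma_int, x$gain_a, x$n_sat, x$ext_b, x$lapse
  ))
  invisible(x)
}

#' Evidence mean and SD for a stimulus
#'
#' @param params an [observer_params()].
#' @param coherence fraction of coherent dots, in `[0, 1]`.
#' @param n_dots total dot count (>= 1); may be a vector.
#' @return a tibble with columns `n_dots`, `mu`, `sigma`.
#' @export
#' @examples
#' p <- observer_params(gain_a = 2, n_sat = 100, sigma_int = 0.5, ext_b = 0.05)
#' evidence_moments(p, coherence = 0.1, n_dots = 100) # mu 0.1, sigma 0.70711
evidence_moments <- function(params, coherence, n_dots) {
  stopifnot(inherits(params, "observer_params"))
  if (!is_fraction(coherence)) stop_domain("coherence must be in [0, 1]")
  if (any(n_dots < 1)) stop_domain("n_dots must be >= 1")
  tibble::tibble(
    n_dots = n_dots,
    mu = params$gain_a * coherence * n_dots / (n_dots + params$n_sat),
    sigma = sqrt(params$sigma_int^2 + params$ext_b^2 * n_dots)
  )
}

#' Probability correct in the 2IFC task
#'
#' Exact probability that the rectified-max observer picks the target
#' interval. Decomposing on whether each interval's evidence crosses the
#' threshold gives two closed-form terms (only the target crosses; neither
#' crosses, resolved by a fair guess) plus one term where both cross,
#' computed by adaptive one-dimensional quadrature to absolute tolerance
#' 1e-6.
#'
#' @param mu target-interval evidence mean (>= 0).
#' @param sigma evidence SD (> 0); shared by both intervals.
#' @param theta detection threshold (> 0).
#' @param lapse lapse rate.
#' @return probability in `[0.5 * lapse + 0.5 * (1 - lapse), 1]`... i.e. a
#'   probability; equals 0.5 exactly when `mu = 0`.
#' @export
#' @examples
#' p_correct_2ifc(mu = 0, sigma = 1, theta = 1) # 0.5
p_correct_2ifc <- function(mu, sigma, theta, lapse = 0) {
  if (any(sigma <= 0)) stop_domain("sigma must be > 0")
  if (any(theta <= 0)) stop_domain("theta must be > 0")
  one <- function(mu, sigma, theta, lapse) {
    z_n <- pnorm(theta / sigma) # P(non-target stays below threshold)
    z_t <- pnorm((theta - mu) / sigma) # P(target stays below threshold)
    p_only_target <- (1 - z_t) * z_n
    p_neither <- 0.5 * z_t * z_n
    # both cross: target density against non-target CDF above theta
    p_both <- integrate(
      function(x) {
        dnorm(x, mean = mu, sd = sigma) *
          (pnorm(x / sigma) - pnorm(theta / sigma))
      },
      lower = theta, upper = Inf, abs.tol = 1e-6
    )$value
    p0 <- p_only_target + p_neither + p_both
    (1 - lapse) * p0 + lapse * 0.5
  }
  n <- max(length(mu), length(sigma), length(theta))
  mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n)
  theta <- rep_len(theta, n)
  vapply(seq_len(n), function(i) one(mu[i], sigma[i], theta[i], lapse),
         numeric(1))
}

#' Accuracy across dot-numerosity levels
#'
#' The deterministic psychometric curve of an observer at fixed coherence:
#' [evidence_moments()] composed with [p_correct_2ifc()] at each level.
#'
#' @inheritParams evidence_moments
#' @param levels integer vector of dot counts (each >= 1).
#' @return a tibble with columns `n_dots`, `coherence`, `p_correct`.
#' @export
accuracy_curve <- function(params, coherence, levels = sr_dot_levels()) {
  if (length(levels) < 1) stop_domain("levels must be non-empty")
  mom <- evidence_moments(params, coherence, levels)
  tibble::tibble(
    n_dots = as.integer(levels),
    coherence = coherence,
    p_correct = p_correct_2ifc(mom$mu, mom$sigma, params$theta, params$lapse)
  )
}

#' The 14 dot-numerosity levels of the constant-stimuli block
#'
#' Quasi-logarithmically spaced between 20 and 2000 dots.
#' @return integer vector of length 14.
#' @export
sr_dot_levels <- function() {
  c(20L, 29L, 41L, 58L, 83L, 118L, 168L, 239L, 340L, 485L, 691L, 999L,
    1403L, 2000L)
}

#' Accuracy-maximising dot numerosity
#'
#' The grid level at which the observer's accuracy peaks; ties go to the
#' smaller level. With rising internal noise the peak moves toward lower
#' external noise (leftward shift).
#'
#' @inheritParams accuracy_curve
#' @param grid sorted ascending integer grid of dot counts.
#' @return one element of `grid`.
#' @export
sr_peak <- function(params, coherence, grid = sr_dot_levels()) {
  if (length(grid) < 1) stop_domain("grid must be non-empty")
  if (is.unsorted(grid)) stop_domain("grid must be sorted ascending")
  curve <- accuracy_curve(params, coherence, grid)
  grid[which.max(curve$p_correct)] # which.max takes the first maximum
}

#' Analytic coherence threshold
#'
#' Inverts the psychometric function at a fixed dot numerosity by bisection
#' on coherence in `[0, 1]`, to a coherence tolerance of 1e-4. Returns
#' `NA_real_` when even full coherence cannot reach the target probability
#' (an "unattainable" threshold; such simulated participants pin the
#' staircase at its ceiling and are later excluded).
#'
#' @inheritParams evidence_moments
#' @param target_p target probability correct, in (0.5, 1); the default is
#'   the 1-up-2-down staircase convergence point `sqrt(1/2)`.
#' @return coherence fraction, or `NA_real_` if unattainable.
#' @export
coherence_threshold <- function(params, n_dots, target_p = sqrt(0.5)) {
  if (target_p <= 0.5 || target_p >= 1) {
    stop_domain("target_p must be in (0.5, 1)")
  }
  f <- function(co) {
    mom <- evidence_moments(params, co, n_dots)
    p_correct_2ifc(mom$mu, mom$sigma, params$theta, params$lapse) - target_p
  }
  if (f(1) < 0) {
    return(NA_real_)
  }
  lo <- 0
  hi <- 1
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate 2IFC trials
#'
#' Stochastic counterpart of [p_correct_2ifc()]: draws the two evidence
#' values, applies the rectified-max rule with a fair guess on ties, and a
#' lapse. Vectorised over trials; the long-run mean converges to
#' [p_correct_2ifc()].
#'
#' @inheritParams evidence_moments
#' @param n_trials number of trials to simulate.
#' @param seed integer seed.
#' @return logical vector of length `n_trials` (`TRUE` = correct).
#' @export
simulate_trials <- function(params, coherence, n_dots, n_trials = 1,
                            seed = NULL) {
  mom <- evidence_moments(params, coherence, n_dots[1])
  with_seed(seed, {
    x_t <- rnorm(n_trials, mom$mu, mom$sigma)
    x_n <- rnorm(n_trials, 0, mom$sigma)
    t_t <- ifelse(x_t > params$theta, x_t, 0)
    t_n <- ifelse(x_n > params$theta, x_n, 0)
    correct <- ifelse(
      t_t == t_n, runif(n_trials) < 0.5, t_t > t_n
    )
    lapsed <- runif(n_trials) < params$lapse
    ifelse(lapsed, runif(n_trials) < 0.5, correct)
  })
}
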