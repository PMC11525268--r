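test_that("evidence moments follow the pooling and noise formulas", {
  p <- observer_params(gain_a = 2, n_sat = 100, sigma_int = 0.5,
                       ext_b = 0.05)
  mom <- evidence_moments(p, coherence = 0.1, n_dots = 100)
  expect_equal(mom$mu, 0.1)
  expect_equal(mom$sigma, sqrt(0.5), tolerance = 1e-10) # 0.70711

  expect_equal(evidence_moments(p, 0, 123)$mu, 0)
  # saturation limit: mu -> gain_a * coherence
  expect_equal(evidence_moments(p, 0.4, 1e9)$mu, 2 * 0.4, tolerance = 1e-6)
  expect_error(observer_params(theta = -1), "theta")
  expect_error(observer_params(lapse = 0.5), "lapse")
})

test_that("2IFC probability is exact in the closed-form regimes", {
  # symmetry: no signal means chance for any noise and threshold
  for (s in c(0.1, 1, 5)) {
    for (th in c(0.5, 1, 2)) {
      expect_equal(p_correct_2ifc(0, s, th), 0.5, tolerance = 1e-8)
    }
  }
  # deterministic supra-threshold signal against a silent non-target
  expect_equal(p_correct_2ifc(2, 1e-9, 1, lapse = 0), 1)
  # lapse shrinks toward chance
  expect_equal(p_correct_2ifc(2, 1e-9, 1, lapse = 0.1), 0.95)
  expect_error(p_correct_2ifc(1, -1, 1), "sigma")
})

test_that("quadrature matches Monte-Carlo simulation of the decision rule", {
  set.seed(10)
  n_mc <- 1e6
  lattice <- expand.grid(
    mu = c(0.3, 0.8, 1.2, 2.5),
    sigma = c(0.3, 0.8, 1.5, 3),
    theta = c(1, 2)
  )
  lattice <- lattice[sample(nrow(lattice), 20), ]
  for (i in seq_len(nrow(lattice))) {
    mu <- lattice$mu[i]; sg <- lattice$sigma[i]; th <- lattice$theta[i]
    x_t <- rnorm(n_mc, mu, sg)
    x_n <- rnorm(n_mc, 0, sg)
    t_t <- ifelse(x_t > th, x_t, 0)
    t_n <- ifelse(x_n > th, x_n, 0)
    mc <- mean(ifelse(t_t == t_n, 0.5, t_t > t_n))
    se <- sqrt(mc * (1 - mc) / n_mc)
    expect_lt(abs(p_correct_2ifc(mu, sg, th) - mc), 4 * se + 1e-6)
  }
})

test_that("sub-threshold signals show stochastic resonance in noise", {
  # fixed mu < theta: accuracy vs sigma is an inverted U with chance limits
  sigmas <- 10^seq(-3, 3, length.out = 40)
  p <- p_correct_2ifc(0.7, sigmas, 1)
  expect_gt(max(p), 0.51)
  interior <- which.max(p)
  expect_gt(interior, 1)
  expect_lt(interior, length(sigmas))
  expect_lt(abs(p[1] - 0.5), 0.005)
  expect_lt(abs(p[length(sigmas)] - 0.5), 0.02)
})

test_that("accuracy curves respect the chance and noise-dominated limits", {
  obs <- observer_params(lapse = 0)
  flat <- accuracy_curve(obs, 0)
  expect_true(all(abs(flat$p_correct - 0.5) < 1e-8))
  # huge external noise at the top level forces chance
  noisy <- observer_params(ext_b = 50, lapse = 0)
  curve <- accuracy_curve(noisy, 0.5)
  expect_lt(abs(curve$p_correct[14] - 0.5), 0.01)
})

test_that("the accuracy peak moves to lower noise as internal noise rises", {
  # supra-threshold observer: monotone decreasing curve peaks at the first level
  supra <- observer_params(sigma_int = 2, lapse = 0)
  th <- coherence_threshold(supra, 100)
  expect_equal(sr_peak(supra, th), 20L)

  # lattice of internal-noise values at fixed coherence
  peaks <- vapply(c(0.1, 0.3, 0.5, 0.8, 1.2, 1.8), function(si) {
    sr_peak(observer_params(sigma_int = si), coherence = 0.16)
  }, integer(1))
  expect_true(all(diff(peaks) <= 0))
  # explicit pair from the lattice
  expect_lte(sr_peak(observer_params(sigma_int = 1), 0.16),
             sr_peak(observer_params(sigma_int = 0.2), 0.16))
})

test_that("coherence threshold inverts the psychometric function", {
  obs <- observer_params()
  # a barely-above-chance target needs very little coherence
  expect_lt(coherence_threshold(obs, 100, target_p = 0.505), 0.05)
  expect_lt(coherence_threshold(obs, 100, target_p = 0.505),
            coherence_threshold(obs, 100))
  # an observer too weak to ever reach the target is flagged unattainable
  weak <- observer_params(gain_a = 0.3, sigma_int = 3)
  expect_true(is.na(coherence_threshold(weak, 100)))
  expect_error(coherence_threshold(obs, 100, target_p = 0.4), "target_p")

  # bisection agrees with a dense grid scan
  th <- coherence_threshold(obs, 100)
  grid <- seq(0, 1, length.out = 2000)
  mom <- evidence_moments(obs, 1, 100) # sigma constant in coherence
  p_grid <- p_correct_2ifc(obs$gain_a * grid * 100 / (100 + obs$n_sat),
                           mom$sigma, obs$theta, obs$lapse)
  th_grid <- grid[which.min(abs(p_grid - sqrt(0.5)))]
  expect_lt(abs(th - th_grid), 1e-3)
})

test_that("trial simulation is consistent with the exact probability", {
  obs <- observer_params(lapse = 0)
  # forced guessing
  guess <- mean(simulate_trials(observer_params(lapse = 0), 0, 100,
                                n_trials = 20000, seed = 1))
  expect_lt(abs(guess - 0.5), 3 * sqrt(0.25 / 20000))
  # supra-threshold noiseless observer is always correct
  sure <- observer_params(sigma_int = 1e-6, ext_b = 1e-9, lapse = 0)
  expect_true(all(simulate_trials(sure, 1, 100, n_trials = 100, seed = 2)))
  # long-run mean matches quadrature at (mu = 1, sigma = 1, theta = 2)
  one <- observer_params(theta = 2, sigma_int = sqrt(1 - 0.04^2 * 100),
                         gain_a = 1 * (100 + 0.01) / 100, lapse = 0)
  p_exact <- p_correct_2ifc(1, 1, 2)
  sim <- mean(simulate_trials(one, 1, 100, n_trials = 1e5, seed = 3))
  expect_lt(abs(sim - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 1e5))
  # determinism
  expect_identical(simulate_trials(obs, 0.2, 100, 50, seed = 9),
                   simulate_trials(obs, 0.2, 100, 50, seed = 9))
})
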