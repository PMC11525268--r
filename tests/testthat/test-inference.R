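test_that("zscale centres and scales with stored transform parameters", {
  z <- zscale(c(1, 2, 3))
  expect_equal(z$scaled, c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(50, 7, 3)
  z2 <- zscale(x)
  expect_equal(mean(z2$scaled), 0, tolerance = 1e-12)
  expect_equal(sd(z2$scaled), 1, tolerance = 1e-12)
  expect_equal(z2$scaled, (x - mean(x)) / sd(x))
  expect_error(zscale(rep(2, 5)), "distinct")
})

test_that("orthogonal polynomials are orthonormal and match poly()", {
  op <- orthogonal_poly(c(1, 2, 3), 1)
  expect_equal(op$basis[, 1], c(-1, 0, 1) / sqrt(2), tolerance = 1e-12)

  set.seed(2)
  x <- rnorm(40)
  op4 <- orthogonal_poly(x, 4)
  gram <- crossprod(op4$basis)
  expect_lt(max(abs(gram - diag(4))), 1e-10)
  expect_lt(max(abs(colSums(op4$basis))), 1e-10)

  # column-by-column agreement with stats::poly up to sign
  xl <- log(sr_dot_levels())
  for (d in c(2, 4)) {
    mine <- orthogonal_poly(xl, d)$basis
    ref <- unclass(stats::poly(xl, degree = d))
    for (j in seq_len(d)) {
      expect_lt(min(max(abs(mine[, j] - ref[, j])),
                    max(abs(mine[, j] + ref[, j]))), 1e-10)
    }
  }

  # recurrence projects new values into the same basis
  op2 <- orthogonal_poly(xl, 3)
  expect_equal(poly_eval(op2, xl), op2$basis, tolerance = 1e-12)
  x_new <- c(3.5, 5.1)
  ref_new <- unclass(predict(stats::poly(xl, degree = 3), x_new))
  mine_new <- poly_eval(op2, x_new)
  for (j in 1:3) {
    sign_j <- sign(sum(orthogonal_poly(xl, 3)$basis[, j] *
                         unclass(stats::poly(xl, degree = 3))[, j]))
    expect_equal(mine_new[, j], sign_j * ref_new[, j], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  expect_error(orthogonal_poly(c(1, 1, 2), 2), "distinct")
})

test_that("AICc and Akaike weights follow their formulas", {
  expect_equal(aicc(-10, 2, 10), 25.71429, tolerance = 1e-6)
  expect_equal(aicc(-10, 2, 1e9), -2 * -10 + 4, tolerance = 1e-6)
  expect_error(aicc(-10, 9, 10), "n_obs")
  set.seed(3)
  ll <- rnorm(5, -100, 10); k <- 2:6; n <- 50
  expect_equal(aicc(ll, k, n),
               -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1))

  expect_equal(akaike_weights(rep(12, 4)), rep(0.25, 4))
  expect_equal(akaike_weights(c(0, 2)), c(0.7311, 0.2689), tolerance = 1e-4)
  # printed-table AICc column reproduces the published weights
  w <- akaike_weights(c(13408.62, 13409.76, 13424.48, 13720.58))
  expect_equal(round(w, 2), c(0.64, 0.36, 0, 0))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_error(akaike_weights(c(1, Inf)), "finite")
})

test_that("the selection table ranks, weights and checks its inputs", {
  fake_fit <- function(ll, k, agg) {
    structure(list(loglik = ll, K = k, n_obs = sum(agg$m), agg = agg),
              class = "sr_glmm")
  }
  agg <- tibble::tibble(participant_id = rep(1:2, each = 2),
                        k = c(3, 4, 5, 6), m = 20L)
  n <- sum(agg$m)
  # back out log-likelihoods that reproduce the published AICc column
  aiccs <- c(13720.58, 13424.48, 13409.76, 13408.62)
  ks <- c(5L, 7L, 9L, 11L)
  lls <- -(aiccs - 2 * ks - 2 * ks * (ks + 1) / (n - ks - 1)) / 2
  fits <- list(linear = fake_fit(lls[1], ks[1], agg),
               quadratic = fake_fit(lls[2], ks[2], agg),
               cubic = fake_fit(lls[3], ks[3], agg),
               fourth_degree = fake_fit(lls[4], ks[4], agg))
  tbl <- model_selection_table(fits)
  expect_equal(tbl$model,
               c("fourth_degree", "cubic", "quadratic", "linear"))
  expect_equal(tbl$delta_AICc, c(0, 1.14, 15.86, 311.96), tolerance = 1e-8)
  expect_equal(round(tbl$cum_weight, 2), c(0.64, 1, 1, 1))
  # order invariance
  expect_equal(model_selection_table(rev(fits)), tbl, ignore_attr = TRUE)
  # single fit
  one <- model_selection_table(fits[1])
  expect_equal(one$delta_AICc, 0)
  expect_equal(one$weight, 1)
  # mismatched data refused
  agg2 <- dplyr::mutate(agg, k = k + 1)
  fits$linear$agg <- agg2
  expect_error(model_selection_table(fits), "identical data")
})

test_that("the log-threshold LM matches the lm() oracle", {
  set.seed(4)
  n <- 120
  participants <- tibble::tibble(
    age = runif(n, 18, 82),
    group_dots = sample(c(100, 400), n, replace = TRUE),
    threshold_pct = exp(2.8 + 0.005 * age +
                          0.1 * (group_dots == 100) + rnorm(n, 0, 0.3))
  )
  fit <- fit_threshold_lm(participants)
  # oracle: base lm with identical coding
  d <- data.frame(
    y = log(participants$threshold_pct),
    a = scale(participants$age)[, 1],
    g = ifelse(participants$group_dots == 100, 1, -1)
  )
  ref <- lm(y ~ a * g, data = d)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-10)
  ref_anova <- anova(ref)
  expect_equal(fit$anova$f, ref_anova$`F value`[1:3], tolerance = 1e-8)
  expect_equal(fit$anova$p, ref_anova$`Pr(>F)`[1:3], tolerance = 1e-8)
  expect_equal(fit$anova$partial_eta2,
               ref_anova$`Sum Sq`[1:3] /
                 (ref_anova$`Sum Sq`[1:3] + ref_anova$`Sum Sq`[4]),
               tolerance = 1e-10)
  # marginal means at the mean age back-transform with exp
  expect_equal(fit$marginal_means$mean_pct,
               exp(fit$marginal_means$ln_mean))
  mm100 <- unname(coef(ref)[1] + coef(ref)[3])
  expect_equal(fit$marginal_means$ln_mean[1], mm100, tolerance = 1e-10)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$nobs, n)
})

test_that("the threshold LM recovers known generative coefficients", {
  truth <- c(b0 = 2.9, b_age = 0.25, b_g = 0.09, b_int = -0.05)
  est <- replicate(60, {
    n <- 100
    age <- runif(n, 18, 82)
    g <- sample(c(1, -1), n, replace = TRUE)
    a_s <- scale(age)[, 1]
    y <- truth[1] + truth[2] * a_s + truth[3] * g + truth[4] * a_s * g +
      rnorm(n, 0, 0.25)
    fit <- fit_threshold_lm(tibble::tibble(
      age = age, group_dots = ifelse(g == 1, 100, 400),
      threshold_pct = exp(y)
    ))
    fit$coefficients
  })
  expect_lt(max(abs(rowMeans(est) - truth)), 2 * 0.25 / sqrt(100 * 60 / 4))
})

test_that("GLMM with zero heterogeneity matches plain logistic regression", {
  sim <- sim_glmm_trials(40, 2, beta = c(0.6, -4, -6, 0.2, -1, -0.5),
                         sigma_u2 = 0, seed = 11)
  fit <- fit_logistic_glmm(sim$trials, degree = 2, nodes = 15)
  agg <- srmotion:::aggregate_trials(sim$trials)
  glm_fit <- glm.fit(sim$design$x, agg$k / agg$m, weights = agg$m,
                     family = binomial())
  expect_lt(max(abs(fit$beta - coef(glm_fit))), 1e-4)
  expect_lt(fit$sigma_u2, 1e-3)
  expect_true(fit$converged)
})

test_that("a symmetric split yields a zero intercept and boundary variance", {
  agg <- tibble::tibble(
    participant_id = rep(1:2, each = 14),
    age = rep(c(30, 60), each = 14),
    n_dots = rep(sr_dot_levels(), 2),
    k = 10L, m = 20L
  )
  fit <- fit_logistic_glmm(srmotion:::expand_counts(agg), degree = 1)
  expect_lt(abs(fit$beta[["(Intercept)"]]), 1e-3)
  expect_lt(fit$sigma_u2, 1e-4)
})

test_that("AGQ estimates agree with the glmmTMB Laplace oracle", {
  skip_if_not_installed("glmmTMB")
  sim <- sim_glmm_trials(30, 2, beta = c(0.8, -3, -5, 0.3, -1, -0.4),
                         sigma_u2 = 0.25, seed = 12)
  fit <- fit_logistic_glmm(sim$trials, degree = 2, nodes = 1)
  agg <- srmotion:::aggregate_trials(sim$trials)
  df <- data.frame(k = agg$k, m = agg$m, sim$design$x[, -1],
                   pidf = factor(agg$participant_id), check.names = FALSE)
  fo <- stats::as.formula(paste(
    "cbind(k, m - k) ~",
    paste(sprintf("`%s`", colnames(sim$design$x)[-1]), collapse = "+"),
    "+ (1 | pidf)"
  ))
  ref <- glmmTMB::glmmTMB(fo, data = df, family = stats::binomial())
  expect_lt(max(abs(glmmTMB::fixef(ref)$cond - fit$beta)), 1e-3)
  expect_equal(fit$sigma_u2,
               unname(glmmTMB::VarCorr(ref)$cond$pidf[1]), tolerance = 1e-3)
  # Bernoulli log-likelihood differs from the binomial one by the constant
  # sum of log binomial coefficients
  expect_equal(fit$loglik,
               as.numeric(stats::logLik(ref)) - sum(lchoose(agg$m, agg$k)),
               tolerance = 1e-4)
  expect_lt(max(abs(sqrt(diag(fit$vcov)) -
                      sqrt(diag(stats::vcov(ref)$cond)))), 1e-2)
})

test_that("fixed effects are insensitive to the quadrature node count", {
  sim <- sim_glmm_trials(30, 2, beta = c(0.7, -3, -4, 0.2, -0.8, -0.3),
                         sigma_u2 = 0.3, seed = 13)
  f7 <- fit_logistic_glmm(sim$trials, degree = 2, nodes = 7)
  f25 <- fit_logistic_glmm(sim$trials, degree = 2, nodes = 25)
  expect_lt(max(abs(f7$beta - f25$beta)), 1e-3)
  expect_lt(abs(f7$sigma_u2 - f25$sigma_u2), 1e-3)
})

test_that("log-likelihood is non-decreasing in polynomial degree", {
  q <- simulate_quartic_cohort(40, seed = 5)
  lls <- vapply(1:4, function(d) {
    fit_logistic_glmm(q$trials, degree = d, nodes = 7)$loglik
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-4))
  # Table-1 bookkeeping: K = 2d + 3 (fixed effects + variance)
  ks <- vapply(1:4, function(d) {
    fit_logistic_glmm(q$trials, degree = d, nodes = 1)$K
  }, integer(1))
  expect_equal(ks, c(5L, 7L, 9L, 11L))
})

test_that("Type III Wald blocks match the quadratic-form oracle", {
  sim <- sim_glmm_trials(40, 2, beta = c(0.7, -3, -5, 0.4, -1.2, -0.5),
                         sigma_u2 = 0.2, seed = 14)
  fit <- fit_logistic_glmm(sim$trials, degree = 2, nodes = 7)
  w <- wald_type3(fit)
  expect_equal(w$term, c("dots", "age", "dots:age"))
  expect_equal(w$df, c(2L, 1L, 2L))
  # brute-force recomputation from beta and vcov
  for (tm in w$term) {
    idx <- which(fit$design$terms == tm)
    b <- fit$beta[idx]
    v <- fit$vcov[idx, idx, drop = FALSE]
    expect_equal(w$chisq[w$term == tm], drop(t(b) %*% solve(v) %*% b))
  }
  # single-coefficient term: chi-square is the squared z statistic
  i_age <- which(fit$design$terms == "age")
  expect_equal(w$chisq[w$term == "age"],
               (fit$beta[i_age] / sqrt(fit$vcov[i_age, i_age]))^2,
               ignore_attr = TRUE)
})

test_that("Wald tests are calibrated: power when on, level when off", {
  beta_on <- c(0.7, -4, -6, 0.3, -8, -5)
  beta_off <- c(0.7, -4, -6, 0.3, 0, 0)
  p_on <- p_off <- numeric(20)
  for (r in 1:20) {
    on <- sim_glmm_trials(80, 2, beta_on, sigma_u2 = 0.2, seed = 500 + r)
    off <- sim_glmm_trials(80, 2, beta_off, sigma_u2 = 0.2, seed = 700 + r)
    p_on[r] <- wald_type3(
      fit_logistic_glmm(on$trials, degree = 2, nodes = 7)
    )$p.value[3]
    p_off[r] <- wald_type3(
      fit_logistic_glmm(off$trials, degree = 2, nodes = 7)
    )$p.value[3]
  }
  expect_gte(mean(p_on < 0.05), 0.8)
  expect_lte(mean(p_off < 0.05), 0.1)
})

test_that("marginal R2 follows the Nakagawa formula", {
  null_fit <- fake_glmm(rep(0, 10))
  expect_equal(marginal_r2(null_fit), 0)

  # balanced 0/1 covariate with unit effect and no random variance
  agg <- tibble::tibble(participant_id = rep(1:2, each = 14),
                        age = rep(c(30, 60), each = 14),
                        n_dots = rep(sr_dot_levels(), 2),
                        k = 10L, m = 20L)
  design <- srmotion:::build_glmm_design(agg, 1)
  x01 <- rep(c(0, 1), each = 14)
  fit <- structure(
    list(beta = c(0, 1), sigma_u2 = 0, converged = TRUE,
         design = list(x = cbind(1, x01), terms = c("(Intercept)", "age"),
                       degree = 1),
         agg = agg),
    class = "sr_glmm"
  )
  expect_equal(marginal_r2(fit), 0.25 / (0.25 + pi^2 / 3), tolerance = 1e-12)

  # general recomputation from first principles
  f2 <- fake_glmm(c(0.5, -2, -3, 0.1, 0.4, 0.2, -1, -0.3, -0.2, 0.1),
                  sigma_u2 = 0.3)
  eta <- drop(f2$design$x %*% f2$beta)
  vf <- mean((eta - mean(eta))^2)
  expect_equal(marginal_r2(f2), vf / (vf + 0.3 + pi^2 / 3))
})

test_that("part R2 isolates term contributions", {
  q <- simulate_quartic_cohort(80, seed = 6)
  fit <- fit_logistic_glmm(q$trials, degree = 4, nodes = 7)
  dr_dots <- part_r2(fit, "dots")
  dr_age <- part_r2(fit, "age")
  dr_int <- part_r2(fit, "dots:age")
  # numerosity dominates, as in the generative surface
  expect_gt(dr_dots, dr_age)
  expect_gt(dr_dots, 0.001)
  # a null term contributes approximately nothing
  null_sim <- sim_glmm_trials(50, 2, c(0.7, -4, -6, 0, 0, 0),
                              sigma_u2 = 0.2, seed = 15)
  nf <- fit_logistic_glmm(null_sim$trials, degree = 2, nodes = 7)
  expect_lt(abs(part_r2(nf, "age")), 0.005)
})

test_that("population predictions reconstruct the linear predictor", {
  beta <- c(0.5, -2, -3, 0.1, 0.4, 0.2, -1, -0.3, -0.2, 0.1)
  fit <- fake_glmm(beta)
  grid <- c(25, 80, 250, 800, 1900)
  pred <- predict_accuracy(fit, age = 40, n_dots = grid)
  # manual matrix reconstruction
  pb <- poly_eval(fit$design$poly, log(grid))
  a_s <- (40 - fit$design$age_meta$center) / fit$design$age_meta$spread
  x_new <- cbind(1, pb, a_s, pb * a_s)
  expect_equal(pred$eta, drop(x_new %*% beta))
  expect_equal(pred$p_correct, plogis(pred$eta))

  # intercept-only null model predicts chance
  pred0 <- predict_accuracy(fake_glmm(rep(0, 10)), 40, grid)
  expect_true(all(pred0$p_correct == 0.5))

  # a monotone degree-1 surface yields a monotone curve
  f1 <- fake_glmm(c(0.2, -3, 0, 0), degree = 1)
  p1 <- predict_accuracy(f1, 40, sr_dot_levels())
  expect_true(all(diff(p1$p_correct) < 0))
  expect_warning(predict_accuracy(fit, 40, c(10, 100)), "range")
})

test_that("peak location finds the argmax of the predicted curve", {
  expect_false(peak_location(fake_glmm(c(0.2, -3, 0, 0), degree = 1),
                             40)$applicable)

  # pure concave quadratic in log dots: compare with a continuous optimizer
  beta <- c(0.5, 0.3, -4, 0, 0, 0)
  fit <- fake_glmm(beta, degree = 2)
  pk <- peak_location(fit, 40)
  oracle <- optimize(function(ln) {
    pb <- poly_eval(fit$design$poly, ln)
    plogis(beta[1] + pb[1] * beta[2] + pb[2] * beta[3])
  }, c(log(20), log(2000)), maximum = TRUE)$maximum
  step <- (log(2000) - log(20)) / 2000
  expect_lt(abs(pk$peak_log_n - oracle), 2 * step)

  # known quartic with an interior maximum
  beta4 <- c(0.5, 1, -5, -0.5, -1, 0, 0, 0, 0, 0)
  fit4 <- fake_glmm(beta4)
  pk4 <- peak_location(fit4, 40)
  oracle4 <- optimize(function(ln) {
    pb <- poly_eval(fit4$design$poly, ln)
    plogis(beta4[1] + sum(pb * beta4[2:5]))
  }, c(log(20), log(2000)), maximum = TRUE)$maximum
  expect_lt(abs(pk4$peak_log_n - oracle4), 2 * step)
})

test_that("quartic evaluation reproduces the printed model predictions", {
  # predictions at the covariate origin for the two reference ages
  expect_equal(evaluate_quartic(c(0.76, -0.21, -0.35, -0.032, 0.021), 0),
               0.76)
  expect_equal(evaluate_quartic(c(0.75, -0.5, -0.38, -0.18, 0.031), 0),
               0.75)
  expect_equal(evaluate_quartic(rep(0, 5), 3), 0)
  # Horner evaluation equals the direct power expansion
  set.seed(16)
  co <- rnorm(5); xs <- rnorm(7)
  expect_equal(evaluate_quartic(co, xs),
               co[1] + co[2] * xs + co[3] * xs^2 + co[4] * xs^3 +
                 co[5] * xs^4)
})

test_that("age dichotomisation splits at the documented boundary", {
  expect_equal(as.character(dichotomize_age(c(35, 65, 50, 18, 82))),
               c("younger", "older", "older", "younger", "older"))
  fitg <- fit_logistic_glmm(simulate_quartic_cohort(30, seed = 8)$trials,
                            degree = 2, age_mode = "group", nodes = 7)
  expect_equal(fitg$design$age_meta$mode, "group")
  pg <- predict_accuracy(fitg, "younger")
  expect_equal(nrow(pg), 14)
  expect_error(predict_accuracy(fitg, "ancient"), "younger")
})

test_that("simulated residuals are uniform under the fitted model", {
  q <- simulate_quartic_cohort(40, seed = 9)
  fit <- fit_logistic_glmm(q$trials, degree = 4, nodes = 7)
  ks <- simulated_residual_ks(fit, n_sim = 200, seed = 1)
  expect_gte(ks$statistic, 0)
  expect_lte(ks$statistic, 1)
  expect_true(all(ks$residuals >= 0 & ks$residuals <= 1))

  # calibration: refreshing the data from the fitted model itself gives
  # roughly uniform KS p-values. With a zero variance component the rows
  # are independent, the regime in which the KS test is exactly calibrated
  # (shared random intercepts correlate residuals within participant and
  # overdisperse D, which is why the check fixes sigma_u2 = 0).
  null_sim <- sim_glmm_trials(40, 2, c(0.6, -4, -6, 0.2, -1, -0.4),
                              sigma_u2 = 0, seed = 77)
  fit0 <- fit_logistic_glmm(null_sim$trials, degree = 2, nodes = 7,
                            fix_sigma_u2 = 0)
  pvals <- vapply(1:60, function(r) {
    fit2 <- fit0
    sim_tr <- simulate_glmm(fit0, seed = 524000 + r)
    fit2$agg <- srmotion:::aggregate_trials(sim_tr)
    simulated_residual_ks(fit2, n_sim = 150, seed = 881000 + r)$p.value
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("misspecified fits show larger residual deviations", {
  # mean-structure misfit, isolated from random-intercept absorption by
  # generating without between-participant variance
  worse <- 0
  for (r in 1:10) {
    q <- simulate_quartic_cohort(100, sigma_u2 = 0, seed = 40 + r)
    f4 <- fit_logistic_glmm(q$trials, degree = 4, nodes = 7)
    f1 <- fit_logistic_glmm(q$trials, degree = 1, nodes = 7)
    d4 <- simulated_residual_ks(f4, n_sim = 200, seed = r)$statistic
    d1 <- simulated_residual_ks(f1, n_sim = 200, seed = r)$statistic
    worse <- worse + (d1 > d4)
  }
  expect_gte(worse, 10)
})
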