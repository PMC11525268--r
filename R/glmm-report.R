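# Reporting on fitted GLMMs: Type III Wald tests, Nakagawa marginal and
# part R^2, population-level predictions, peak extraction, and the
# simulation-based residual check.

#' Type III Wald chi-square tests
#'
#' For each fixed-effect term block b with covariance V_b, the statistic is
#' `b' V_b^{-1} b` on as many degrees of freedom as the block has
#' coefficients. Factor contrasts are sum-to-zero by construction of the
#' design, which makes the tests invariant to factor-level ordering.
#'
#' @param fit an `sr_glmm` from [fit_logistic_glmm()].
#' @return tibble with columns `term`, `chisq`, `df`, `p.value`.
#' @export
wald_type3 <- function(fit) {
  stopifnot(inherits(fit, "sr_glmm"))
  if (!fit$converged) stop_domain("fit did not converge")
  if (any(!is.finite(fit$vcov))) stop_domain("singular coefficient covariance")
  terms <- setdiff(unique(fit$design$terms), "(Intercept)")
  rows <- lapply(terms, function(tm) {
    idx <- which(fit$design$terms == tm)
    b <- fit$beta[idx]
    v <- fit$vcov[idx, idx, drop = FALSE]
    chisq <- tryCatch(drop(t(b) %*% solve(v) %*% b),
                      error = function(e) NA_real_)
    tibble::tibble(
      term = tm, chisq = chisq, df = length(idx),
      p.value = pchisq(chisq, length(idx), lower.tail = FALSE)
    )
  })
  dplyr::bind_rows(rows)
}

#' Nakagawa marginal R-squared
#'
#' Fixed-effect variance over total latent variance for a logit model:
#' `var(X beta) / (var(X beta) + sigma_u2 + pi^2 / 3)`, with the
#' fixed-effect variance taken over Bernoulli trials (aggregated rows
#' weighted by their trial counts).
#'
#' @param fit an `sr_glmm`.
#' @return a number in `[0, 1]`.
#' @export
marginal_r2 <- function(fit) {
  stopifnot(inherits(fit, "sr_glmm"))
  eta <- drop(fit$design$x %*% fit$beta)
  w <- fit$agg$m
  mu_w <- sum(w * eta) / sum(w)
  var_fix <- sum(w * (eta - mu_w)^2) / sum(w)
  var_fix / (var_fix + fit$sigma_u2 + pi^2 / 3)
}

#' Part (semipartial) R-squared of a term
#'
#' The drop in [marginal_r2()] when the term is removed. The reference
#' model is the full model for the interaction term, and the
#' interaction-free model for the two main effects (main-effect shares are
#' assessed in a model without the interaction).
#'
#' @param fit the full `sr_glmm`.
#' @param term one of `"dots"`, `"age"`, `"dots:age"`.
#' @return a number (can be slightly negative through refitting noise on
#'   null terms).
#' @export
part_r2 <- function(fit, term = c("dots", "age", "dots:age")) {
  stopifnot(inherits(fit, "sr_glmm"))
  term <- match.arg(term)
  ref <- if (term == "dots:age") fit else drop_glmm_terms(fit, "dots:age")
  reduced_drop <- if (term == "dots:age") {
    "dots:age"
  } else {
    c("dots:age", term)
  }
  reduced <- drop_glmm_terms(fit, reduced_drop)
  if (!ref$converged || !reduced$converged) {
    stop_domain("part_r2 refit did not converge")
  }
  marginal_r2(ref) - marginal_r2(reduced)
}

# Refit with the named term blocks removed from the design.
drop_glmm_terms <- function(fit, drop_terms) {
  keep <- !(fit$design$terms %in% drop_terms)
  design <- fit$design
  design$x <- design$x[, keep, drop = FALSE]
  design$terms <- design$terms[keep]
  fit_glmm_design(fit$agg, design, nodes = fit$nodes)
}

#' Population-level accuracy predictions
#'
#' The fixed-effects linear predictor (random intercept at zero) mapped
#' through the inverse logit, with new dot numerosities projected through
#' the stored orthogonal-polynomial recurrence and age through the stored
#' scaling.
#'
#' @param fit an `sr_glmm`.
#' @param age age in years (continuous fit) or `"younger"`/`"older"`
#'   (group fit).
#' @param n_dots dot-numerosity grid.
#' @return tibble with columns `n_dots`, `age`, `eta`, `p_correct`.
#' @export
predict_accuracy <- function(fit, age, n_dots = sr_dot_levels()) {
  stopifnot(inherits(fit, "sr_glmm"))
  if (any(n_dots < 20 * (1 - 1e-9) | n_dots > 2000 * (1 + 1e-9))) {
    warning("predicting outside the fitted 20..2000 dot range")
  }
  pb <- poly_eval(fit$design$poly, log(n_dots))
  meta <- fit$design$age_meta
  age_val <- if (meta$mode == "continuous") {
    (age - meta$center) / meta$spread
  } else {
    if (!age %in% c("younger", "older")) {
      stop_domain('group fit: age must be "younger" or "older"')
    }
    if (age == "younger") 1 else -1
  }
  x_new <- cbind(1, pb, age_val, pb * age_val)
  # internal refits drop whole term blocks; align columns by term label
  full_terms <- c("(Intercept)", rep("dots", fit$design$degree), "age",
                  rep("dots:age", fit$design$degree))
  x_new <- x_new[, full_terms %in% fit$design$terms, drop = FALSE]
  eta <- drop(x_new %*% fit$beta)
  tibble::tibble(
    n_dots = n_dots,
    age = if (meta$mode == "continuous") age else as.character(age),
    eta = eta,
    p_correct = plogis(eta)
  )
}

#' Accuracy peak location
#'
#' The dot numerosity maximising the fixed-effects accuracy prediction on a
#' dense log-spaced grid over the modelled range; ties resolve to the
#' smaller level. Peak extraction needs curvature, so fits of degree < 2
#' return an NA peak with `applicable = FALSE`.
#'
#' @param fit an `sr_glmm`.
#' @param age as in [predict_accuracy()].
#' @param grid_size number of grid points.
#' @param range dot-numerosity range to search.
#' @return tibble with `age`, `peak_n_dots`, `peak_log_n`, `p_at_peak`,
#'   `applicable`.
#' @export
peak_location <- function(fit, age, grid_size = 2001, range = c(20, 2000)) {
  stopifnot(inherits(fit, "sr_glmm"))
  if (fit$design$degree < 2) {
    return(tibble::tibble(
      age = age, peak_n_dots = NA_real_, peak_log_n = NA_real_,
      p_at_peak = NA_real_, applicable = FALSE
    ))
  }
  grid <- exp(seq(log(range[1]), log(range[2]), length.out = grid_size))
  pred <- predict_accuracy(fit, age, grid)
  i <- which.max(pred$p_correct) # first maximum = smaller level on ties
  tibble::tibble(
    age = age,
    peak_n_dots = grid[i],
    peak_log_n = log(grid[i]),
    p_at_peak = pred$p_correct[i],
    applicable = TRUE
  )
}

#' Evaluate a quartic polynomial
#'
#' `c0 + c1 x + c2 x^2 + c3 x^3 + c4 x^4`, by Horner's rule.
#'
#' @param coeffs numeric vector of 5 coefficients, constant first.
#' @param x evaluation points.
#' @return numeric vector.
#' @export
#' @examples
#' evaluate_quartic(c(0.76, -0.21, -0.35, -0.032, 0.021), 0) # 0.76
evaluate_quartic <- function(coeffs, x) {
  stopifnot(length(coeffs) == 5)
  ((((coeffs[5] * x) + coeffs[4]) * x + coeffs[3]) * x + coeffs[2]) * x +
    coeffs[1]
}

#' Simulation-based uniformity check of GLMM residuals
#'
#' Simulates `n_sim` response tables from the fitted model (fresh random
#' intercepts each time), computes a randomized quantile (PIT) residual for
#' every observed count - its jittered rank within its simulated
#' distribution - and tests the residuals against Uniform(0, 1) with a
#' one-sample Kolmogorov-Smirnov test. A well-specified model yields
#' approximately uniform residuals.
#'
#' @param fit an `sr_glmm`.
#' @param n_sim number of simulated datasets.
#' @param seed integer seed.
#' @return list with `statistic` (KS D), `p.value`, and the `residuals`.
#' @export
simulated_residual_ks <- function(fit, n_sim = 250, seed = NULL) {
  stopifnot(inherits(fit, "sr_glmm"))
  if (!fit$converged) stop_domain("fit did not converge")
  agg <- fit$agg
  eta_fix <- drop(fit$design$x %*% fit$beta)
  pid <- match(agg$participant_id, unique(agg$participant_id))
  n_part <- max(pid)
  n_row <- nrow(agg)
  sims <- with_seed(seed, {
    sim <- matrix(0L, n_row, n_sim)
    for (s in seq_len(n_sim)) {
      u <- rnorm(n_part, 0, sqrt(fit$sigma_u2))
      p <- plogis(eta_fix + u[pid])
      sim[, s] <- rbinom(n_row, agg$m, p)
    }
    lt <- rowSums(sim < agg$k)
    eq <- rowSums(sim == agg$k)
    (lt + runif(n_row) * (eq + 1)) / (n_sim + 1)
  })
  ks <- suppressWarnings(ks.test(sims, "punif"))
  list(
    statistic = unname(ks$statistic),
    p.value = ks$p.value,
    residuals = sims
  )
}

#' Simulate a response table from a fitted GLMM
#'
#' Parametric simulation used by recovery experiments: draws fresh random
#' intercepts and binomial counts at the fitted (or supplied) parameters,
#' returning a trial-level tibble compatible with [fit_logistic_glmm()].
#'
#' @param fit an `sr_glmm` providing the design.
#' @param beta fixed effects (default: the fitted ones).
#' @param sigma_u2 random-intercept variance (default: fitted).
#' @param seed integer seed.
#' @return trial-level tibble with columns `participant_id`, `age`,
#'   `n_dots`, `correct`.
#' @export
simulate_glmm <- function(fit, beta = fit$beta, sigma_u2 = fit$sigma_u2,
                          seed = NULL) {
  agg <- fit$agg
  eta_fix <- drop(fit$design$x %*% beta)
  pid <- match(agg$participant_id, unique(agg$participant_id))
  with_seed(seed, {
    u <- rnorm(max(pid), 0, sqrt(sigma_u2))
    p <- plogis(eta_fix + u[pid])
    k_new <- rbinom(nrow(agg), agg$m, p)
    tidyr::uncount(
      tibble::tibble(
        participant_id = agg$participant_id,
        age = agg$age,
        n_dots = agg$n_dots,
        k_new = k_new,
        m = agg$m
      ),
      weights = .data$m, .id = "rep"
    ) |>
      dplyr::group_by(.data$participant_id, .data$n_dots) |>
      dplyr::mutate(correct = dplyr::row_number() <= .data$k_new) |>
      dplyr::ungroup() |>
      dplyr::select("participant_id", "age", "n_dots", "correct")
  })
}
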