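# Binomial random-intercept GLMM, fitted by maximum marginal likelihood
# with adaptive Gauss-Hermite quadrature.
#
# Trial-level Bernoulli data are aggregated to binomial counts per
# participant x dot-numerosity level (exact for the likelihood, since
# trials are conditionally independent given the random intercept). The
# reported log-likelihood is the Bernoulli-trial log-likelihood (no
# binomial coefficients), and n_obs is the number of Bernoulli trials, so
# information criteria are on the trial scale.
#
# Fixed effects: orthogonal polynomials of log dot numerosity up to the
# requested degree, scaled age (or a sum-to-zero age-group contrast), and
# the polynomial x age interactions. One Gaussian random intercept per
# participant.

# Gauss-Hermite nodes/weights for weight function exp(-z^2) (Golub-Welsch).
gauss_hermite <- function(n) {
  if (n == 1) {
    return(list(nodes = 0, weights = sqrt(pi)))
  }
  i <- seq_len(n - 1)
  jac <- matrix(0, n, n)
  jac[cbind(i, i + 1)] <- sqrt(i / 2)
  jac[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(jac, symmetric = TRUE)
  ord <- order(e$values)
  list(
    nodes = e$values[ord],
    weights = sqrt(pi) * (e$vectors[1, ord])^2
  )
}

#' Split ages at a cut point
#'
#' Ages strictly below the cut are "younger", ages at or above it "older"
#' (the boundary age goes to the older group).
#'
#' @param age numeric vector of ages.
#' @param cut cut point in years.
#' @return factor with levels `younger`, `older`.
#' @export
#' @examples
#' dichotomize_age(c(35, 50, 65))
dichotomize_age <- function(age, cut = 50) {
  factor(ifelse(age < cut, "younger", "older"),
         levels = c("younger", "older"))
}

# Aggregate trial-level data to binomial counts per participant x level.
aggregate_trials <- function(trials) {
  needed <- c("participant_id", "n_dots", "correct", "age")
  if (!all(needed %in% names(trials))) {
    stop_domain("trials must have columns %s", paste(needed, collapse = ", "))
  }
  trials |>
    dplyr::group_by(.data$participant_id, .data$age, .data$n_dots) |>
    dplyr::summarise(
      k = sum(.data$correct), m = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$participant_id, .data$n_dots)
}

# Build the fixed-effects design for aggregated data. Scaling and the
# polynomial basis are computed on the trial-level expansion (each row
# weighted by its trial count), so they match a fit on raw Bernoulli rows.
build_glmm_design <- function(agg, degree, age_mode = "continuous",
                              age_cut = 50) {
  x_log <- log(agg$n_dots)
  op <- orthogonal_poly(rep(x_log, agg$m), degree)
  pb <- poly_eval(op, x_log)
  if (age_mode == "continuous") {
    zs <- zscale(rep(agg$age, agg$m))
    age_col <- (agg$age - zs$center) / zs$spread
    age_meta <- list(mode = "continuous", center = zs$center,
                     spread = zs$spread)
  } else {
    grp <- dichotomize_age(agg$age, age_cut)
    age_col <- ifelse(grp == "younger", 1, -1)
    age_meta <- list(mode = "group", cut = age_cut)
  }
  inter <- pb * age_col
  colnames(inter) <- paste0(colnames(pb), ":age")
  x <- cbind(`(Intercept)` = 1, pb, age = age_col, inter)
  terms <- c("(Intercept)", rep("dots", degree), "age",
             rep("dots:age", degree))
  list(x = x, terms = terms, poly = op, age_meta = age_meta,
       degree = degree)
}

# Marginal Bernoulli log-likelihood by adaptive Gauss-Hermite quadrature.
# Rows must be sorted by participant (aggregate_trials guarantees this);
# per-participant sums then reduce to cumsum differences over row blocks.
# `cache$u` carries participant modes between calls for warm starts.
glmm_loglik <- function(par, x, k, m, pid, gh, cache = NULL) {
  p_fix <- ncol(x)
  beta <- par[seq_len(p_fix)]
  sigma <- exp(par[p_fix + 1])
  eta_fix <- drop(x %*% beta)
  n_part <- pid[length(pid)]
  ends <- which(c(pid[-1] != pid[-length(pid)], TRUE))
  starts_minus1 <- c(0L, ends[-n_part])
  group_sum <- function(v) {
    cs <- cumsum(v)
    cs[ends] - c(0, cs[starts_minus1[-1]])
  }
  u <- if (!is.null(cache) && !is.null(cache$u) &&
           length(cache$u) == n_part) cache$u else numeric(n_part)
  k_sum <- group_sum(k)
  # conditional log-likelihood summed per participant; stable log1p(exp())
  cond_by_part <- function(u_row) {
    eta <- eta_fix + u_row[pid]
    eta_c <- pmin(eta, 30)
    log1pe <- log1p(exp(eta_c)) + (eta - eta_c)
    group_sum(k * eta - m * log1pe)
  }
  # Newton for the posterior mode of each random intercept (concave target)
  inv_s2 <- 1 / sigma^2
  hess <- NULL
  for (it in 1:50) {
    pr <- plogis(eta_fix + u[pid])
    grad <- k_sum - group_sum(m * pr) - u * inv_s2
    hess <- -group_sum(m * pr * (1 - pr)) - inv_s2
    step <- pmax(pmin(grad / hess, 3), -3)
    u <- u - step
    if (max(abs(step)) < 1e-9) break
  }
  if (!is.null(cache)) cache$u <- u
  tau <- 1 / sqrt(-hess)
  nq <- length(gh$nodes)
  log_w <- log(gh$weights) + gh$nodes^2
  logint <- matrix(0, n_part, nq)
  for (q in seq_len(nq)) {
    u_q <- u + sqrt(2) * tau * gh$nodes[q]
    logint[, q] <- log_w[q] + cond_by_part(u_q) - u_q^2 / (2 * sigma^2)
  }
  row_max <- do.call(pmax, as.data.frame(logint))
  log_li <- row_max + log(rowSums(exp(logint - row_max))) +
    log(sqrt(2) * tau) - log(sigma * sqrt(2 * pi))
  sum(log_li)
}

# Log-likelihood together with its gradient. The gradient uses Fisher's
# identity - the expected complete-data score under the posterior of the
# random intercepts - evaluated on the same quadrature points, which is
# exact up to the quadrature error (negligible from ~7 nodes up for
# binomial counts of this size).
glmm_loglik_grad <- function(par, x, k, m, pid, gh, cache = NULL) {
  p_fix <- ncol(x)
  beta <- par[seq_len(p_fix)]
  sigma <- exp(par[p_fix + 1])
  eta_fix <- drop(x %*% beta)
  n_part <- pid[length(pid)]
  ends <- which(c(pid[-1] != pid[-length(pid)], TRUE))
  starts_minus1 <- c(0L, ends[-n_part])
  group_sum <- function(v) {
    cs <- cumsum(v)
    cs[ends] - c(0, cs[starts_minus1[-1]])
  }
  u <- if (!is.null(cache) && !is.null(cache$u) &&
           length(cache$u) == n_part) cache$u else numeric(n_part)
  k_sum <- group_sum(k)
  inv_s2 <- 1 / sigma^2
  hess <- NULL
  for (it in 1:50) {
    pr <- plogis(eta_fix + u[pid])
    grad <- k_sum - group_sum(m * pr) - u * inv_s2
    hess <- -group_sum(m * pr * (1 - pr)) - inv_s2
    step <- pmax(pmin(grad / hess, 3), -3)
    u <- u - step
    if (max(abs(step)) < 1e-9) break
  }
  if (!is.null(cache)) cache$u <- u
  tau <- 1 / sqrt(-hess)
  nq <- length(gh$nodes)
  log_w <- log(gh$weights) + gh$nodes^2
  logint <- matrix(0, n_part, nq)
  resid_q <- matrix(0, length(k), nq)
  u_sq <- matrix(0, n_part, nq)
  for (q in seq_len(nq)) {
    u_q <- u + sqrt(2) * tau * gh$nodes[q]
    eta <- eta_fix + u_q[pid]
    eta_c <- pmin(eta, 30)
    log1pe <- log1p(exp(eta_c)) + (eta - eta_c)
    logint[, q] <- log_w[q] + group_sum(k * eta - m * log1pe) -
      u_q^2 / (2 * sigma^2)
    resid_q[, q] <- k - m * plogis(eta)
    u_sq[, q] <- u_q^2
  }
  row_max <- do.call(pmax, as.data.frame(logint))
  wpost <- exp(logint - row_max)
  denom <- rowSums(wpost)
  wpost <- wpost / denom
  log_li <- row_max + log(denom) + log(sqrt(2) * tau) -
    log(sigma * sqrt(2 * pi))
  grad_beta <- drop(crossprod(x, rowSums(resid_q * wpost[pid, ])))
  grad_zeta <- sum(rowSums(u_sq * wpost) * inv_s2 - 1)
  list(value = sum(log_li), grad = c(grad_beta, grad_zeta))
}

#' Fit the binomial random-intercept GLMM
#'
#' Maximises the marginal likelihood of a logit model with a per-participant
#' Gaussian random intercept, integrating each participant's likelihood by
#' adaptive Gauss-Hermite quadrature (`nodes = 1` gives the Laplace
#' approximation). The variance parameter is profiled on the log-SD scale
#' with a soft floor, so a boundary estimate of zero is admissible.
#'
#' @param trials trial-level tibble with columns `participant_id`, `age`,
#'   `n_dots`, `correct`.
#' @param degree polynomial degree for log dot numerosity, 1 to 4.
#' @param age_mode `"continuous"` (scaled age) or `"group"` (sum-to-zero
#'   younger/older contrast).
#' @param age_cut cut for `age_mode = "group"`.
#' @param nodes number of quadrature nodes (default 15).
#' @param fix_sigma_u2 optionally hold the random-intercept variance at a
#'   fixed value instead of estimating it (0 reduces the model to plain
#'   logistic regression).
#' @return object of class `sr_glmm`: `beta`, `vcov` (fixed effects,
#'   observed information), `sigma_u2`, `loglik`, `K`, `n_obs`,
#'   `converged`, `design` metadata, and the aggregated data.
#' @export
fit_logistic_glmm <- function(trials, degree = 4,
                              age_mode = c("continuous", "group"),
                              age_cut = 50, nodes = 15,
                              fix_sigma_u2 = NULL) {
  age_mode <- match.arg(age_mode)
  agg <- aggregate_trials(trials)
  if (length(unique(agg$participant_id)) < 2) {
    stop_domain("need >= 2 participants")
  }
  if (sum(agg$k) == 0 || sum(agg$k) == sum(agg$m)) {
    stop_domain("responses are all failures or all successes (separation)")
  }
  design <- build_glmm_design(agg, degree, age_mode, age_cut)
  fit_glmm_design(agg, design, nodes = nodes, fix_sigma_u2 = fix_sigma_u2)
}

# Fitter shared by the public interface and internal refits (part R2).
fit_glmm_design <- function(agg, design, nodes = 15,
                            fix_sigma_u2 = NULL) {
  x <- design$x
  k <- agg$k
  m <- agg$m
  pid <- match(agg$participant_id, unique(agg$participant_id))
  gh <- gauss_hermite(nodes)
  cache <- new.env(parent = emptyenv())
  negll <- function(par) -glmm_loglik(par, x, k, m, pid, gh, cache)
  # fn/gr pair sharing one evaluation per parameter value
  last <- new.env(parent = emptyenv())
  fn_gr <- function(par) {
    if (is.null(last$par) || !identical(last$par, par)) {
      res <- glmm_loglik_grad(par, x, k, m, pid, gh, cache)
      last$par <- par
      last$value <- -res$value
      last$grad <- -res$grad
    }
    invisible(NULL)
  }
  fn <- function(par) {
    fn_gr(par)
    last$value
  }
  gr <- function(par) {
    fn_gr(par)
    last$grad
  }

  start_glm <- glm.fit(x, k / m, weights = m, family = binomial())
  start <- c(coef(start_glm), log(0.3))
  lower <- c(rep(-Inf, ncol(x)), log(1e-8))
  upper <- c(rep(Inf, ncol(x)), log(20))
  if (!is.null(fix_sigma_u2)) {
    zeta_fix <- log(sqrt(max(fix_sigma_u2, 1e-16)))
    lower[length(lower)] <- zeta_fix
    upper[length(upper)] <- zeta_fix
    start[length(start)] <- zeta_fix
  }
  ctrl <- list(rel.tol = 1e-10, x.tol = 1e-8, iter.max = 500,
               eval.max = 5000)
  use_grad <- nodes >= 7 # gradient is quadrature-exact only with enough nodes
  opt <- if (use_grad) {
    nlminb(start, fn, gradient = gr, lower = lower, upper = upper,
           control = ctrl)
  } else {
    nlminb(start, negll, lower = lower, upper = upper, control = ctrl)
  }
  par <- opt$par
  loglik <- -opt$objective
  # declare convergence from the score itself, not the optimizer code:
  # nlminb's "false convergence" is common at flat optima of large-n
  # likelihoods. Scale the gradient tolerance with the observation count.
  score <- glmm_loglik_grad(par, x, k, m, pid, gh, cache)$grad
  converged <- opt$convergence == 0 ||
    max(abs(score)) < 1e-4 * sum(m)

  # observed information via central-difference Hessian
  p_all <- length(par)
  h <- 1e-4 * pmax(abs(par), 1)
  hess <- matrix(0, p_all, p_all)
  f0 <- negll(par) # re-evaluate: must be exactly consistent with fp/fm
  fp <- numeric(p_all)
  fm <- numeric(p_all)
  for (i in seq_len(p_all)) {
    ei <- replace(numeric(p_all), i, h[i])
    fp[i] <- negll(par + ei)
    fm[i] <- negll(par - ei)
    hess[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  for (i in seq_len(p_all - 1)) {
    for (j in (i + 1):p_all) {
      ei <- replace(numeric(p_all), i, h[i])
      ej <- replace(numeric(p_all), j, h[j])
      fpp <- negll(par + ei + ej)
      fmm <- negll(par - ei - ej)
      hess[i, j] <- hess[j, i] <-
        (fpp - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + fmm) / (2 * h[i] * h[j])
    }
  }
  idx_beta <- seq_len(ncol(x))
  vcov_beta <- tryCatch(
    solve(hess)[idx_beta, idx_beta, drop = FALSE],
    error = function(e) {
      # variance parameter at its boundary: fall back to the beta block
      tryCatch(solve(hess[idx_beta, idx_beta, drop = FALSE]),
               error = function(e2) matrix(NA_real_, ncol(x), ncol(x)))
    }
  )
  dimnames(vcov_beta) <- list(colnames(x), colnames(x))

  sigma_u <- exp(unname(par[p_all]))
  structure(
    list(
      beta = setNames(par[idx_beta], colnames(x)),
      vcov = vcov_beta,
      sigma_u2 = sigma_u^2,
      loglik = loglik,
      K = ncol(x) + 1L,
      n_obs = sum(m),
      converged = converged,
      opt_message = opt$message,
      score_norm = max(abs(score)),
      design = design,
      agg = agg,
      nodes = nodes
    ),
    class = "sr_glmm"
  )
}

#' @export
print.sr_glmm <- function(x, ...) {
  cat(sprintf(
    "<sr_glmm> degree-%d logit GLMM, age %s; %d participants, %d trials\n",
    x$design$degree, x$design$age_meta$mode,
    length(unique(x$agg$participant_id)), x$n_obs
  ))
  cat(sprintf("  logLik %.2f  K %d  sigma_u2 %.4f  converged: %s\n",
              x$loglik, x$K, x$sigma_u2, x$converged))
  invisible(x)
}

#' @method tidy sr_glmm
#' @export
tidy.sr_glmm <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = se,
    statistic = unname(x$beta) / se,
    p.value = 2 * pnorm(abs(unname(x$beta)) / se, lower.tail = FALSE)
  )
}

#' @method glance sr_glmm
#' @export
glance.sr_glmm <- function(x, ...) {
  tibble::tibble(
    nobs = x$n_obs,
    logLik = x$loglik,
    K = x$K,
    AICc = aicc(x$loglik, x$K, x$n_obs),
    sigma_u2 = x$sigma_u2,
    converged = x$converged
  )
}
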