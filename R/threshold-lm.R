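# Linear model for log coherence thresholds.
#
# One row per kept participant: ln(threshold) modelled on scaled age, the
# staircase-density group (sum-to-zero coded: 100 dots = +1, 400 dots = -1)
# and their interaction. F tests come from sequential model reduction;
# partial eta^2 is SS_term / (SS_term + SS_resid); group marginal means are
# evaluated at the mean age and back-transformed with exp().

#' Fit the log-threshold linear model
#'
#' @param participants tibble with columns `age`, `group_dots` (100/400)
#'   and `threshold_pct`; normally the kept rows of a dataset.
#' @return object of class `sr_threshold_lm` with elements `coefficients`,
#'   `vcov`, `sigma2`, `anova` (tibble: term, df, ss, f, p, partial_eta2),
#'   `marginal_means` (tibble: group_dots, ln_mean, se, mean_pct),
#'   `age_scale`, `n`.
#' @export
fit_threshold_lm <- function(participants) {
  needed <- c("age", "group_dots", "threshold_pct")
  if (!all(needed %in% names(participants))) {
    stop_domain("participants must have columns %s",
                paste(needed, collapse = ", "))
  }
  if (min(table(participants$group_dots)) < 2 ||
      length(unique(participants$group_dots)) != 2) {
    stop_domain("need >= 2 participants in each of the two groups")
  }
  y <- log(participants$threshold_pct)
  zs <- zscale(participants$age)
  g <- ifelse(participants$group_dots == 100, 1, -1)
  n <- length(y)

  design <- cbind(
    `(Intercept)` = 1, age_scaled = zs$scaled, group = g,
    `age_scaled:group` = zs$scaled * g
  )
  qr_full <- qr(design)
  if (qr_full$rank < ncol(design)) stop_domain("singular design")
  beta <- qr.coef(qr_full, y)
  resid <- y - design %*% beta
  rss_full <- sum(resid^2)
  df_res <- n - ncol(design)
  sigma2 <- rss_full / df_res
  xtx_inv <- chol2inv(qr.R(qr_full))
  vcov <- sigma2 * xtx_inv
  dimnames(vcov) <- list(colnames(design), colnames(design))

  # sequential (Type I) sums of squares over the term order
  rss_at <- vapply(1:4, function(k) {
    sub <- design[, seq_len(k), drop = FALSE]
    sum(qr.resid(qr(sub), y)^2)
  }, numeric(1))
  ss_terms <- -diff(rss_at)
  terms <- c("age_scaled", "group", "age_scaled:group")
  f_stat <- (ss_terms / 1) / sigma2
  anova_tbl <- tibble::tibble(
    term = terms,
    df1 = 1L,
    df2 = df_res,
    ss = ss_terms,
    f = if (rss_full > 0) f_stat else NA_real_,
    p = if (rss_full > 0) stats::pf(f_stat, 1, df_res, lower.tail = FALSE)
        else NA_real_,
    partial_eta2 = ifelse(ss_terms + rss_full > 0,
                          ss_terms / (ss_terms + rss_full), 0)
  )

  # marginal means per group at the mean age (age_scaled = 0)
  mm_rows <- rbind(
    c(1, 0, 1, 0), # 100-dot group
    c(1, 0, -1, 0) # 400-dot group
  )
  ln_mean <- drop(mm_rows %*% beta)
  mm_se <- sqrt(diag(mm_rows %*% vcov %*% t(mm_rows)))
  marginal_means <- tibble::tibble(
    group_dots = c(100L, 400L),
    ln_mean = ln_mean,
    se = mm_se,
    mean_pct = exp(ln_mean)
  )

  structure(
    list(
      coefficients = setNames(drop(beta), colnames(design)),
      vcov = vcov, sigma2 = sigma2, df_residual = df_res,
      anova = anova_tbl, marginal_means = marginal_means,
      age_scale = zs[c("center", "spread")], n = n
    ),
    class = "sr_threshold_lm"
  )
}

#' @export
print.sr_threshold_lm <- function(x, ...) {
  cat(sprintf("<sr_threshold_lm> n=%d  ln(threshold) ~ age_scaled * group\n",
              x$n))
  print(x$anova)
  print(x$marginal_means)
  invisible(x)
}

#' @method tidy sr_threshold_lm
#' @export
tidy.sr_threshold_lm <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = sqrt(diag(x$vcov)),
    statistic = unname(x$coefficients) / sqrt(diag(x$vcov)),
    p.value = 2 * stats::pt(
      abs(unname(x$coefficients)) / sqrt(diag(x$vcov)),
      df = x$df_residual, lower.tail = FALSE
    )
  )
}

#' @method glance sr_threshold_lm
#' @export
glance.sr_threshold_lm <- function(x, ...) {
  tibble::tibble(
    nobs = x$n,
    sigma = sqrt(x$sigma2),
    df.residual = x$df_residual
  )
}
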