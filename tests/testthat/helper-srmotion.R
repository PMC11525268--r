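# Shared fixtures built in code.

# Trial table simulated from a known logit GLMM on the standard
# participant x 14-level grid (balanced, 20 trials per cell).
sim_glmm_trials <- function(n_part, degree, beta, sigma_u2, seed,
                            ages = NULL) {
  set.seed(seed)
  if (is.null(ages)) ages <- runif(n_part, 18, 82)
  agg <- tidyr::crossing(participant_id = seq_len(n_part),
                         n_dots = sr_dot_levels())
  agg$age <- ages[agg$participant_id]
  agg$m <- 20L
  agg$k <- 0L
  design <- srmotion:::build_glmm_design(agg, degree)
  stopifnot(length(beta) == ncol(design$x))
  u <- rnorm(n_part, 0, sqrt(sigma_u2))
  p <- plogis(drop(design$x %*% beta) + u[agg$participant_id])
  agg$k <- rbinom(nrow(agg), 20, p)
  list(trials = srmotion:::expand_counts(agg), design = design, agg = agg)
}

# Minimal sr_glmm object for prediction/peak/R2 unit tests.
fake_glmm <- function(beta, degree = 4, n_part = 10, sigma_u2 = 0,
                      ages = seq(20, 80, length.out = 10)) {
  agg <- tidyr::crossing(participant_id = seq_len(n_part),
                         n_dots = sr_dot_levels())
  agg$age <- ages[agg$participant_id]
  agg$m <- 20L
  agg$k <- 10L
  design <- srmotion:::build_glmm_design(agg, degree)
  structure(
    list(beta = setNames(beta, colnames(design$x)), design = design,
         agg = agg, sigma_u2 = sigma_u2, converged = TRUE,
         vcov = diag(length(beta)), K = length(beta) + 1L,
         n_obs = sum(agg$m), loglik = NA_real_, nodes = 7),
    class = "sr_glmm"
  )
}
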