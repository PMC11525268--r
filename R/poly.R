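# Covariate scaling and orthogonal polynomial bases.

#' Centre and scale a covariate
#'
#' Subtracts the mean and divides by the sample SD (n - 1 denominator),
#' keeping the transform parameters so new values can be mapped into the
#' same scale at prediction time.
#'
#' @param x numeric vector with at least two distinct values.
#' @return list with `scaled`, `center`, `spread`.
#' @export
#' @examples
#' zscale(c(1, 2, 3))$scaled # -1 0 1
zscale <- function(x) {
  if (length(unique(x)) < 2) stop_domain("zscale needs >= 2 distinct values")
  center <- mean(x)
  spread <- sd(x)
  list(scaled = (x - center) / spread, center = center, spread = spread)
}

#' Orthogonal polynomial basis
#'
#' Discrete orthonormal polynomials of `x` up to `degree`, built by the
#' standard three-term recurrence: columns have zero sum, unit norm and
#' pairwise zero inner products on the data. The recurrence coefficients
#' (`alpha`, `norm2`) are returned so that new `x` values can be projected
#' into the identical basis with [poly_eval()].
#'
#' @param x numeric vector with more distinct values than `degree`.
#' @param degree polynomial degree, 1 to 4.
#' @return list of class `orth_poly` with `basis` (matrix, one column per
#'   degree), `alpha`, `norm2`, `degree`.
#' @export
orthogonal_poly <- function(x, degree) {
  if (!degree %in% 1:4) stop_domain("degree must be in 1..4")
  if (length(unique(x)) <= degree) {
    stop_domain("orthogonal_poly needs more distinct x values than degree")
  }
  n <- length(x)
  p <- matrix(0, n, degree + 1L)
  p[, 1] <- 1
  alpha <- numeric(degree)
  norm2 <- numeric(degree + 1L)
  norm2[1] <- n
  for (j in seq_len(degree)) {
    alpha[j] <- sum(x * p[, j]^2) / sum(p[, j]^2)
    p[, j + 1] <- (x - alpha[j]) * p[, j]
    if (j > 1) {
      p[, j + 1] <- p[, j + 1] - (norm2[j] / norm2[j - 1]) * p[, j - 1]
    }
    norm2[j + 1] <- sum(p[, j + 1]^2)
  }
  basis <- sweep(p[, -1, drop = FALSE], 2, sqrt(norm2[-1]), "/")
  colnames(basis) <- paste0("poly", seq_len(degree))
  structure(
    list(basis = basis, alpha = alpha, norm2 = norm2, degree = degree),
    class = "orth_poly"
  )
}

#' Evaluate an orthogonal polynomial basis at new values
#'
#' @param op an `orth_poly` from [orthogonal_poly()].
#' @param x_new numeric vector.
#' @return matrix with `op$degree` columns, in the basis of the original
#'   data.
#' @export
poly_eval <- function(op, x_new) {
  n <- length(x_new)
  degree <- op$degree
  p <- matrix(0, n, degree + 1L)
  p[, 1] <- 1
  for (j in seq_len(degree)) {
    p[, j + 1] <- (x_new - op$alpha[j]) * p[, j]
    if (j > 1) {
      p[, j + 1] <- p[, j + 1] - (op$norm2[j] / op$norm2[j - 1]) * p[, j - 1]
    }
  }
  basis <- sweep(p[, -1, drop = FALSE], 2, sqrt(op$norm2[-1]), "/")
  colnames(basis) <- paste0("poly", seq_len(degree))
  basis
}

#' Small-sample corrected Akaike information criterion
#'
#' `-2 loglik + 2K + 2K(K + 1)/(n - K - 1)`.
#'
#' @param loglik log-likelihood at the optimum.
#' @param k number of estimated parameters (fixed effects plus variance
#'   components).
#' @param n_obs number of observations.
#' @return a number.
#' @export
#' @examples
#' aicc(-10, 2, 10) # 25.71429
aicc <- function(loglik, k, n_obs) {
  if (any(n_obs <= k + 1)) stop_domain("aicc requires n_obs > K + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with deltas taken
#' from the minimum AICc, so the computation is numerically safe for large
#' criteria.
#'
#' @param aicc_values numeric vector of AICc values.
#' @return weights summing to 1.
#' @export
#' @examples
#' akaike_weights(c(0, 2)) # 0.7311 0.2689
akaike_weights <- function(aicc_values) {
  if (!length(aicc_values) || any(!is.finite(aicc_values))) {
    stop_domain("aicc_values must be non-empty and finite")
  }
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}
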