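# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic half-up rounding (0.5 always rounds up), unlike base
#' `round()`'s round-half-to-even.
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(floor(x + 0.5))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All seeded operations in the package
# go through this so that global RNG state is never disturbed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a stream-specific seed from a master seed
#'
#' Named streams (e.g. `"cohort"`, `"staircase"`) get statistically distinct
#' but reproducible sub-seeds from one master seed, so that adding trials to
#' one stage never perturbs another.
#'
#' @param master integer master seed.
#' @param stream character scalar naming the consumer.
#' @param index optional integer (e.g. participant number) for per-unit
#'   streams.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "cohort")
#' derive_seed(1, "staircase", 12)
derive_seed <- function(master, stream, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  s <- (as.double(master) %% 2147483647) * 48271 %% 2147483647
  out <- (s + h * 7919 + as.double(index) * 104729) %% 2147483646
  as.integer(out + 1)
}

stop_domain <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_fraction <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
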