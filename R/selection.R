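# AICc model selection across polynomial degrees.

#' Model-selection table
#'
#' Ranks candidate fits of the same data by AICc, with deltas, Akaike
#' weights and cumulative weights.
#'
#' @param fits named list of `sr_glmm` fits of the identical response data.
#' @return tibble of class `sr_selection_table` with columns `model`, `K`,
#'   `AICc`, `delta_AICc`, `weight`, `cum_weight`, `loglik`, sorted
#'   ascending by AICc.
#' @export
model_selection_table <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "sr_glmm")))
  n_obs <- vapply(fits, function(f) f$n_obs, numeric(1))
  checksum <- vapply(fits, function(f) sum(f$agg$k * seq_along(f$agg$k)),
                     numeric(1))
  if (length(unique(n_obs)) != 1 || length(unique(checksum)) != 1) {
    stop_domain("model_selection_table: fits are not on identical data")
  }
  if (is.null(names(fits))) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  tbl <- tibble::tibble(
    model = names(fits),
    K = vapply(fits, function(f) f$K, integer(1), USE.NAMES = FALSE),
    loglik = vapply(fits, function(f) f$loglik, numeric(1),
                    USE.NAMES = FALSE),
    AICc = vapply(fits, function(f) aicc(f$loglik, f$K, f$n_obs),
                  numeric(1), USE.NAMES = FALSE)
  )
  tbl <- tbl |>
    dplyr::arrange(.data$AICc) |>
    dplyr::mutate(
      delta_AICc = .data$AICc - min(.data$AICc),
      weight = akaike_weights(.data$AICc),
      cum_weight = cumsum(.data$weight)
    ) |>
    dplyr::select(
      "model", "K", "AICc", "delta_AICc", "weight", "cum_weight", "loglik"
    )
  class(tbl) <- c("sr_selection_table", class(tbl))
  tbl
}

#' Fit and compare polynomial GLMMs
#'
#' Fits the binomial random-intercept GLMM at each requested polynomial
#' degree of log dot numerosity and ranks them by AICc.
#'
#' @inheritParams fit_logistic_glmm
#' @param degrees degrees to compare.
#' @return list of class `sr_selection` with elements `fits` (named list)
#'   and `table` (from [model_selection_table()]).
#' @export
compare_sr_models <- function(trials, degrees = 1:4,
                              age_mode = "continuous", age_cut = 50,
                              nodes = 15) {
  names_map <- c("linear", "quadratic", "cubic", "fourth_degree")
  fits <- lapply(degrees, function(d) {
    fit_logistic_glmm(trials, degree = d, age_mode = age_mode,
                      age_cut = age_cut, nodes = nodes)
  })
  names(fits) <- names_map[degrees]
  structure(
    list(fits = fits, table = model_selection_table(fits)),
    class = "sr_selection"
  )
}

#' @export
print.sr_selection <- function(x, ...) {
  cat("<sr_selection> AICc comparison of polynomial degrees\n")
  print(tibble::as_tibble(x$table))
  invisible(x)
}

#' Best model of a comparison
#'
#' @param selection an `sr_selection`.
#' @return the `sr_glmm` with the smallest AICc.
#' @export
best_model <- function(selection) {
  stopifnot(inherits(selection, "sr_selection"))
  selection$fits[[selection$table$model[1]]]
}

#' Selected polynomial degree
#'
#' @param selection an `sr_selection`.
#' @return integer degree of the AICc-best model.
#' @export
selected_degree <- function(selection) {
  best_model(selection)$design$degree
}
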