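# Random-dot kinematogram stimulus generator.
#
# A dot field lives in a square aperture [0, aperture_deg]^2 (degrees of
# visual angle, origin bottom-left, +x rightward). Coherent dots translate
# rightward by a fixed displacement each frame; the remaining dots take a
# random-walk step of the same length in a fresh uniform direction every
# frame. A dot stepping out of the aperture reappears at a uniformly random
# point on the opposite edge.

#' Stimulus geometry and timing
#'
#' Defaults encode the display used throughout: a 10 degree square aperture,
#' 0.075 degree dots displaced 0.05 degrees per frame at 60 Hz (3 deg/s),
#' shown for 133 ms (8 frames).
#'
#' @param aperture_deg aperture side length, degrees.
#' @param dot_diameter_deg dot diameter, degrees (carried for export only).
#' @param displacement_deg_per_frame per-frame dot displacement, degrees.
#' @param frame_rate_hz display frame rate.
#' @param duration_ms stimulus interval duration.
#' @param coherent_direction direction of coherent motion, radians
#'   (0 = rightward; only rightward is used by the task).
#' @return an object of class `stimulus_spec`.
#' @export
#' @examples
#' spec <- stimulus_spec()
#' spec$n_frames # 8
stimulus_spec <- function(aperture_deg = 10,
                          dot_diameter_deg = 0.075,
                          displacement_deg_per_frame = 0.05,
                          frame_rate_hz = 60,
                          duration_ms = 133,
                          coherent_direction = 0) {
  if (aperture_deg <= 0) stop_domain("aperture_deg must be > 0")
  if (displacement_deg_per_frame <= 0) {
    stop_domain("displacement_deg_per_frame must be > 0")
  }
  n_frames <- round(duration_ms / 1000 * frame_rate_hz)
  if (n_frames < 1) stop_domain("duration and frame rate give < 1 frame")
  structure(
    list(
      aperture_deg = aperture_deg,
      dot_diameter_deg = dot_diameter_deg,
      displacement_deg_per_frame = displacement_deg_per_frame,
      frame_rate_hz = frame_rate_hz,
      duration_ms = duration_ms,
      coherent_direction = coherent_direction,
      n_frames = as.integer(n_frames),
      speed_deg_per_s = displacement_deg_per_frame * frame_rate_hz
    ),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "<stimulus_spec> %g deg aperture, %g deg/frame at %g Hz (%g deg/s), %d frames\n",
    x$aperture_deg, x$displacement_deg_per_frame, x$frame_rate_hz,
    x$speed_deg_per_s, x$n_frames
  ))
  invisible(x)
}

#' Number of coherently moving dots
#'
#' The coherent count is `coherence * n_dots` rounded half-up, so a field
#' can realise any requested coherence as closely as an integer allows.
#'
#' @param n_dots total dots (>= 1).
#' @param coherence fraction of dots moving coherently, in `[0, 1]`.
#' @return non-negative integer, at most `n_dots`.
#' @export
#' @examples
#' coherent_dot_count(100, 0.12) # 12
#' coherent_dot_count(400, 0.0715) # 29 (28.6 rounds up)
coherent_dot_count <- function(n_dots, coherence) {
  if (!is.numeric(n_dots) || any(n_dots < 1)) stop_domain("n_dots must be >= 1")
  if (!is_fraction(coherence)) stop_domain("coherence must be in [0, 1]")
  pmin(round_half_up(coherence * n_dots), as.integer(n_dots))
}

#' Initialise a dot field
#'
#' Dots are placed i.i.d. uniformly over the aperture; exactly
#' [coherent_dot_count()] of them, chosen uniformly without replacement, are
#' flagged coherent.
#'
#' @param spec a [stimulus_spec()].
#' @param n_dots total number of dots.
#' @param coherence fraction of coherent dots.
#' @param seed integer seed; identical seeds give identical fields.
#' @return a tibble of class `dot_field` with columns `dot_id`, `x_deg`,
#'   `y_deg`, `coherent`, and attributes `spec`, `coherence`.
#' @export
#' @examples
#' f <- rdk_init(stimulus_spec(), n_dots = 100, coherence = 0.1, seed = 1)
#' sum(f$coherent) # 10
rdk_init <- function(spec, n_dots, coherence, seed = NULL) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (n_dots < 1) stop_domain("n_dots must be >= 1")
  n_dots <- as.integer(n_dots)
  n_coh <- coherent_dot_count(n_dots, coherence)
  field <- with_seed(seed, {
    xy <- matrix(runif(2 * n_dots, 0, spec$aperture_deg), ncol = 2)
    idx <- sample.int(n_dots, n_coh)
    tibble::tibble(
      dot_id = seq_len(n_dots),
      x_deg = xy[, 1],
      y_deg = xy[, 2],
      coherent = seq_len(n_dots) %in% idx
    )
  })
  attr(field, "spec") <- spec
  attr(field, "coherence") <- coherence
  class(field) <- c("dot_field", class(field))
  field
}

# Wrap rule: a dot leaving the aperture reappears at a uniformly random
# point on the opposite edge; on a corner exit the edge opposite the axis
# with the larger overshoot is used.
wrap_dots <- function(x, y, ap) {
  over_x <- pmax(x - ap, -x, 0)
  over_y <- pmax(y - ap, -y, 0)
  out <- over_x > 0 | over_y > 0
  if (!any(out)) {
    return(list(x = x, y = y, wrapped = out))
  }
  use_x <- out & over_x >= over_y # x-axis exit wins ties
  use_y <- out & !use_x
  n_x <- sum(use_x)
  n_y <- sum(use_y)
  if (n_x) {
    # left exit -> right edge, right exit -> left edge
    x[use_x] <- ifelse(x[use_x] < 0, ap, 0)
    y[use_x] <- runif(n_x, 0, ap)
  }
  if (n_y) {
    y[use_y] <- ifelse(y[use_y] < 0, ap, 0)
    x[use_y] <- runif(n_y, 0, ap)
  }
  list(x = x, y = y, wrapped = out)
}

#' Advance a dot field by one frame
#'
#' Coherent dots translate along the coherent direction by the per-frame
#' displacement; each random dot takes a step of the same length in a fresh
#' uniform direction. Dots leaving the aperture wrap to the opposite edge.
#' The dot count and coherent assignment never change within a trial.
#'
#' @param field a `dot_field`.
#' @param spec the [stimulus_spec()]; defaults to the one stored on `field`.
#' @return the advanced `dot_field`, with a logical attribute-free column
#'   `wrapped` marking dots repositioned by the wrap rule this frame.
#' @export
rdk_advance <- function(field, spec = attr(field, "spec")) {
  stopifnot(inherits(field, "dot_field"), inherits(spec, "stimulus_spec"))
  d <- spec$displacement_deg_per_frame
  ap <- spec$aperture_deg
  x <- field$x_deg
  y <- field$y_deg
  coh <- field$coherent
  x[coh] <- x[coh] + d * cos(spec$coherent_direction)
  y[coh] <- y[coh] + d * sin(spec$coherent_direction)
  n_rand <- sum(!coh)
  if (n_rand) {
    ang <- runif(n_rand, 0, 2 * pi)
    x[!coh] <- x[!coh] + d * cos(ang)
    y[!coh] <- y[!coh] + d * sin(ang)
  }
  w <- wrap_dots(x, y, ap)
  out <- field
  out$x_deg <- w$x
  out$y_deg <- w$y
  out$wrapped <- w$wrapped
  out
}

#' Generate all frames of a trial
#'
#' @inheritParams rdk_init
#' @param n_frames number of frames; defaults to `spec$n_frames`.
#' @return a tibble with columns `frame`, `dot_id`, `x_deg`, `y_deg`,
#'   `coherent`, `wrapped` (frame 1 has `wrapped = FALSE`). Suitable for the
#'   CSV fixture export via [readr::write_csv()].
#' @export
rdk_frames <- function(spec, n_dots, coherence, seed = NULL,
                       n_frames = spec$n_frames) {
  field <- rdk_init(spec, n_dots, coherence, seed = seed)
  with_seed(if (is.null(seed)) NULL else seed + 1L, {
    frames <- vector("list", n_frames)
    cur <- field
    cur$wrapped <- FALSE
    frames[[1]] <- dplyr::mutate(tibble::as_tibble(cur), frame = 1L)
    if (n_frames > 1) {
      for (k in 2:n_frames) {
        cur <- rdk_advance(cur, spec)
        frames[[k]] <- dplyr::mutate(tibble::as_tibble(cur), frame = k)
      }
    }
    dplyr::select(
      dplyr::bind_rows(frames),
      "frame", "dot_id", "x_deg", "y_deg", "coherent", "wrapped"
    )
  })
}

#' Net rightward motion energy of a frame sequence
#'
#' The mean over dots and frame transitions of the x-displacement divided by
#' the per-frame displacement, with wrapped transitions counted as zero. For
#' a field of coherence `c` the expectation is `c`: coherent dots contribute
#' 1 per transition, random-walk dots 0 on average.
#'
#' @param frames a tibble as returned by [rdk_frames()].
#' @param spec the [stimulus_spec()] the frames were generated under.
#' @return a single number.
#' @export
directional_energy <- function(frames, spec = stimulus_spec()) {
  n_frames <- length(unique(frames$frame))
  if (n_frames < 2) stop_domain("directional_energy needs >= 2 frames")
  d <- spec$displacement_deg_per_frame
  steps <- frames |>
    dplyr::arrange(.data$dot_id, .data$frame) |>
    dplyr::group_by(.data$dot_id) |>
    dplyr::mutate(
      dx = .data$x_deg - dplyr::lag(.data$x_deg),
      step_wrapped = .data$wrapped
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$dx))
  mean(ifelse(steps$step_wrapped, 0, steps$dx / d))
}
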