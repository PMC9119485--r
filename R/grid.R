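#' Build the response grid for an estimation trial
#'
#' Places `n_response_options` evenly spaced option centres so that the option
#' at the veridical index is centred on the true final ball position. The grid
#' footprint (`grid_width_frac` of the screen) is the distance between the
#' outer edges of the first and last option cells, so the option spacing is
#' `grid_width_frac / n_response_options` and centres sit at cell midpoints.
#' The veridical index is drawn uniformly from the design's
#' `veridical_index_range`, which guarantees response options on both sides of
#' the true position and makes the grid's absolute position uninformative.
#'
#' If the veridical-centred grid would extend beyond the screen, it is
#' translated minimally so that all cells fit in \eqn{[0, 1]} and the
#' `clamped` flag is set; the veridical index is preserved (the veridical
#' option is then no longer exactly ball-centred).
#'
#' @param ball_pos True final ball position as a fraction of screen width.
#' @param design A [task_design()].
#' @param seed Optional integer seed for the veridical-index draw; when `NULL`
#'   the current RNG stream is used.
#' @return A list of class `estimation_grid` with elements `centres` (option
#'   centres, screen fractions), `veridical_index`, `spacing` and `clamped`.
#' @export
build_estimation_grid <- function(ball_pos, design = task_design(), seed = NULL) {
  stopifnot(is.numeric(ball_pos), length(ball_pos) == 1)
  if (ball_pos < 0 || ball_pos > 1) stop("ball_pos must lie in [0, 1]", call. = FALSE)
  n <- design$n_response_options
  spacing <- design$grid_width_frac / n
  draw <- function() {
    r <- design$veridical_index_range
    if (r[1] == r[2]) r[1] else sample(seq.int(r[1], r[2]), 1L)
  }
  veridical <- if (is.null(seed)) draw() else with_seed(seed, draw())
  centres <- ball_pos + (seq_len(n) - veridical) * spacing
  lo <- centres[1] - spacing / 2
  hi <- centres[n] + spacing / 2
  clamped <- FALSE
  if (hi - lo > 1) stop("estimation grid wider than the screen", call. = FALSE)
  if (lo < 0) {
    # rebuild flush against the lower screen edge (exact arithmetic)
    centres <- spacing / 2 + (seq_len(n) - 1) * spacing
    clamped <- TRUE
  } else if (hi > 1) {
    centres <- 1 - spacing / 2 - (n - seq_len(n)) * spacing
    clamped <- TRUE
  }
  structure(list(centres = centres, veridical_index = as.integer(veridical),
                 spacing = spacing, clamped = clamped),
            class = "estimation_grid")
}

#' Snap a continuous position to the nearest grid option
#'
#' Ties are broken toward the lower index; positions beyond the outermost
#' cells are clamped to options 1 and n.
#'
#' @param pos Position in screen fractions (vectorised).
#' @param grid An [build_estimation_grid()] result.
#' @return Integer option indices.
#' @export
snap_to_grid <- function(pos, grid) {
  n <- length(grid$centres)
  # centres are evenly spaced: 0-based offset k, rounded to the nearest
  # integer with half-way cases (within a small float guard) going down
  k <- (pos - grid$centres[1]) / grid$spacing
  k0 <- floor(k)
  idx <- k0 + ((k - k0) > 0.5 + 1e-9) + 1
  as.integer(pmin(pmax(idx, 1L), n))
}

#' Convert screen fractions to pixels
#'
#' @param frac Positions as fractions of screen width.
#' @param design A [task_design()]; supplies `screen_width_px`.
#' @return Positions in pixels.
#' @export
frac_to_px <- function(frac, design = task_design()) {
  frac * design$screen_width_px
}
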