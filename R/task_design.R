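#' Task design for the effort-based visuomotor experiment
#'
#' Constructs the deterministic scaffolding of the task: block structure,
#' trial-type counts, effort and reward manipulations, and the response-grid
#' geometry used on estimation trials. All spatial quantities are expressed as
#' fractions of screen width in \eqn{[0, 1]}; pixel conversion happens only at
#' I/O via `screen_width_px`.
#'
#' @param n_blocks Number of test blocks.
#' @param trials_per_block Trials per block; must equal
#'   `basic_per_block + estimation_per_block`.
#' @param basic_per_block Trials per block on which the ball trajectory is
#'   shown (feedback trials).
#' @param estimation_per_block Trials per block on which the trajectory is
#'   hidden and the participant estimates the final ball position.
#' @param effort_levels Target positions as fractions of maximum force (and,
#'   equivalently, of screen width). The default corresponds to the low/high
#'   physical-effort manipulation.
#' @param reward_levels Reward manipulation levels.
#' @param n_response_options Number of evenly spaced response options on the
#'   estimation grid.
#' @param grid_width_frac Footprint of the estimation grid as a fraction of
#'   screen width, measured between the outer edges of the first and last
#'   option cells.
#' @param veridical_index_range Inclusive integer interval from which the
#'   veridical (ball-centred) option index is drawn uniformly.
#' @param screen_width_px Display width in pixels, used only for unit
#'   conversion at I/O.
#'
#' @return An object of class `task_design`.
#' @export
task_design <- function(n_blocks = 4L,
                        trials_per_block = 30L,
                        basic_per_block = 20L,
                        estimation_per_block = 10L,
                        effort_levels = c(0.35, 0.65),
                        reward_levels = c("off", "on"),
                        n_response_options = 12L,
                        grid_width_frac = 0.30,
                        veridical_index_range = c(3L, 10L),
                        screen_width_px = 1920L) {
  d <- structure(
    list(
      n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      basic_per_block = as.integer(basic_per_block),
      estimation_per_block = as.integer(estimation_per_block),
      effort_levels = as.numeric(effort_levels),
      reward_levels = as.character(reward_levels),
      n_response_options = as.integer(n_response_options),
      grid_width_frac = as.numeric(grid_width_frac),
      veridical_index_range = as.integer(veridical_index_range),
      screen_width_px = as.integer(screen_width_px)
    ),
    class = "task_design"
  )
  validate_task_design(d)
  d
}

validate_task_design <- function(d) {
  stopifnot(inherits(d, "task_design"))
  if (d$trials_per_block != d$basic_per_block + d$estimation_per_block) {
    stop("constraint violated: trials_per_block must equal basic_per_block + estimation_per_block",
         call. = FALSE)
  }
  if (d$veridical_index_range[1] < 1L ||
      d$veridical_index_range[2] > d$n_response_options ||
      d$veridical_index_range[1] > d$veridical_index_range[2]) {
    stop("constraint violated: veridical_index_range must be an ordered interval within [1, n_response_options]",
         call. = FALSE)
  }
  if (d$grid_width_frac <= 0 || d$grid_width_frac >= 1) {
    stop("constraint violated: grid_width_frac must lie in (0, 1)", call. = FALSE)
  }
  if (any(d$effort_levels <= 0) || any(d$effort_levels >= 1)) {
    stop("constraint violated: effort_levels must lie in (0, 1)", call. = FALSE)
  }
  if (d$n_blocks < 1L || d$trials_per_block < 1L ||
      d$basic_per_block < 0L || d$estimation_per_block < 0L) {
    stop("constraint violated: counts must be positive", call. = FALSE)
  }
  invisible(d)
}

#' @export
print.task_design <- function(x, ...) {
  cat("Visuomotor task design\n")
  cat(sprintf("  %d blocks x %d trials (%d basic + %d estimation)\n",
              x$n_blocks, x$trials_per_block, x$basic_per_block,
              x$estimation_per_block))
  cat(sprintf("  estimation grid: %d options over %.0f%% of screen width, veridical index in [%d, %d]\n",
              x$n_response_options, 100 * x$grid_width_frac,
              x$veridical_index_range[1], x$veridical_index_range[2]))
  invisible(x)
}

# Uniform draw of k non-adjacent positions among m slots (first slot may be
# used; adjacency means consecutive slots). Bijection with unordered k-subsets
# of m - k + 1 slots: sample the subset, then spread.
sample_nonadjacent <- function(m, k) {
  if (k == 0L) return(integer(0))
  if (k > (m + 1L) %/% 2L) {
    stop("constraint violated: too many estimation trials per block to avoid consecutive estimation trials",
         call. = FALSE)
  }
  base <- sort(sample.int(m - k + 1L, k))
  base + seq_len(k) - 1L
}

#' Build a task design and a pseudorandom trial sequence
#'
#' Produces a [task_design()] (with optional field overrides) together with a
#' trial sequence satisfying the structural constraints of the experiment: the
#' first 3 trials of every block are basic trials, no two estimation trials
#' are consecutive, and per-block type counts match the design. Each
#' effort-by-reward combination is assigned to one block, in seeded random
#' order. Estimation-trial placement is sampled uniformly over all admissible
#' arrangements.
#'
#' @param config Named list of [task_design()] field overrides.
#' @param seed Integer seed; the sequence is reproducible from it.
#' @param n_lead_basic Number of leading basic trials per block.
#'
#' @return A list with elements `design` (a `task_design`) and `sequence`
#'   (a data frame with columns `block`, `trial`, `trial_type`, `effort`,
#'   `reward`), of class `trial_sequence`.
#' @export
build_task_design <- function(config = list(), seed = 1L, n_lead_basic = 3L) {
  design <- do.call(task_design, config)
  free <- design$trials_per_block - n_lead_basic
  if (free < 0L) stop("constraint violated: fewer trials per block than leading basic trials", call. = FALSE)
  if (design$estimation_per_block > (free + 1L) %/% 2L) {
    stop("constraint violated: too many estimation trials per block to avoid consecutive estimation trials",
         call. = FALSE)
  }
  seq_df <- with_seed(seed, generate_trial_sequence(design, n_lead_basic))
  list(design = design, sequence = seq_df)
}

# Draws a trial sequence from the current RNG stream.
generate_trial_sequence <- function(design, n_lead_basic = 3L) {
  free <- design$trials_per_block - n_lead_basic
  combos <- expand.grid(effort = design$effort_levels,
                        reward = design$reward_levels,
                        stringsAsFactors = FALSE)
  idx <- rep_len(sample.int(nrow(combos)), design$n_blocks)
  blocks <- lapply(seq_len(design$n_blocks), function(b) {
    types <- rep("basic", design$trials_per_block)
    # positions among the free slots; slot 1 (trial n_lead_basic + 1) is
    # allowed because the preceding trial is always basic
    pos <- sample_nonadjacent(free, design$estimation_per_block)
    types[n_lead_basic + pos] <- "estimation"
    data.frame(
      block = b,
      trial = seq_len(design$trials_per_block),
      trial_type = types,
      effort = combos$effort[idx[b]],
      reward = combos$reward[idx[b]],
      stringsAsFactors = FALSE
    )
  })
  seq_df <- do.call(rbind, blocks)
  seq_df$trial <- seq_len(nrow(seq_df))
  rownames(seq_df) <- NULL
  class(seq_df) <- c("trial_sequence", "data.frame")
  seq_df
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
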