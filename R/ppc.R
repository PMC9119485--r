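#' Posterior predictive check
#'
#' For each retained posterior draw (optionally a thinned subset), simulates
#' replicated estimation responses from the model and summarizes, per
#' participant, the replicated-response distributions and the distribution of
#' mean predictive error (observed minus replicated responses, averaged over
#' the participant's trials). Under a well-specified model the mean-residual
#' distributions are centred on zero.
#'
#' @param samples A `posterior_samples` object.
#' @param data The `model_data` the model was fitted to (defaults to the data
#'   stored in the fit).
#' @param seed Integer seed for the replicated draws.
#' @param max_draws Number of posterior draws to use (evenly thinned).
#' @return An object of class `ppc_summary`: `replicated` (list per
#'   participant: matrix draws x trials), `observed` (list per participant),
#'   `residual_means` (matrix draws x participants), `n_rep` (number of
#'   replicated datasets).
#' @export
posterior_predictive_check <- function(samples, data = samples$data, seed = 1L,
                                       max_draws = 500L) {
  stopifnot(inherits(samples, "posterior_samples"), inherits(data, "model_data"))
  if (!identical(data$index, samples$data$index)) {
    stop("samples and data are not aligned", call. = FALSE)
  }
  model <- build_generative_model(samples$variant, samples$hyper)
  flat <- flatten_draws(samples)
  take <- unique(round(seq(1, nrow(flat), length.out = min(nrow(flat), max_draws))))
  obs <- lapply(data$participants, function(p) unlist(lapply(p, `[[`, "estimate")))
  nt <- vapply(obs, length, 0L)
  part_col <- rep(seq_len(data$n), nt)
  rep_list <- lapply(nt, function(k) matrix(NA_real_, length(take), k))
  resid <- matrix(NA_real_, length(take), data$n,
                  dimnames = list(NULL, data$ids))
  with_seed(seed, {
    for (r in seq_along(take)) {
      theta <- flat_to_theta(flat[take[r], ], samples$families, data$ids)
      y_rep <- model$simulate_responses(theta, data)
      for (i in seq_len(data$n)) {
        yi <- y_rep[part_col == i]
        rep_list[[i]][r, ] <- yi
        resid[r, i] <- mean(obs[[i]]) - mean(yi)
      }
    }
  })
  structure(list(replicated = rep_list, observed = obs,
                 residual_means = resid, n_rep = length(take)),
            class = "ppc_summary")
}

#' @export
print.ppc_summary <- function(x, ...) {
  cat(sprintf("ppc_summary: %d replicated datasets, %d participants\n",
              x$n_rep, ncol(x$residual_means)))
  cat("mean residuals (posterior-predictive mean error) per participant:\n")
  print(round(colMeans(x$residual_means), 4))
  invisible(x)
}

# draws array -> (kept * chains) x params matrix with parameter names
flatten_draws <- function(samples) {
  d <- samples$draws
  out <- matrix(d, nrow = dim(d)[1] * dim(d)[2])
  colnames(out) <- dimnames(d)[[3]]
  out
}

#' Participant-level posterior summaries
#'
#' Posterior medians of each participant-level parameter, plus the derived
#' per-session prior weighting: the weighting is computed per draw from the
#' session-specific sds and the median is taken over draws (median of the
#' derived quantity, not the derived quantity of medians).
#'
#' @param samples A `posterior_samples` object.
#' @return A data frame, one row per participant, with posterior medians of
#'   `sigma_prior`, `sigma_evidence`, `delta_prior`, `delta_evidence`,
#'   `x_shift`, per-session prior weighting (`w_placebo`, `w_atomoxetine`)
#'   and the drug effects on prior weighting and on the two sds.
#' @export
extract_participant_effects <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (!samples$converged) {
    warning("summaries from a fit whose convergence was not confirmed", call. = FALSE)
  }
  flat <- flatten_draws(samples)
  ids <- samples$data$ids
  fams <- samples$families
  col <- function(f, id) {
    nm <- sprintf("%s[%s]", f, id)
    if (nm %in% colnames(flat)) flat[, nm] else rep(0, nrow(flat))
  }
  rows <- lapply(ids, function(id) {
    sp <- col("sigma_prior", id); se <- col("sigma_evidence", id)
    dp <- col("delta_prior", id); de <- col("delta_evidence", id)
    xs <- col("x_shift", id)
    w1 <- prior_weighting(sp, se)
    w2 <- prior_weighting(sp + dp, se + de)
    data.frame(
      participant_id = id,
      sigma_prior = stats::median(sp), sigma_evidence = stats::median(se),
      delta_prior = stats::median(dp), delta_evidence = stats::median(de),
      x_shift = stats::median(xs),
      w_placebo = stats::median(w1), w_atomoxetine = stats::median(w2),
      delta_w = stats::median(w2 - w1),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior draws of participant-level parameters
#'
#' @param samples A `posterior_samples` object.
#' @param family Parameter family name.
#' @return Matrix of draws (rows) by participants (columns); structurally
#'   absent families return zeros.
#' @export
participant_draws <- function(samples, family = model_families) {
  family <- match.arg(family)
  flat <- flatten_draws(samples)
  ids <- samples$data$ids
  out <- sapply(ids, function(id) {
    nm <- sprintf("%s[%s]", family, id)
    if (nm %in% colnames(flat)) flat[, nm] else rep(0, nrow(flat))
  })
  colnames(out) <- ids
  out
}
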