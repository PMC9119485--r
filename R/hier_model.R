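#' Hyperprior specification for the hierarchical model
#'
#' Weakly informative priors on the group-level parameters, in screen-fraction
#' units. Group means of the sd parameters have positive-truncated normal
#' priors centred at zero (scale 0.2); group sds have half-normal priors
#' (scale 0.1); the drug-delta and evidence-shift group means are zero-centred
#' normals (scale 0.1) and their group sds half-normals (scale 0.1). All
#' constants are overridable per family.
#'
#' @param ... Named overrides, one list per family among `sigma_prior`,
#'   `sigma_evidence`, `delta_prior`, `delta_evidence`, `x_shift`; each a list
#'   with elements `mean_loc`, `mean_scale`, `mean_positive` (logical),
#'   `sd_scale`.
#' @return An object of class `hyper_prior_spec`.
#' @export
hyper_prior_spec <- function(...) {
  sigma_like <- list(mean_loc = 0, mean_scale = 0.2, mean_positive = TRUE, sd_scale = 0.1)
  delta_like <- list(mean_loc = 0, mean_scale = 0.1, mean_positive = FALSE, sd_scale = 0.1)
  spec <- list(sigma_prior = sigma_like, sigma_evidence = sigma_like,
               delta_prior = delta_like, delta_evidence = delta_like,
               x_shift = delta_like)
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(spec)) stop("unknown parameter family: ", nm, call. = FALSE)
    if (!isTRUE(over[[nm]]$mean_positive) && nm %in% c("delta_prior", "delta_evidence", "x_shift") &&
        over[[nm]]$mean_loc != 0) {
      stop("delta and x_shift group-mean priors must be centred at zero", call. = FALSE)
    }
    spec[[nm]] <- utils::modifyList(spec[[nm]], over[[nm]])
  }
  structure(spec, class = "hyper_prior_spec")
}

model_families <- c("sigma_prior", "sigma_evidence", "delta_prior",
                    "delta_evidence", "x_shift")

# Families with free participant-level parameters under each variant;
# restricted variants fix the omitted deltas at 0 (structurally absent).
variant_families <- function(variant) {
  switch(variant,
    full = model_families,
    prior_delta_only = setdiff(model_families, "delta_evidence"),
    evidence_delta_only = setdiff(model_families, "delta_prior"),
    no_delta = setdiff(model_families, c("delta_prior", "delta_evidence")),
    stop("unknown model variant: ", variant, call. = FALSE)
  )
}

#' Prepare crossover data for the hierarchical model
#'
#' Collects the estimation trials of participants with exactly one placebo
#' and one atomoxetine session (the model is fitted to the drug-manipulated
#' group only). Responses enter in screen-fraction units.
#'
#' @param x A `cohort` or a list of `session_data`.
#' @return An object of class `model_data`: per-participant session data
#'   (targets, ball positions, observed estimates) plus a trial index map
#'   defining the column order of pointwise log-likelihood matrices.
#' @export
prepare_model_data <- function(x) {
  sessions <- if (inherits(x, "cohort")) x$sessions else x
  if (inherits(sessions, "session_data")) sessions <- list(sessions)
  ids <- unique(vapply(sessions, `[[`, "", "participant_id"))
  participants <- list()
  for (id in ids) {
    ss <- Filter(function(s) s$participant_id == id, sessions)
    conds <- vapply(ss, `[[`, "", "condition")
    if (!setequal(conds, c("placebo", "atomoxetine")) || length(ss) != 2L) next
    ss <- ss[order(match(conds, c("placebo", "atomoxetine")))]
    participants[[id]] <- lapply(ss, function(s) {
      est <- estimation_trials(s)
      est <- est[is.finite(est$estimate_pos), , drop = FALSE]
      list(condition = s$condition, target = est$target_pos,
           ball = est$ball_pos, estimate = est$estimate_pos)
    })
  }
  if (!length(participants)) {
    stop("no participants with exactly one placebo and one atomoxetine session", call. = FALSE)
  }
  n_trials <- vapply(participants, function(p) {
    sum(vapply(p, function(s) length(s$estimate), 0L))
  }, 0L)
  if (sum(n_trials) == 0L) stop("no estimation trials to fit", call. = FALSE)
  index <- do.call(rbind, lapply(names(participants), function(id) {
    do.call(rbind, lapply(participants[[id]], function(s) {
      if (!length(s$estimate)) return(NULL)
      data.frame(participant_id = id, condition = s$condition,
                 trial = seq_along(s$estimate), stringsAsFactors = FALSE)
    }))
  }))
  structure(list(participants = participants, ids = names(participants),
                 n = length(participants), n_trials = sum(n_trials),
                 index = index),
            class = "model_data")
}

# log density of N+(x; mu, tau^2) (positive-truncated normal)
ldtnorm_pos <- function(x, mu, tau) {
  if (x <= 0) return(-Inf)
  stats::dnorm(x, mu, tau, log = TRUE) -
    stats::pnorm(0, mu, tau, lower.tail = FALSE, log.p = TRUE)
}

# session-specific sds from a participant parameter row (named vector)
theta_session_sigmas <- function(th, condition) {
  sp <- th[["sigma_prior"]]
  se <- th[["sigma_evidence"]]
  if (condition == "atomoxetine") {
    sp <- sp + th[["delta_prior"]]
    se <- se + th[["delta_evidence"]]
  }
  c(sigma_prior = sp, sigma_evidence = se)
}

#' Build the hierarchical generative model
#'
#' Returns a joint log-density evaluator over group-level parameters,
#' participant-level parameters, and the observed estimation responses. The
#' per-trial likelihood is
#' `estimate ~ N(w * target + (1 - w) * (ball + x_shift), posterior_sd^2)`
#' with `w` and `posterior_sd` derived from the session-specific prior and
#' evidence sds (atomoxetine sessions add the delta offsets). Participant
#' parameters are drawn from group-level distributions: positive-truncated
#' normals for the sds, normals for the deltas and the shift. Restricted
#' variants structurally omit the corresponding delta parameters. Parameter
#' points implying a non-positive session sd receive `-Inf` log density
#' (a rejected region, not an error).
#'
#' @param variant One of `"full"`, `"prior_delta_only"`,
#'   `"evidence_delta_only"`, `"no_delta"`.
#' @param hyper A [hyper_prior_spec()].
#' @return An object of class `generative_model` with functions
#'   `log_density(theta, data)`, `pointwise_loglik(theta, data)` and
#'   `simulate_responses(theta, data)`. `theta` is a list with `group`
#'   (named list, per active family `mu_<family>` and `tau_<family>`) and
#'   `participants` (matrix, one row per participant, columns named by
#'   family; omitted-family columns are ignored and treated as 0).
#' @export
build_generative_model <- function(variant = c("full", "prior_delta_only",
                                               "evidence_delta_only", "no_delta"),
                                   hyper = hyper_prior_spec()) {
  variant <- match.arg(variant)
  stopifnot(inherits(hyper, "hyper_prior_spec"))
  fams <- variant_families(variant)

  # fills inactive delta columns with structural zeros
  theta_row <- function(theta, i) {
    th <- c(sigma_prior = 0, sigma_evidence = 0, delta_prior = 0,
            delta_evidence = 0, x_shift = 0)
    for (f in fams) th[[f]] <- theta$participants[i, f]
    th
  }

  group_log_prior <- function(group) {
    lp <- 0
    for (f in fams) {
      h <- hyper[[f]]
      mu <- group[[paste0("mu_", f)]]
      tau <- group[[paste0("tau_", f)]]
      if (tau <= 0) return(-Inf)
      lp <- lp + if (h$mean_positive) {
        ldtnorm_pos(mu, h$mean_loc, h$mean_scale)
      } else {
        stats::dnorm(mu, h$mean_loc, h$mean_scale, log = TRUE)
      }
      # half-normal on the group sd
      lp <- lp + stats::dnorm(tau, 0, h$sd_scale, log = TRUE) + log(2)
    }
    lp
  }

  participant_log_prior <- function(group, th) {
    lp <- 0
    for (f in fams) {
      mu <- group[[paste0("mu_", f)]]
      tau <- group[[paste0("tau_", f)]]
      lp <- lp + if (f %in% c("sigma_prior", "sigma_evidence")) {
        ldtnorm_pos(th[[f]], mu, tau)
      } else {
        stats::dnorm(th[[f]], mu, tau, log = TRUE)
      }
      if (!is.finite(lp)) return(-Inf)
    }
    lp
  }

  session_loglik <- function(th, s) {
    sg <- theta_session_sigmas(th, s$condition)
    if (sg[["sigma_prior"]] <= 0 || sg[["sigma_evidence"]] <= 0) return(-Inf)
    w <- prior_weighting(sg[["sigma_prior"]], sg[["sigma_evidence"]])
    psd <- posterior_sd(sg[["sigma_prior"]], sg[["sigma_evidence"]])
    mu <- w * s$target + (1 - w) * (s$ball + th[["x_shift"]])
    sum(stats::dnorm(s$estimate, mu, psd, log = TRUE))
  }

  log_density <- function(theta, data) {
    stopifnot(inherits(data, "model_data"))
    lp <- group_log_prior(theta$group)
    if (!is.finite(lp)) return(-Inf)
    for (i in seq_len(data$n)) {
      th <- theta_row(theta, i)
      lp <- lp + participant_log_prior(theta$group, th)
      if (!is.finite(lp)) return(-Inf)
      for (s in data$participants[[i]]) lp <- lp + session_loglik(th, s)
      if (!is.finite(lp)) return(-Inf)
    }
    lp
  }

  pointwise_loglik <- function(theta, data) {
    stopifnot(inherits(data, "model_data"))
    unlist(lapply(seq_len(data$n), function(i) {
      th <- theta_row(theta, i)
      unlist(lapply(data$participants[[i]], function(s) {
        if (!length(s$estimate)) return(numeric(0))
        sg <- theta_session_sigmas(th, s$condition)
        if (sg[["sigma_prior"]] <= 0 || sg[["sigma_evidence"]] <= 0) {
          return(rep(-Inf, length(s$estimate)))
        }
        w <- prior_weighting(sg[["sigma_prior"]], sg[["sigma_evidence"]])
        psd <- posterior_sd(sg[["sigma_prior"]], sg[["sigma_evidence"]])
        mu <- w * s$target + (1 - w) * (s$ball + th[["x_shift"]])
        stats::dnorm(s$estimate, mu, psd, log = TRUE)
      }))
    }), use.names = FALSE)
  }

  simulate_responses <- function(theta, data) {
    unlist(lapply(seq_len(data$n), function(i) {
      th <- theta_row(theta, i)
      unlist(lapply(data$participants[[i]], function(s) {
        if (!length(s$estimate)) return(numeric(0))
        sg <- theta_session_sigmas(th, s$condition)
        w <- prior_weighting(sg[["sigma_prior"]], sg[["sigma_evidence"]])
        psd <- posterior_sd(sg[["sigma_prior"]], sg[["sigma_evidence"]])
        mu <- w * s$target + (1 - w) * (s$ball + th[["x_shift"]])
        stats::rnorm(length(mu), mu, psd)
      }))
    }), use.names = FALSE)
  }

  structure(list(variant = variant, hyper = hyper, families = fams,
                 log_density = log_density,
                 pointwise_loglik = pointwise_loglik,
                 simulate_responses = simulate_responses),
            class = "generative_model")
}

#' @export
print.generative_model <- function(x, ...) {
  cat(sprintf("generative_model (variant '%s'): families %s\n",
              x$variant, paste(x$families, collapse = ", ")))
  invisible(x)
}
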