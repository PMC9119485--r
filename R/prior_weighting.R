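#' Z-score a session's estimation and performance errors
#'
#' Standardizes each variable to mean 0 and sd 1 within the session, using the
#' population (n) denominator. Estimation errors enter in option units and
#' performance errors in screen fractions, as recorded in the task;
#' standardization removes the unit mismatch before the slope fit.
#'
#' @param trials A trial table (only rows with `trial_type == "estimation"`
#'   are used) containing `estimation_error_options` and `performance_error`.
#' @return A data frame with columns `estimation_error_z` and
#'   `performance_error_z`.
#' @export
zscore_session_errors <- function(trials) {
  if (inherits(trials, "session_data")) trials <- trials$trials
  est <- trials[trials$trial_type == "estimation", , drop = FALSE]
  y <- est$estimation_error_options
  x <- est$performance_error
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  if (length(y) < 3) stop("degenerate session: fewer than 3 usable estimation trials", call. = FALSE)
  zpop <- function(v, nm) {
    s <- stats::sd(v) * sqrt((length(v) - 1) / length(v))
    if (!is.finite(s) || s == 0) {
      stop(sprintf("degenerate session: zero variance in %s", nm), call. = FALSE)
    }
    (v - mean(v)) / s
  }
  data.frame(estimation_error_z = zpop(y, "estimation error"),
             performance_error_z = zpop(x, "performance error"))
}

# Stack per-session (estimation error, performance error) pairs across
# sessions -- z-scored by default, or in common raw units (screen fractions)
# when standardize = FALSE; sessions with fewer than 3 usable trials are
# dropped with a warning.
stack_session_errors <- function(sessions, standardize = TRUE) {
  if (inherits(sessions, "cohort")) sessions <- sessions$sessions
  if (inherits(sessions, "session_data")) sessions <- list(sessions)
  raw_errors <- function(s) {
    est <- s$trials[s$trials$trial_type == "estimation", , drop = FALSE]
    y <- est$estimation_error_pos
    x <- est$performance_error
    keep <- is.finite(y) & is.finite(x)
    if (sum(keep) < 3) stop("degenerate session", call. = FALSE)
    data.frame(estimation_error_z = y[keep], performance_error_z = x[keep])
  }
  rows <- list(); dropped <- character(0)
  for (s in sessions) {
    sid <- sprintf("%s_%s", s$participant_id, s$condition)
    z <- tryCatch(
      if (standardize) zscore_session_errors(s) else raw_errors(s),
      error = function(e) NULL
    )
    if (is.null(z)) {
      dropped <- c(dropped, sid)
      next
    }
    z$session_id <- sid
    rows[[length(rows) + 1L]] <- z
  }
  if (length(dropped)) {
    warning("sessions omitted (fewer than 3 usable estimation trials or zero variance): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (!length(rows)) stop("no usable sessions", call. = FALSE)
  do.call(rbind, rows)
}

#' Estimate prior weighting from estimation-trial data
#'
#' Fits the linear relationship between z-scored estimation errors and
#' z-scored performance errors on estimation trials only; the prior weighting
#' estimate is the negative of the fitted slope. `method = "mixed"` fits one
#' no-intercept model with a random slope per session by REML (the study's
#' estimator; no fixed or random intercepts, matching the zero-intercept
#' structure enforced by z-scoring); `method = "per-session"` fits independent
#' no-intercept least squares per session, a transparent shrinkage-free
#' oracle. For z-scored no-intercept OLS the slope equals the Pearson
#' correlation of the two error series.
#'
#' With z-scoring the slope magnitude is carried by the ratio of the error
#' variabilities: a session with no response noise has correlation exactly
#' -1, so its estimate is 1 regardless of the generating weighting. The
#' `standardize = FALSE` mode regresses the raw errors in common units
#' (screen fractions), which recovers the slope directly and serves as an
#' unstandardized oracle.
#'
#' @param sessions A `cohort`, a list of `session_data`, or one session.
#' @param method `"mixed"` or `"per-session"`. The mixed method needs at
#'   least two sessions; with fewer it falls back to per-session least
#'   squares with a message.
#' @param standardize Z-score the error series per session first (the
#'   study's convention)?
#' @return A data frame of class `prior_weighting_estimate` with columns
#'   `session_id`, `w_hat`, `se`, `method`, `n_trials`, `out_of_range`
#'   (`TRUE` when `w_hat` falls outside `[0, 1]`; estimates are reported
#'   unclipped).
#' @export
estimate_prior_weighting <- function(sessions, method = c("mixed", "per-session"),
                                     standardize = TRUE) {
  method <- match.arg(method)
  dat <- stack_session_errors(sessions, standardize = standardize)
  dat$session_id <- factor(dat$session_id, levels = unique(dat$session_id))
  if (method == "mixed" && nlevels(dat$session_id) < 2L) {
    message("mixed method needs >= 2 sessions; using per-session least squares")
    method <- "per-session"
  }
  out <- if (method == "per-session") {
    do.call(rbind, lapply(split(dat, dat$session_id), function(d) {
      x <- d$performance_error_z; y <- d$estimation_error_z
      slope <- sum(x * y) / sum(x^2)
      res <- y - slope * x
      se <- sqrt(sum(res^2) / (length(x) - 1) / sum(x^2))
      data.frame(session_id = as.character(d$session_id[1]), w_hat = -slope,
                 se = se, n_trials = length(x), stringsAsFactors = FALSE)
    }))
  } else {
    fit <- lme4::lmer(
      estimation_error_z ~ 0 + performance_error_z + (0 + performance_error_z | session_id),
      data = dat, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")
    )
    fe <- lme4::fixef(fit)[["performance_error_z"]]
    fe_var <- as.numeric(stats::vcov(fit)["performance_error_z", "performance_error_z"])
    re <- lme4::ranef(fit, condVar = TRUE)$session_id
    cv <- attr(re, "postVar")
    slopes <- fe + re[["performance_error_z"]]
    ses <- sqrt(fe_var + as.numeric(cv[1, 1, ]))
    nt <- as.integer(table(dat$session_id)[rownames(re)])
    data.frame(session_id = rownames(re), w_hat = -slopes, se = ses,
               n_trials = nt, stringsAsFactors = FALSE)
  }
  out$method <- method
  out$out_of_range <- out$w_hat < 0 | out$w_hat > 1
  rownames(out) <- NULL
  class(out) <- c("prior_weighting_estimate", "data.frame")
  out
}

#' Predicted estimation-error quantile bands
#'
#' Under the observer model the predicted estimation error for a given
#' performance error `e` is distributed `N(-w * e, posterior_sd^2)`. Returns
#' the median and the central 25% and 50% quantile bands for each input.
#'
#' @param w Prior weighting in \eqn{[0, 1]}.
#' @param performance_errors Numeric vector (screen fractions).
#' @param posterior_sd Posterior sd (>= 0).
#' @return A data frame with columns `performance_error`, `median`,
#'   `lo25`, `hi25`, `lo50`, `hi50`.
#' @export
predict_estimation_quantiles <- function(w, performance_errors, posterior_sd) {
  stopifnot(w >= 0, w <= 1, posterior_sd >= 0)
  m <- -w * performance_errors
  q <- function(p) m + stats::qnorm(p) * posterior_sd
  data.frame(performance_error = performance_errors, median = m,
             lo25 = q(0.375), hi25 = q(0.625),
             lo50 = q(0.25), hi50 = q(0.75))
}

#' Observer parameters that generate a given prior weighting
#'
#' Maps a generating prior weighting to observer sds such that the variance of
#' the estimation errors matches the variance of the performance errors, the
#' regime in which the standardized slope estimator is unbiased (and which
#' matches the study's empirical error variabilities, both about 6.8% of
#' screen width): `sigma_evidence^2 = (1 + w) * motor_noise_sd^2` and
#' `sigma_prior^2 = sigma_evidence^2 * (1 - w) / w`.
#'
#' @param w Generating prior weighting in \eqn{[0, 1]}.
#' @param motor_noise_sd Motor noise sd (screen fractions).
#' @return An [observer_params()].
#' @export
recovery_observer_params <- function(w, motor_noise_sd = 0.068) {
  stopifnot(w >= 0, w <= 1)
  se <- motor_noise_sd * sqrt(1 + w)
  sp <- se * sqrt((1 - min(max(w, 1e-9), 1 - 1e-9)) / min(max(w, 1e-9), 1 - 1e-9))
  observer_params(sigma_prior = sp, sigma_evidence = se,
                  motor_noise_sd = motor_noise_sd)
}

#' Parameter-recovery study for the slope estimator
#'
#' For each generating prior weighting on a grid, simulates `n_sims` sessions
#' under the default task design, estimates prior weighting per session, and
#' tabulates the median and 95% quantile interval of the estimates. Generating
#' parameters come from [recovery_observer_params()].
#'
#' @param w_grid Generating prior weightings in \eqn{[0, 1]}.
#' @param design A [task_design()].
#' @param n_sims Simulated sessions per grid point (>= 100).
#' @param seed Master seed.
#' @param discretize Snap responses to the 12-option grid (the realistic
#'   mode)?
#' @param motor_noise_sd Motor noise sd for the generator.
#' @return A list of class `recovery_table` with elements `table` (data frame:
#'   `w_generating`, `median_w_hat`, `q2.5`, `q97.5`, `n_sims`) and
#'   `deviations` (matrix of `w_hat - w_generating`, `n_sims` rows).
#' @export
run_parameter_recovery <- function(w_grid = seq(0.1, 0.9, by = 0.1),
                                   design = task_design(), n_sims = 2000L,
                                   seed = 1L, discretize = TRUE,
                                   motor_noise_sd = 0.068) {
  stopifnot(all(w_grid >= 0), all(w_grid <= 1), n_sims >= 100)
  with_seed(seed, {
    dev <- matrix(NA_real_, nrow = n_sims, ncol = length(w_grid))
    what <- matrix(NA_real_, nrow = n_sims, ncol = length(w_grid))
    for (j in seq_along(w_grid)) {
      op <- recovery_observer_params(w_grid[j], motor_noise_sd)
      for (k in seq_len(n_sims)) {
        ses <- simulate_session(op, design, "none", discretize = discretize)
        est <- estimate_prior_weighting(list(ses), method = "per-session")
        what[k, j] <- est$w_hat[1]
      }
      dev[, j] <- what[, j] - w_grid[j]
    }
    tab <- data.frame(
      w_generating = w_grid,
      median_w_hat = apply(what, 2, stats::median),
      q2.5 = apply(what, 2, stats::quantile, probs = 0.025),
      q97.5 = apply(what, 2, stats::quantile, probs = 0.975),
      n_sims = n_sims
    )
    structure(list(table = tab, deviations = dev), class = "recovery_table")
  })
}

#' @export
print.recovery_table <- function(x, ...) {
  cat("Parameter recovery of prior weighting\n")
  print(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}
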