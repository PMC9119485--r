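#' Simulate one testing session of the visuomotor task
#'
#' Generates a full session of trials for a single observer. The
#' force-to-position physics is not simulated: the ball's final position is
#' drawn directly as `target + N(0, motor_noise_sd^2)`, which is
#' observationally equivalent for every downstream analysis. On estimation
#' trials the response is drawn from the observer's posterior over the final
#' ball position: `N(w * target + (1 - w) * (ball + x_shift), posterior_sd^2)`
#' with `w` and `posterior_sd` given by the session-specific prior and
#' evidence sds (the atomoxetine session applies the delta offsets). By
#' default the response is then snapped to the nearest option of a freshly
#' drawn 12-option grid (ties toward the lower index, clamped to the grid);
#' `discretize = FALSE` keeps the continuous response for oracle analyses.
#'
#' `evidence_noise = TRUE` additionally draws an explicit sensory-evidence
#' sample `s = ball + x_shift + N(0, sigma_evidence^2)` and centres the
#' posterior on it; the default (`FALSE`) matches the likelihood of the
#' hierarchical model, in which the evidence distribution is centred on the
#' true final ball position.
#'
#' @param params An [observer_params()].
#' @param design A [task_design()].
#' @param condition One of `"none"`, `"placebo"`, `"atomoxetine"`.
#' @param seed Optional integer seed.
#' @param discretize Snap estimation responses to the response grid?
#' @param evidence_noise Draw an explicit sensory-evidence sample?
#' @param participant_id,group,session_order Metadata carried into the result.
#' @return An object of class `session_data`: a list with the trial table
#'   (`$trials`), the generating parameters, the session-specific true prior
#'   weighting (`$w_true`) and posterior sd, and metadata.
#' @export
simulate_session <- function(params, design = task_design(),
                             condition = c("none", "placebo", "atomoxetine"),
                             seed = NULL, discretize = TRUE,
                             evidence_noise = FALSE,
                             participant_id = "obs01", group = "control",
                             session_order = 1L) {
  stopifnot(inherits(params, "observer_params"), inherits(design, "task_design"))
  condition <- match.arg(condition)
  sig <- session_sigmas(params, condition)
  w <- prior_weighting(sig$sigma_prior, sig$sigma_evidence)
  psd <- posterior_sd(sig$sigma_prior, sig$sigma_evidence)

  with_seed(seed, {
    sq <- generate_trial_sequence(design)
    n <- nrow(sq)
    target <- sq$effort
    ball <- pmin(pmax(target + stats::rnorm(n, 0, params$motor_noise_sd), 0), 1)
    perf_err <- ball - target

    est <- sq$trial_type == "estimation"
    veridical <- chosen <- rep(NA_integer_, n)
    estimate_pos <- est_opt <- est_pos_err <- grid_first <- rep(NA_real_, n)
    grid_clamped <- rep(NA, n)
    spacing <- design$grid_width_frac / design$n_response_options

    for (i in which(est)) {
      g <- build_estimation_grid(ball[i], design)
      centre <- if (evidence_noise) {
        ball[i] + params$x_shift + stats::rnorm(1, 0, sig$sigma_evidence)
      } else {
        ball[i] + params$x_shift
      }
      xhat <- w * target[i] + (1 - w) * centre
      raw <- stats::rnorm(1, xhat, psd)
      veridical[i] <- g$veridical_index
      grid_first[i] <- g$centres[1]
      grid_clamped[i] <- g$clamped
      if (discretize) {
        chosen[i] <- snap_to_grid(raw, g)
        estimate_pos[i] <- g$centres[chosen[i]]
        est_opt[i] <- chosen[i] - g$veridical_index
      } else {
        estimate_pos[i] <- raw
        est_opt[i] <- (raw - g$centres[g$veridical_index]) / spacing
      }
      est_pos_err[i] <- estimate_pos[i] - ball[i]
    }

    trials <- data.frame(
      index = sq$trial, block = sq$block, trial_type = sq$trial_type,
      effort = sq$effort, reward = sq$reward,
      target_pos = target, ball_pos = ball, performance_error = perf_err,
      grid_first_centre = grid_first, grid_spacing = ifelse(est, spacing, NA_real_),
      grid_clamped = grid_clamped,
      veridical_index = veridical, chosen_index = chosen,
      estimate_pos = estimate_pos,
      estimation_error_options = est_opt,
      estimation_error_pos = est_pos_err,
      stringsAsFactors = FALSE
    )
    structure(
      list(participant_id = participant_id, group = group,
           condition = condition, session_order = as.integer(session_order),
           trials = trials, params = params, w_true = w, posterior_sd = psd,
           discretize = discretize, seed = seed),
      class = "session_data"
    )
  })
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf("session_data: %s (%s, %s), %d trials (%d estimation), true w = %.3f\n",
              x$participant_id, x$group, x$condition, nrow(x$trials),
              sum(x$trials$trial_type == "estimation"), x$w_true))
  invisible(x)
}

#' Estimation trials of a session
#'
#' @param session A `session_data` object.
#' @return The subset of the trial table with `trial_type == "estimation"`.
#' @export
estimation_trials <- function(session) {
  stopifnot(inherits(session, "session_data"))
  session$trials[session$trials$trial_type == "estimation", , drop = FALSE]
}

#' Interquartile range of force error for a session
#'
#' Force error in percentage points equals 100 times the performance error in
#' screen fractions (target position and required relative force coincide by
#' design).
#'
#' @param session A `session_data` object.
#' @return IQR of force error in percentage points.
#' @export
force_error_iqr <- function(session) {
  stopifnot(inherits(session, "session_data"))
  unname(diff(stats::quantile(100 * session$trials$performance_error,
                              c(0.25, 0.75), names = FALSE)))
}

# positive-truncated normal draws (rejection; cheap at the scales used here)
rtrunc_pos <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a full study cohort
#'
#' Draws a cohort with the statistical structure the downstream analyses
#' assume: controls complete one session without drug; Parkinson's disease
#' participants complete a placebo and an atomoxetine session with order
#' counterbalanced in blocks of six (three of each order per block, as in the
#' study). Participant-level observer parameters are drawn from the group
#' hyperparameters and then adjusted so that (a) prior weighting decreases
#' with apathy at the standardized slope `coupling_apathy_w`, and (b) the
#' drug-induced change in prior weighting decreases with locus coeruleus CNR
#' at standardized slope `coupling_cnr_delta`. All randomness flows from the
#' master seed via per-session derived streams recorded in the output.
#'
#' @param cohort A [cohort_config()].
#' @param hyper A [group_hyper_params()].
#' @param design A [task_design()].
#' @param seed Master integer seed.
#' @param discretize Passed to [simulate_session()].
#' @return An object of class `cohort`: a list with `sessions` (list of
#'   `session_data`), `covariates` (one row per session, including the true
#'   per-session prior weighting), `params` (one row per participant with the
#'   generating observer parameters) and the seed.
#' @export
simulate_cohort <- function(cohort = cohort_config(),
                            hyper = group_hyper_params(),
                            design = task_design(), seed = 1L,
                            discretize = TRUE) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(hyper, "group_hyper_params"))
  with_seed(seed, {
    n_pd <- cohort$n_pd
    n_co <- cohort$n_controls
    n <- n_pd + n_co
    ids <- c(sprintf("pd%02d", seq_len(n_pd)), sprintf("co%02d", seq_len(n_co)))
    group <- rep(c("PD", "control"), c(n_pd, n_co))

    apathy <- round(clip(stats::rnorm(
      n,
      ifelse(group == "PD", cohort$apathy_mean_pd, cohort$apathy_mean_control),
      ifelse(group == "PD", cohort$apathy_sd_pd, cohort$apathy_sd_control)
    ), 0, 42))
    lc_cnr <- stats::rnorm(n, cohort$cnr_mean, cohort$cnr_sd)
    ledd <- ifelse(group == "PD", pmax(stats::rnorm(n, cohort$ledd_mean, cohort$ledd_sd), 0), NA_real_)
    updrs <- ifelse(group == "PD", pmax(stats::rnorm(n, cohort$updrs_mean, cohort$updrs_sd), 0), NA_real_)

    sigma_e <- rtrunc_pos(n, hyper$mu_sigma_evidence, hyper$sd_sigma_evidence)
    x_shift <- stats::rnorm(n, hyper$mu_xshift, hyper$sd_xshift)

    # With a zero coupling the parameters come straight from the group-level
    # distributions (the hierarchy the inference model assumes); a non-zero
    # coupling instead targets the prior weighting on the scale of the
    # reported group summaries and back-solves the sds, which induces the
    # requested standardized association.
    c_aw <- cohort$coupling_apathy_w
    if (c_aw == 0) {
      sigma_p <- rtrunc_pos(n, hyper$mu_sigma_prior, hyper$sd_sigma_prior)
      w1 <- prior_weighting(sigma_p, sigma_e)
    } else {
      z_ap <- if (n > 1 && stats::sd(apathy) > 0) as.numeric(scale(apathy)) else rep(0, n)
      w_mean <- ifelse(group == "PD", cohort$w_mean_pd, cohort$w_mean_control)
      w_sd <- ifelse(group == "PD", cohort$w_sd_pd, cohort$w_sd_control)
      w1 <- clip(w_mean + w_sd * (c_aw * z_ap + sqrt(1 - c_aw^2) * stats::rnorm(n)),
                 0.03, 0.97)
      sigma_p <- sigma_e * sqrt((1 - w1) / w1)
    }

    # drug-induced change in w coupled to LC CNR within the PD group
    delta_p <- delta_e <- rep(0, n)
    w2 <- rep(NA_real_, n)
    if (n_pd > 0) {
      pd <- seq_len(n_pd)
      c_cd <- cohort$coupling_cnr_delta
      if (c_cd == 0 && cohort$dw_sd == 0) {
        # pure hierarchy draws, truncated to keep the drug-session sds positive
        dp <- stats::rnorm(n_pd, hyper$mu_delta_prior, hyper$sd_delta_prior)
        bad <- which(sigma_p[pd] + dp <= 0)
        while (length(bad)) {
          dp[bad] <- stats::rnorm(length(bad), hyper$mu_delta_prior, hyper$sd_delta_prior)
          bad <- bad[sigma_p[pd][bad] + dp[bad] <= 0]
        }
        de <- stats::rnorm(n_pd, hyper$mu_delta_evidence, hyper$sd_delta_evidence)
        bad <- which(sigma_e[pd] + de <= 0)
        while (length(bad)) {
          de[bad] <- stats::rnorm(length(bad), hyper$mu_delta_evidence, hyper$sd_delta_evidence)
          bad <- bad[sigma_e[pd][bad] + de[bad] <= 0]
        }
        delta_p[pd] <- dp
        delta_e[pd] <- de
        w2[pd] <- prior_weighting(sigma_p[pd] + dp, sigma_e[pd] + de)
      } else {
        z_cnr <- if (n_pd > 1 && stats::sd(lc_cnr[pd]) > 0) as.numeric(scale(lc_cnr[pd])) else rep(0, n_pd)
        dw <- cohort$dw_mean +
          cohort$dw_sd * (c_cd * z_cnr + sqrt(1 - c_cd^2) * stats::rnorm(n_pd))
        w2[pd] <- clip(w1[pd] + dw, 0.03, 0.97)
        de <- stats::rnorm(n_pd, hyper$mu_delta_evidence, hyper$sd_delta_evidence)
        bad <- which(sigma_e[pd] + de <= 0)
        tries <- 0L
        while (length(bad)) { # truncate the tail draws; give up only if the
          tries <- tries + 1L # configuration makes positivity implausible
          if (tries > 1000L) {
            stop("impossible coupling configuration: drug-session evidence sd not positive", call. = FALSE)
          }
          de[bad] <- stats::rnorm(length(bad), hyper$mu_delta_evidence, hyper$sd_delta_evidence)
          bad <- bad[sigma_e[pd][bad] + de[bad] <= 0]
        }
        delta_e[pd] <- de
        se2 <- sigma_e[pd] + delta_e[pd]
        sp2 <- se2 * sqrt((1 - w2[pd]) / w2[pd])
        delta_p[pd] <- sp2 - sigma_p[pd]
      }
    }

    params <- data.frame(
      participant_id = ids, group = group,
      sigma_prior = sigma_p, sigma_evidence = sigma_e,
      delta_prior = delta_p, delta_evidence = delta_e, x_shift = x_shift,
      apathy = apathy, lc_cnr = lc_cnr, ledd = ledd, updrs_iii = updrs,
      w_placebo = w1, w_atomoxetine = w2,
      delta_w = w2 - w1,
      stringsAsFactors = FALSE
    )

    # counterbalanced drug order in blocks of six (three per order)
    order_first <- character(n_pd)
    k <- 1L
    while (k <= n_pd) {
      m <- min(6L, n_pd - k + 1L)
      half <- sample(rep_len(c("placebo", "atomoxetine"), 2L * ceiling(m / 2)))[seq_len(m)]
      order_first[k:(k + m - 1L)] <- half
      k <- k + m
    }

    n_sessions <- 2L * n_pd + n_co
    session_seeds <- sample.int(.Machine$integer.max - 1L, n_sessions)

    sessions <- vector("list", n_sessions)
    cov_rows <- vector("list", n_sessions)
    s <- 0L
    for (i in seq_len(n)) {
      op <- observer_params(sigma_prior = sigma_p[i], sigma_evidence = sigma_e[i],
                            delta_prior = delta_p[i], delta_evidence = delta_e[i],
                            x_shift = x_shift[i])
      conds <- if (group[i] == "PD") {
        first <- order_first[i]
        c(first, setdiff(c("placebo", "atomoxetine"), first))
      } else "none"
      for (j in seq_along(conds)) {
        s <- s + 1L
        ses <- simulate_session(op, design, conds[j], seed = session_seeds[s],
                                discretize = discretize,
                                participant_id = ids[i], group = group[i],
                                session_order = j)
        sessions[[s]] <- ses
        cov_rows[[s]] <- data.frame(
          session_id = sprintf("%s_%s", ids[i], conds[j]),
          participant_id = ids[i], group = group[i], condition = conds[j],
          session_order = j, apathy = apathy[i], lc_cnr = lc_cnr[i],
          ledd = ledd[i], updrs_iii = updrs[i],
          w_true = ses$w_true, posterior_sd = ses$posterior_sd,
          perf_error_iqr = force_error_iqr(ses),
          seed = session_seeds[s],
          stringsAsFactors = FALSE
        )
      }
    }
    covariates <- do.call(rbind, cov_rows)
    rownames(covariates) <- NULL
    structure(list(sessions = sessions, covariates = covariates,
                   params = params, config = cohort, hyper = hyper,
                   design = design, seed = seed),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d sessions (%d PD x 2 + %d controls), master seed %s\n",
              length(x$sessions), x$config$n_pd, x$config$n_controls,
              format(x$seed)))
  invisible(x)
}

#' Write a cohort to CSV files with a JSON metadata sidecar
#'
#' Writes one trials table (one row per trial, with session identifiers), one
#' covariate table (one row per session) and a JSON sidecar echoing the
#' configuration and all seeds.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trials <- do.call(rbind, lapply(cohort$sessions, function(s) {
    cbind(session_id = sprintf("%s_%s", s$participant_id, s$condition),
          participant_id = s$participant_id, group = s$group,
          condition = s$condition, s$trials, stringsAsFactors = FALSE)
  }))
  paths <- c(trials = file.path(dir, "trials.csv"),
             covariates = file.path(dir, "covariates.csv"),
             metadata = file.path(dir, "metadata.json"))
  utils::write.csv(trials, paths[["trials"]], row.names = FALSE)
  utils::write.csv(cohort$covariates, paths[["covariates"]], row.names = FALSE)
  meta <- list(seed = cohort$seed,
               session_seeds = cohort$covariates$seed,
               config = unclass(cohort$config), hyper = unclass(cohort$hyper),
               design = unclass(cohort$design))
  jsonlite::write_json(meta, paths[["metadata"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a cohort's tables back from disk
#'
#' @param dir Directory written by [write_cohort()].
#' @return A list with `trials`, `covariates` and `metadata`.
#' @export
read_cohort_tables <- function(dir) {
  list(trials = utils::read.csv(file.path(dir, "trials.csv")),
       covariates = utils::read.csv(file.path(dir, "covariates.csv")),
       metadata = jsonlite::read_json(file.path(dir, "metadata.json"),
                                      simplifyVector = TRUE))
}
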