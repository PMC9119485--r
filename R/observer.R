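#' Observer parameters for the Gaussian cue-combination model
#'
#' A participant-session observer combines a Gaussian prior centred on the
#' target (sd `sigma_prior`) with Gaussian sensory evidence centred on the
#' final ball position (sd `sigma_evidence`, optionally shifted by `x_shift`).
#' Atomoxetine-induced changes are additive offsets `delta_prior` and
#' `delta_evidence` applied to the standard deviations in the drug session.
#' `motor_noise_sd` is generator-only: the sd of the ball's final position
#' around the target, standing in for the force-to-position physics.
#' All quantities are in screen-width fractions.
#'
#' @param sigma_prior Prior sd (> 0).
#' @param sigma_evidence Sensory-evidence sd (> 0).
#' @param delta_prior,delta_evidence Drug-induced additive changes.
#' @param x_shift Consistent spatial shift of the sensory evidence.
#' @param motor_noise_sd Sd of the ball position around the target (> 0).
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(sigma_prior, sigma_evidence,
                            delta_prior = 0, delta_evidence = 0,
                            x_shift = 0, motor_noise_sd = 0.068) {
  if (sigma_prior <= 0 || sigma_evidence <= 0 || motor_noise_sd <= 0) {
    stop("sigma_prior, sigma_evidence and motor_noise_sd must be positive", call. = FALSE)
  }
  structure(list(sigma_prior = sigma_prior, sigma_evidence = sigma_evidence,
                 delta_prior = delta_prior, delta_evidence = delta_evidence,
                 x_shift = x_shift, motor_noise_sd = motor_noise_sd),
            class = "observer_params")
}

#' Prior weighting implied by prior and evidence standard deviations
#'
#' The precision of the prior relative to total precision:
#' \eqn{w = \sigma^2_{evidence} / (\sigma^2_{evidence} + \sigma^2_{prior})}.
#'
#' @param sigma_prior,sigma_evidence Standard deviations (> 0).
#' @return Prior weighting in (0, 1).
#' @export
prior_weighting <- function(sigma_prior, sigma_evidence) {
  sigma_evidence^2 / (sigma_evidence^2 + sigma_prior^2)
}

#' Posterior standard deviation of the combined estimate
#'
#' \eqn{\sigma_{\hat{x}} = \sqrt{\sigma^2_e \sigma^2_p / (\sigma^2_e + \sigma^2_p)}}.
#'
#' @inheritParams prior_weighting
#' @return Posterior sd in the same units as the inputs.
#' @export
posterior_sd <- function(sigma_prior, sigma_evidence) {
  sqrt(sigma_evidence^2 * sigma_prior^2 / (sigma_evidence^2 + sigma_prior^2))
}

# Session-specific sds under a drug condition (additive deltas on atomoxetine)
session_sigmas <- function(params, condition) {
  sp <- params$sigma_prior
  se <- params$sigma_evidence
  if (identical(condition, "atomoxetine")) {
    sp <- sp + params$delta_prior
    se <- se + params$delta_evidence
  }
  if (sp <= 0 || se <= 0) {
    stop("invalid drug configuration: session-specific sd is not positive", call. = FALSE)
  }
  list(sigma_prior = sp, sigma_evidence = se)
}

#' Group-level hyperparameters for the synthetic cohort
#'
#' Participant-level observer parameters are drawn from these group
#' distributions: positive-truncated normals for the sds, normals for the
#' drug deltas and the evidence shift. Defaults give a mean prior weighting
#' near the study's placebo value (~0.45) with realistic spread, and
#' estimation noise comparable to the reported estimation-error variability
#' (~6.8% of screen width).
#'
#' @param mu_sigma_prior,sd_sigma_prior Group mean/sd of the prior sd.
#' @param mu_sigma_evidence,sd_sigma_evidence Group mean/sd of the evidence sd.
#' @param mu_delta_prior,sd_delta_prior Group mean/sd of the drug effect on
#'   the prior sd.
#' @param mu_delta_evidence,sd_delta_evidence Group mean/sd of the drug effect
#'   on the evidence sd.
#' @param mu_xshift,sd_xshift Group mean/sd of the evidence shift.
#' @return An object of class `group_hyper_params`.
#' @export
group_hyper_params <- function(mu_sigma_prior = 0.090, sd_sigma_prior = 0.020,
                               mu_sigma_evidence = 0.082, sd_sigma_evidence = 0.018,
                               mu_delta_prior = 0, sd_delta_prior = 0.020,
                               mu_delta_evidence = 0, sd_delta_evidence = 0.015,
                               mu_xshift = 0, sd_xshift = 0.010) {
  h <- list(mu_sigma_prior = mu_sigma_prior, sd_sigma_prior = sd_sigma_prior,
            mu_sigma_evidence = mu_sigma_evidence, sd_sigma_evidence = sd_sigma_evidence,
            mu_delta_prior = mu_delta_prior, sd_delta_prior = sd_delta_prior,
            mu_delta_evidence = mu_delta_evidence, sd_delta_evidence = sd_delta_evidence,
            mu_xshift = mu_xshift, sd_xshift = sd_xshift)
  sds <- h[grepl("^sd_", names(h))]
  if (any(unlist(sds) <= 0)) stop("all group sds must be positive", call. = FALSE)
  structure(h, class = "group_hyper_params")
}

#' Cohort configuration for the synthetic crossover study
#'
#' Describes the simulated study population: group sizes, covariate
#' distributions, and the two generative couplings the analysis is designed to
#' detect -- a negative association between apathy and prior weighting, and a
#' negative association between locus coeruleus CNR and the drug-induced
#' change in prior weighting. Defaults reproduce the study's cohort: 17
#' participants with Parkinson's disease tested twice (placebo/atomoxetine
#' crossover) and 20 controls tested once, Apathy Scale distributions matched
#' to the reported group summaries, and coupling strengths equal to the
#' reported standardized effects.
#'
#' @param n_pd,n_controls Group sizes.
#' @param apathy_mean_pd,apathy_sd_pd,apathy_mean_control,apathy_sd_control
#'   Apathy Scale distributions per group (scores are rounded and clipped to
#'   the instrument range 0--42).
#' @param cnr_mean,cnr_sd Locus coeruleus CNR distribution (arbitrary units).
#' @param ledd_mean,ledd_sd Levodopa-equivalent daily dose distribution
#'   (mg/day, clipped at 0; PD only).
#' @param updrs_mean,updrs_sd UPDRS-III motor score distribution (PD only).
#' @param w_mean_pd,w_sd_pd,w_mean_control,w_sd_control Prior-weighting
#'   distributions per group.
#' @param dw_mean,dw_sd Distribution of the drug-induced change in prior
#'   weighting (atomoxetine minus placebo).
#' @param coupling_apathy_w Standardized slope linking apathy to prior
#'   weighting (negative in the study).
#' @param coupling_cnr_delta Standardized slope linking LC CNR to the
#'   drug-induced change in prior weighting (the study reports r = -0.59).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_pd = 17L, n_controls = 20L,
                          apathy_mean_pd = 12.68, apathy_sd_pd = 5.77,
                          apathy_mean_control = 10.58, apathy_sd_control = 5.09,
                          cnr_mean = 15, cnr_sd = 3,
                          ledd_mean = 659.94, ledd_sd = 514.90,
                          updrs_mean = 27.94, updrs_sd = 12.05,
                          w_mean_pd = 0.45, w_sd_pd = 0.26,
                          w_mean_control = 0.48, w_sd_control = 0.21,
                          dw_mean = 0, dw_sd = 0.27,
                          coupling_apathy_w = -0.35,
                          coupling_cnr_delta = -0.59) {
  stopifnot(n_pd >= 0, n_controls >= 0,
            is.finite(coupling_apathy_w), is.finite(coupling_cnr_delta),
            abs(coupling_apathy_w) <= 1, abs(coupling_cnr_delta) <= 1)
  structure(list(n_pd = as.integer(n_pd), n_controls = as.integer(n_controls),
                 apathy_mean_pd = apathy_mean_pd, apathy_sd_pd = apathy_sd_pd,
                 apathy_mean_control = apathy_mean_control,
                 apathy_sd_control = apathy_sd_control,
                 cnr_mean = cnr_mean, cnr_sd = cnr_sd,
                 ledd_mean = ledd_mean, ledd_sd = ledd_sd,
                 updrs_mean = updrs_mean, updrs_sd = updrs_sd,
                 w_mean_pd = w_mean_pd, w_sd_pd = w_sd_pd,
                 w_mean_control = w_mean_control, w_sd_control = w_sd_control,
                 dw_mean = dw_mean, dw_sd = dw_sd,
                 coupling_apathy_w = coupling_apathy_w,
                 coupling_cnr_delta = coupling_cnr_delta),
            class = "cohort_config")
}
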