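zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a zero-variance variable", call. = FALSE)
  (x - mean(x)) / s
}

tidy_lm <- function(fit) {
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), beta = sm[, 1], se = sm[, 2],
             t = sm[, 3], df = fit$df.residual, p = sm[, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Regression of prior weighting on apathy, group and their interaction
#'
#' Ordinary least squares on one row per session (controls plus the
#' Parkinson's placebo sessions): prior weighting regressed on apathy, group,
#' their interaction, and the interquartile range of performance error as a
#' covariate of no interest. Continuous variables are z-scored and the group
#' factor receives sum-to-zero contrasts, so coefficients are standardized
#' betas.
#'
#' @param data Data frame with columns `w` (prior weighting estimate),
#'   `apathy`, `group` (two levels), `perf_iqr`.
#' @return A `regression_result` data frame (term, beta, se, t, df, p).
#' @export
regress_apathy <- function(data) {
  stopifnot(all(c("w", "apathy", "group", "perf_iqr") %in% names(data)))
  d <- data.frame(w = zscore(data$w), apathy = zscore(data$apathy),
                  group = factor(data$group), perf_iqr = zscore(data$perf_iqr))
  stats::contrasts(d$group) <- stats::contr.sum(nlevels(d$group))
  fit <- stats::lm(w ~ apathy * group + perf_iqr, data = d)
  if (fit$rank < length(stats::coef(fit))) {
    alias <- names(which(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear terms: ", paste(alias, collapse = ", "),
         call. = FALSE)
  }
  out <- tidy_lm(fit)
  attr(out, "fit") <- fit
  class(out) <- c("regression_result", "data.frame")
  out
}

#' Mixed model of prior weighting by drug condition and locus coeruleus CNR
#'
#' Fits the crossover drug analysis: prior weighting (both sessions of each
#' Parkinson's participant) on drug condition, LC CNR and their interaction,
#' with the interquartile range of performance error as covariate of no
#' interest and a random participant intercept. Continuous variables are
#' z-scored and the drug factor sum-to-zero coded. Per-term F tests use
#' Satterthwaite denominator degrees of freedom. Also returns each
#' participant's drug-induced change in prior weighting and its correlation
#' with LC CNR.
#'
#' @param data Data frame with columns `participant_id`, `condition`
#'   (`"placebo"`/`"atomoxetine"`), `w`, `lc_cnr`, `perf_iqr`.
#' @return A list of class `drug_cnr_result`: `coefficients` (standardized
#'   betas with t statistics), `anova` (per-term F, df, p), `delta_w` (per
#'   participant), `correlation` (r, df, p between delta-w and CNR).
#' @export
fit_drug_cnr_model <- function(data) {
  stopifnot(all(c("participant_id", "condition", "w", "lc_cnr", "perf_iqr") %in% names(data)))
  cnt <- table(data$participant_id)
  if (any(cnt != 2)) {
    bad <- names(cnt)[cnt != 2]
    warning("participants without both sessions excluded: ",
            paste(bad, collapse = ", "), call. = FALSE)
    data <- data[!data$participant_id %in% bad, , drop = FALSE]
  }
  # performance variability enters as a participant-level trait covariate
  # (mean over the two sessions); this reproduces the crossover's degrees of
  # freedom: within-participant effects (drug, drug x CNR) on n - 2, the
  # between-participant CNR effect on n - 3
  iqr_p <- stats::ave(data$perf_iqr, data$participant_id)
  d <- data.frame(
    id = factor(data$participant_id),
    drug = factor(data$condition, levels = c("placebo", "atomoxetine")),
    w = zscore(data$w), cnr = zscore(data$lc_cnr), perf_iqr = zscore(iqr_p)
  )
  stats::contrasts(d$drug) <- stats::contr.sum(2)
  fit <- lmerTest::lmer(w ~ drug * cnr + perf_iqr + (1 | id), data = d,
                        control = lme4::lmerControl(check.conv.singular = "ignore"))
  sm <- stats::coef(summary(fit))
  coefs <- data.frame(term = rownames(sm), beta = sm[, "Estimate"],
                      se = sm[, "Std. Error"], df = sm[, "df"],
                      t = sm[, "t value"], p = sm[, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  anova_df <- data.frame(term = rownames(an), F = an[, "F value"],
                         df1 = an[, "NumDF"], df2 = an[, "DenDF"],
                         p = an[, "Pr(>F)"], row.names = NULL,
                         stringsAsFactors = FALSE)
  wide <- stats::reshape(data[, c("participant_id", "condition", "w")],
                         idvar = "participant_id", timevar = "condition",
                         direction = "wide")
  dw <- wide$w.atomoxetine - wide$w.placebo
  cnr_p <- data$lc_cnr[match(wide$participant_id, data$participant_id)]
  r <- stats::cor(dw, cnr_p)
  dfr <- length(dw) - 2L
  tr <- r * sqrt(dfr) / sqrt(1 - r^2)
  structure(list(
    coefficients = coefs, anova = anova_df,
    delta_w = data.frame(participant_id = wide$participant_id, delta_w = dw,
                         lc_cnr = cnr_p, stringsAsFactors = FALSE),
    correlation = list(r = r, df = dfr, t = tr,
                       p = 2 * stats::pt(-abs(tr), dfr)),
    fit = fit
  ), class = "drug_cnr_result")
}

#' @export
print.drug_cnr_result <- function(x, ...) {
  cat("Drug x LC CNR mixed model (Satterthwaite F tests)\n")
  print(format(x$anova, digits = 3), row.names = FALSE)
  cat(sprintf("cor(delta w, LC CNR): r(%d) = %.3f, p = %.4f\n",
              x$correlation$df, x$correlation$r, x$correlation$p))
  invisible(x)
}

#' Pitman's test of equality of variance for paired data
#'
#' Tests whether two paired samples have equal variances via the correlation
#' between their sums and differences: `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' with `n - 2` degrees of freedom, two-sided.
#'
#' @param x,y Equal-length paired numeric vectors (n >= 3).
#' @return A list of class `pitman_test` with `statistic` (t), `df`,
#'   `p.value` and `estimate` (the sum-difference correlation).
#' @export
pitman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("Pitman's test needs at least 3 pairs", call. = FALSE)
  s <- x + y; d <- x - y
  if (stats::sd(s) == 0 || stats::sd(d) == 0) {
    stop("degenerate input: zero variance in sums or differences", call. = FALSE)
  }
  r <- stats::cor(s, d)
  df <- n - 2L
  t <- r * sqrt(df) / sqrt(1 - r^2)
  structure(list(statistic = t, df = df, p.value = 2 * stats::pt(-abs(t), df),
                 estimate = r, n = n),
            class = "pitman_test")
}

#' @export
print.pitman_test <- function(x, ...) {
  cat(sprintf("Pitman paired-variance test: t(%d) = %.3f, p = %.4f (r = %.3f)\n",
              x$df, x$statistic, x$p.value, x$estimate))
  invisible(x)
}

#' Johnson-Neyman region of significance for a moderated slope
#'
#' Given a regression with a focal slope and a focal-by-moderator interaction,
#' solves for the moderator values at which the conditional slope
#' `b_focal + b_int * z` crosses the two-sided significance boundary
#' `|slope / se(slope)| = t_crit(alpha, df)` (a quadratic in `z`). Thresholds
#' are returned in moderator z units and, if moderator statistics are given,
#' in raw units. A discriminant with no real roots yields a region that is
#' either the entire moderator range or empty, depending on the sign of the
#' quadratic.
#'
#' @param fit Either an `lm`/`lmerMod` fit or a list with elements `coef`
#'   (named vector), `vcov` (named matrix) and `df`.
#' @param focal Name of the focal predictor term.
#' @param interaction Name of the interaction term.
#' @param alpha Two-sided significance level.
#' @param moderator_mean,moderator_sd Raw-unit statistics of the moderator
#'   used only to report thresholds on the instrument scale.
#' @return An object of class `jn_region`: `thresholds_z`, `thresholds_raw`,
#'   `region` (`"inside"`, `"outside"`, `"all"` or `"none"`: where the slope
#'   is significant relative to the thresholds), `alpha`, `df`.
#' @export
johnson_neyman <- function(fit, focal, interaction, alpha = 0.05,
                           moderator_mean = 0, moderator_sd = 1) {
  if (is.list(fit) && !inherits(fit, c("lm", "lmerMod"))) {
    b <- fit$coef; V <- fit$vcov; df <- fit$df
  } else {
    b <- stats::coef(fit); V <- as.matrix(stats::vcov(fit)); df <- stats::df.residual(fit)
  }
  stopifnot(all(c(focal, interaction) %in% names(b)))
  b1 <- b[[focal]]; b3 <- b[[interaction]]
  v11 <- V[focal, focal]; v13 <- V[focal, interaction]; v33 <- V[interaction, interaction]
  tc2 <- stats::qt(1 - alpha / 2, df)^2
  # significant where (b1 + b3 z)^2 - tc2 * (v11 + 2 v13 z + v33 z^2) > 0
  A <- b3^2 - tc2 * v33
  B <- 2 * (b1 * b3 - tc2 * v13)
  C <- b1^2 - tc2 * v11
  disc <- B^2 - 4 * A * C
  qval <- function(z) (b1 + b3 * z)^2 - tc2 * (v11 + 2 * v13 * z + v33 * z^2)
  if (abs(A) < .Machine$double.eps^0.75) {
    # linear (or constant) boundary
    if (abs(B) < .Machine$double.eps^0.75) {
      region <- if (C > 0) "all" else "none"
      z <- numeric(0)
    } else {
      z <- -C / B
      region <- if (qval(z + 1) > 0) "above" else "below"
    }
  } else if (disc < 0) {
    z <- numeric(0)
    region <- if (A > 0) "all" else "none"
  } else {
    z <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
    region <- if (A > 0) "outside" else "inside"
  }
  structure(list(thresholds_z = unname(z),
                 thresholds_raw = unname(moderator_mean + moderator_sd * z),
                 region = region, alpha = alpha, df = df,
                 coef = c(focal = b1, interaction = b3)),
            class = "jn_region")
}

#' @export
print.jn_region <- function(x, ...) {
  cat(sprintf("Johnson-Neyman region (alpha = %g, df = %d): slope significant %s",
              x$alpha, x$df, x$region))
  if (length(x$thresholds_z)) {
    cat(sprintf(" [z thresholds: %s; raw: %s]",
                paste(round(x$thresholds_z, 3), collapse = ", "),
                paste(round(x$thresholds_raw, 2), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Repeated-measures ANCOVA of the drug effects on the two precision terms
#'
#' Tests whether the drug effect on prior weighting relates differently to
#' the drug effect on the prior sd than to the drug effect on the evidence
#' sd: a long-format model with within-subject factor precision-term (prior
#' vs. sensory evidence), between-subject covariate delta-w, and their
#' interaction, fitted with an `Error(participant)` stratum. The interaction
#' F has 1 and n - 2 degrees of freedom. The two delta-sd variables are
#' standardized by default before the within-subject contrast.
#'
#' @param delta_sigma_prior,delta_sigma_evidence,delta_w One value per
#'   participant.
#' @param standardize Z-score the two delta-sd variables first?
#' @return A list of class `ancova_result` with `F`, `df1`, `df2`, `p` for
#'   the precision-term by delta-w interaction, and the full `aov` tables.
#' @export
precision_term_ancova <- function(delta_sigma_prior, delta_sigma_evidence,
                                  delta_w, standardize = TRUE) {
  keep <- stats::complete.cases(delta_sigma_prior, delta_sigma_evidence, delta_w)
  if (!all(keep)) {
    warning(sum(!keep), " participants with missing values excluded", call. = FALSE)
  }
  dsp <- delta_sigma_prior[keep]; dse <- delta_sigma_evidence[keep]
  dw <- delta_w[keep]
  n <- length(dw)
  if (n < 3) stop("need at least 3 complete participants", call. = FALSE)
  if (standardize) {
    dsp <- zscore(dsp); dse <- zscore(dse)
  }
  long <- data.frame(
    id = factor(rep(seq_len(n), 2)),
    term = factor(rep(c("prior", "evidence"), each = n), levels = c("prior", "evidence")),
    dw = rep(dw, 2),
    value = c(dsp, dse)
  )
  fit <- stats::aov(value ~ dw * term + Error(id), data = long)
  within <- summary(fit)[["Error: Within"]][[1]]
  row <- grep("dw:term", rownames(within))
  structure(list(F = within[row, "F value"], df1 = within[row, "Df"],
                 df2 = within["Residuals", "Df"],
                 p = within[row, "Pr(>F)"],
                 tables = summary(fit), n = n),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("precision-term x delta-w interaction: F(%d, %d) = %.3f, p = %.4f\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Plausible-values analysis of the precision decomposition
#'
#' Propagates posterior uncertainty in the participant-level drug effects:
#' for each posterior draw, correlates the drawn delta-sd values (prior and
#' evidence) with the observed drug effect on prior weighting across
#' participants, and summarizes the two correlation distributions and the
#' distribution of their difference.
#'
#' @param delta_prior_draws,delta_evidence_draws Matrices, draws x
#'   participants, aligned column-wise.
#' @param delta_w One observed drug effect on prior weighting per participant.
#' @return A list of class `plausible_values` with the per-draw data frame
#'   (`r_prior`, `r_evidence`, `diff`) and a `summary` of central 95%
#'   intervals.
#' @export
plausible_values <- function(delta_prior_draws, delta_evidence_draws, delta_w) {
  stopifnot(is.matrix(delta_prior_draws), is.matrix(delta_evidence_draws),
            ncol(delta_prior_draws) == length(delta_w),
            ncol(delta_evidence_draws) == length(delta_w),
            nrow(delta_prior_draws) == nrow(delta_evidence_draws))
  if (length(delta_w) < 3) stop("need at least 3 participants", call. = FALSE)
  r1 <- apply(delta_prior_draws, 1, stats::cor, y = delta_w)
  r2 <- apply(delta_evidence_draws, 1, stats::cor, y = delta_w)
  per_draw <- data.frame(r_prior = r1, r_evidence = r2, diff = r1 - r2)
  ci <- function(v) stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
  summ <- data.frame(
    quantity = c("r_prior", "r_evidence", "difference"),
    lo95 = c(ci(r1)[1], ci(r2)[1], ci(r1 - r2)[1]),
    median = c(ci(r1)[2], ci(r2)[2], ci(r1 - r2)[2]),
    hi95 = c(ci(r1)[3], ci(r2)[3], ci(r1 - r2)[3])
  )
  structure(list(per_draw = per_draw, summary = summ), class = "plausible_values")
}

#' @export
print.plausible_values <- function(x, ...) {
  cat("Plausible-values correlations (central 95% intervals)\n")
  print(format(x$summary, digits = 3), row.names = FALSE)
  invisible(x)
}

#' BIC approximation to an inclusion Bayes factor
#'
#' Approximate Bayes factor for including a model term, from the BIC
#' difference of the models with and without it:
#' `BF ~= exp((BIC_reduced - BIC_full) / 2)`. A coarse substitute for Bayes
#' factors obtained by model averaging; flagged as an approximation in the
#' output.
#'
#' @param full,reduced Fitted models with a `BIC` method, `reduced` nested in
#'   `full`.
#' @return A list with `bf10` and `approximation = "BIC"`.
#' @export
bic_inclusion_bf <- function(full, reduced) {
  list(bf10 = exp((stats::BIC(reduced) - stats::BIC(full)) / 2),
       approximation = "BIC")
}
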