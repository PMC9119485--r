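make_apathy_data <- function(cohort) {
  est <- estimate_prior_weighting(cohort, method = "per-session")
  cov <- merge(est, cohort$covariates, by = "session_id")
  base <- cov[cov$condition %in% c("none", "placebo"), ]
  data.frame(w = base$w_hat, apathy = base$apathy, group = base$group,
             perf_iqr = base$perf_error_iqr)
}

test_that("apathy regression has the study's degrees of freedom and structure", {
  ch <- simulate_cohort(seed = 51)
  fit <- regress_apathy(make_apathy_data(ch))
  expect_equal(nrow(fit), 5L) # intercept, apathy, group, iqr, interaction
  expect_equal(unique(fit$df), 37L - 5L)
  expect_true(all(fit$p >= 0 & fit$p <= 1))
})

test_that("apathy regression t statistics are invariant to affine covariate rescaling", {
  ch <- simulate_cohort(seed = 52)
  d <- make_apathy_data(ch)
  f1 <- regress_apathy(d)
  d2 <- d
  d2$apathy <- 5 * d2$apathy - 3
  d2$perf_iqr <- 0.1 * d2$perf_iqr + 2
  f2 <- regress_apathy(d2)
  expect_equal(f1$t, f2$t, tolerance = 1e-10)
})

test_that("apathy regression is calibrated under the null and recovers the coupling", {
  n_sim <- 120
  cover <- logical(n_sim)
  for (k in seq_len(n_sim)) {
    ch <- simulate_cohort(cohort_config(coupling_apathy_w = 0), seed = 3000 + k)
    fit <- regress_apathy(make_apathy_data(ch))
    b <- fit[fit$term == "apathy", ]
    cover[k] <- abs(b$beta) <= 2 * b$se
  }
  expect_gte(mean(cover), 0.88)
  betas <- vapply(seq_len(60), function(k) {
    ch <- simulate_cohort(seed = 4000 + k)
    fit <- regress_apathy(make_apathy_data(ch))
    fit$beta[fit$term == "apathy"]
  }, 0)
  # attenuated relative to the generative -0.35 by estimation noise in w,
  # but clearly negative and in its vicinity
  expect_lt(mean(betas), -0.15)
  expect_gt(mean(betas), -0.5)
})

test_that("rank deficiency is reported as a singularity error", {
  d <- data.frame(w = rnorm(10), apathy = rep(1:5, 2),
                  group = rep(c("PD", "control"), each = 5), perf_iqr = rnorm(10))
  d$apathy <- ave(seq_len(10), d$group) # constant within group -> collinear
  d2 <- d
  d2$perf_iqr <- d2$apathy
  expect_error(regress_apathy(d2), "collinear|zero-variance")
})

make_drug_data <- function(cohort) {
  est <- estimate_prior_weighting(cohort, method = "per-session")
  cov <- merge(est, cohort$covariates, by = "session_id")
  pd <- cov[cov$condition %in% c("placebo", "atomoxetine"), ]
  data.frame(participant_id = pd$participant_id, condition = pd$condition,
             w = pd$w_hat, lc_cnr = pd$lc_cnr, perf_iqr = pd$perf_error_iqr)
}

test_that("drug x CNR mixed model reproduces the crossover degrees of freedom", {
  ch <- simulate_cohort(seed = 61)
  fit <- fit_drug_cnr_model(make_drug_data(ch))
  an <- fit$anova
  expect_equal(an$df1, rep(1, nrow(an)))
  inter <- an[an$term == "drug:cnr", ]
  expect_equal(round(inter$df2), 15)
  drug <- an[an$term == "drug", ]
  expect_equal(round(drug$df2), 15)
  cnr <- an[an$term == "cnr", ]
  expect_equal(round(cnr$df2), 14)
  expect_equal(fit$correlation$df, 15L)
  expect_equal(nrow(fit$delta_w), 17L)
})

test_that("drug x CNR interaction is calibrated under the null", {
  hits <- vapply(seq_len(150), function(k) {
    ch <- simulate_cohort(cohort_config(n_controls = 0, coupling_cnr_delta = 0),
                          seed = 5000 + k)
    fit <- fit_drug_cnr_model(make_drug_data(ch))
    fit$anova$p[fit$anova$term == "drug:cnr"] < 0.05
  }, TRUE)
  expect_lt(mean(hits), 0.12)
})

test_that("the default coupling yields a mostly-negative delta-w/CNR correlation", {
  rs <- vapply(seq_len(60), function(k) {
    ch <- simulate_cohort(cohort_config(n_controls = 0), seed = 6000 + k)
    fit_drug_cnr_model(make_drug_data(ch))$correlation$r
  }, 0)
  expect_gte(mean(rs < 0), 0.95)
})

test_that("participants with a single session are excluded with a warning", {
  ch <- simulate_cohort(cohort_config(n_pd = 5, n_controls = 0), seed = 3)
  d <- make_drug_data(ch)
  d <- d[-1, ]
  expect_warning(fit <- fit_drug_cnr_model(d), "excluded")
  expect_equal(nrow(fit$delta_w), 4L)
})

test_that("Pitman's test matches its formula and degrees of freedom", {
  set.seed(7)
  x <- rnorm(17); y <- 0.5 * x + rnorm(17, sd = 2)
  out <- pitman_test(x, y)
  expect_equal(out$df, 15L)
  r <- cor(x + y, x - y)
  expect_equal(out$statistic, r * sqrt(15) / sqrt(1 - r^2))
  expect_equal(out$p.value, 2 * pt(-abs(out$statistic), 15))
  expect_error(pitman_test(x[1:2], y[1:2]), "at least 3")
  expect_error(pitman_test(rep(1, 5), rep(1, 5)), "zero variance")
})

test_that("Pitman's test has nominal type-I error and detects unequal variances", {
  set.seed(11)
  n_sim <- 4000
  rej <- logical(n_sim)
  for (k in seq_len(n_sim)) {
    z1 <- rnorm(17); z2 <- rnorm(17)
    x <- z1
    y <- 0.5 * z1 + sqrt(0.75) * z2 # correlated, equal variance
    rej[k] <- pitman_test(x, y)$p.value < 0.05
  }
  expect_gt(mean(rej), 0.035)
  expect_lt(mean(rej), 0.065)
  # power case matches a direct Monte-Carlo of the same statistic
  pow <- mean(vapply(seq_len(1500), function(k) {
    z1 <- rnorm(17); z2 <- rnorm(17)
    x <- z1
    y <- 2 * (0.5 * z1 + sqrt(0.75) * z2) # sd ratio 2, correlation 0.5
    pitman_test(x, y)$p.value < 0.05
  }, TRUE))
  expect_gt(pow, 0.5)
})

test_that("Johnson-Neyman regions cover the trivial and oracle cases", {
  # a model with no interaction term at all (coefficient and variance zero):
  # the conditional slope is constant in the moderator
  V <- diag(c(0.01, 0))
  dimnames(V) <- list(c("cnr", "cnr:apathy"), c("cnr", "cnr:apathy"))
  fit <- list(coef = c(cnr = 1, `cnr:apathy` = 0), vcov = V, df = 15)
  expect_equal(johnson_neyman(fit, "cnr", "cnr:apathy")$region, "all")
  fit$coef <- c(cnr = 0.01, `cnr:apathy` = 0)
  expect_equal(johnson_neyman(fit, "cnr", "cnr:apathy")$region, "none")
})

test_that("Johnson-Neyman thresholds agree with a dense grid search", {
  set.seed(21)
  for (k in 1:100) {
    A <- matrix(rnorm(4, sd = 0.1), 2)
    V <- crossprod(A) + diag(1e-4, 2)
    dimnames(V) <- list(c("f", "i"), c("f", "i"))
    fit <- list(coef = c(f = rnorm(1, 0, 0.5), i = rnorm(1, 0, 0.5)),
                vcov = V, df = sample(10:40, 1))
    jn <- johnson_neyman(fit, "f", "i")
    zg <- seq(-6, 6, by = 1e-3)
    tstat <- abs(fit$coef["f"] + fit$coef["i"] * zg) /
      sqrt(V["f", "f"] + 2 * zg * V["f", "i"] + zg^2 * V["i", "i"])
    sig <- tstat >= qt(0.975, fit$df)
    if (length(jn$thresholds_z)) {
      # grid sign changes should bracket each analytic threshold
      flips <- zg[which(diff(sig) != 0)]
      inrange <- jn$thresholds_z[jn$thresholds_z > -6 & jn$thresholds_z < 6]
      for (th in inrange) expect_lt(min(abs(flips - th)), 1e-2)
    } else {
      expect_true(all(sig) == (jn$region == "all"))
      expect_true(all(!sig) == (jn$region == "none"))
    }
  }
})

test_that("JN thresholds are mapped back to instrument units", {
  V <- matrix(c(0.04, 0.001, 0.001, 0.02), 2,
              dimnames = list(c("f", "i"), c("f", "i")))
  fit <- list(coef = c(f = -0.3, i = -0.4), vcov = V, df = 13)
  jn <- johnson_neyman(fit, "f", "i", moderator_mean = 11.6, moderator_sd = 5.5)
  expect_equal(jn$thresholds_raw, 11.6 + 5.5 * jn$thresholds_z)
})

test_that("precision-term ANCOVA equals the difference-regression identity", {
  set.seed(31)
  n <- 17
  dw <- rnorm(n)
  dsp <- -0.6 * dw + rnorm(n, sd = 0.5)
  dse <- rnorm(n, sd = 0.5)
  out <- precision_term_ancova(dsp, dse, dw, standardize = FALSE)
  expect_equal(out$df1, 1L)
  expect_equal(out$df2, n - 2L)
  # interaction F equals t^2 from regressing the within-subject difference
  # on the covariate (halved difference since the contrast is 2-level)
  t2 <- summary(lm(I(dsp - dse) ~ dw))$coefficients["dw", "t value"]^2
  expect_equal(out$F, t2, tolerance = 1e-8)
  # identical drug effects on both terms -> no differential relationship:
  # the interaction sum of squares vanishes (the F ratio is then 0/0)
  out0 <- precision_term_ancova(dsp, dsp, dw, standardize = FALSE)
  within0 <- out0$tables[["Error: Within"]][[1]]
  expect_lt(within0[grep("dw:term", rownames(within0)), "Sum Sq"], 1e-20)
})

test_that("precision-term ANCOVA interaction is calibrated under the null", {
  set.seed(41)
  rej <- vapply(seq_len(4000), function(k) {
    dw <- rnorm(17)
    precision_term_ancova(rnorm(17), rnorm(17), dw)$p < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.035)
  expect_lt(mean(rej), 0.065)
})

test_that("plausible values reduce to plain correlations for point-mass posteriors", {
  set.seed(51)
  dw <- rnorm(17)
  dsp <- -0.5 * dw + rnorm(17, sd = 0.4)
  dse <- rnorm(17)
  pv <- plausible_values(matrix(rep(dsp, 10), 10, byrow = TRUE),
                         matrix(rep(dse, 10), 10, byrow = TRUE), dw)
  expect_equal(unique(pv$per_draw$r_prior), cor(dsp, dw))
  expect_equal(unique(pv$per_draw$r_evidence), cor(dse, dw))
  # a variable against itself has an identically-zero difference distribution
  pv2 <- plausible_values(matrix(rep(dsp, 10), 10, byrow = TRUE),
                          matrix(rep(dsp, 10), 10, byrow = TRUE), dw)
  expect_true(all(pv2$per_draw$diff == 0))
  expect_error(plausible_values(matrix(1, 2, 2), matrix(1, 2, 2), c(1, 2)),
               "at least 3")
})
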