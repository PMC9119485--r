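test_that("error fields obey their defining identities in every simulated session", {
  ch <- simulate_cohort(cohort_config(n_pd = 2, n_controls = 2), seed = 8)
  for (s in ch$sessions) {
    tr <- s$trials
    expect_equal(tr$performance_error, tr$ball_pos - tr$target_pos)
    est <- tr[tr$trial_type == "estimation", ]
    expect_equal(est$estimation_error_options,
                 est$chosen_index - est$veridical_index)
    basic <- tr[tr$trial_type == "basic", ]
    expect_true(all(is.na(basic$chosen_index)))
    expect_true(all(is.na(basic$estimate_pos)))
    expect_true(all(is.finite(est$estimate_pos)))
  }
})

test_that("limiting observers collapse onto evidence or prior", {
  d <- task_design()
  # evidence dominates: w -> 0
  op <- observer_params(sigma_prior = 10, sigma_evidence = 1e-6,
                        x_shift = 0, motor_noise_sd = 0.05)
  s <- simulate_session(op, d, "none", seed = 2, discretize = FALSE)
  est <- estimation_trials(s)
  expect_lt(max(abs(est$estimate_pos - est$ball_pos)), 1e-4)
  # prior dominates: w -> 1
  op <- observer_params(sigma_prior = 1e-6, sigma_evidence = 10,
                        x_shift = 0, motor_noise_sd = 0.05)
  s <- simulate_session(op, d, "none", seed = 2, discretize = FALSE)
  est <- estimation_trials(s)
  expect_lt(max(abs(est$estimate_pos - est$target_pos)), 1e-4)
})

test_that("continuous-mode responses regress on performance error with slope -w", {
  op <- recovery_observer_params(0.6)
  set.seed(5)
  # many estimation trials via an enlarged design
  s <- simulate_session(op, task_design(n_blocks = 150), "none", seed = 7,
                        discretize = FALSE)
  est <- estimation_trials(s)
  expect_gt(nrow(est), 1000)
  slope <- coef(lm(estimation_error_pos ~ 0 + performance_error, data = est))[[1]]
  expect_lt(abs(slope - (-0.6)), 0.05)
})

test_that("continuous responses given (target, ball) match the closed-form posterior", {
  # pin the ball to the target so every estimation trial shares its geometry,
  # then compare the response distribution to N(x_hat, posterior_sd^2)
  op <- observer_params(sigma_prior = 0.06, sigma_evidence = 0.05,
                        x_shift = 0.01, motor_noise_sd = 1e-9)
  w <- prior_weighting(0.06, 0.05)
  psd <- posterior_sd(0.06, 0.05)
  s <- simulate_session(op, task_design(n_blocks = 80), "none", seed = 13,
                        discretize = FALSE)
  est <- estimation_trials(s)
  for (target in c(0.35, 0.65)) {
    x <- est$estimate_pos[est$target_pos == target]
    expect_gt(length(x), 300)
    xhat <- w * target + (1 - w) * (target + op$x_shift)
    expect_gt(ks.test(x, pnorm, mean = xhat, sd = psd)$p.value, 0.01)
  }
})

test_that("default cohort reproduces the crossover bookkeeping", {
  ch <- simulate_cohort(seed = 21)
  expect_length(ch$sessions, 54L)
  expect_equal(nrow(ch$covariates), 54L)
  pd <- ch$covariates[ch$covariates$group == "PD", ]
  expect_equal(nrow(pd), 34L)
  expect_setequal(unique(pd$condition), c("placebo", "atomoxetine"))
  # counterbalanced order: half of each six-block starts with placebo
  first <- pd$condition[pd$session_order == 1]
  expect_equal(sum(first[1:6] == "placebo"), 3L)
  expect_equal(sum(first[7:12] == "placebo"), 3L)
  co <- ch$covariates[ch$covariates$group == "control", ]
  expect_true(all(co$condition == "none"))
  expect_true(all(ch$params$apathy >= 0 & ch$params$apathy <= 42))
  expect_true(all(ch$params$apathy == round(ch$params$apathy)))
})

test_that("null couplings leave covariates uncorrelated with the generative weights", {
  ch <- simulate_cohort(
    cohort_config(n_pd = 100, n_controls = 100,
                  coupling_apathy_w = 0, coupling_cnr_delta = 0),
    seed = 5
  )
  p <- ch$params
  expect_lt(abs(cor(p$apathy, p$w_placebo)), 0.15)
  pd <- p[p$group == "PD", ]
  expect_lt(abs(cor(pd$lc_cnr, pd$delta_w)), 0.15)
})

test_that("default couplings generate the intended negative associations", {
  r_aw <- r_cd <- numeric(40)
  for (k in seq_len(40)) {
    ch <- simulate_cohort(seed = 100 + k)
    p <- ch$params
    r_aw[k] <- cor(p$apathy, p$w_placebo)
    pd <- p[p$group == "PD", ]
    r_cd[k] <- cor(pd$lc_cnr, pd$delta_w)
  }
  # mean sample correlations near the generative targets; bounding w to
  # (0.03, 0.97) attenuates the drug coupling somewhat
  expect_lt(abs(mean(r_aw) - (-0.35)), 0.06)
  expect_lt(abs(mean(r_cd) - (-0.59)), 0.07)
})

test_that("zero deltas make the two drug sessions exchangeable", {
  hyper <- group_hyper_params(sd_delta_prior = 1e-9, sd_delta_evidence = 1e-9,
                              mu_delta_prior = 0, mu_delta_evidence = 0)
  ch <- simulate_cohort(cohort_config(n_pd = 12, n_controls = 0, dw_sd = 1e-9,
                                      coupling_cnr_delta = 0),
                        hyper = hyper, seed = 9)
  est <- estimate_prior_weighting(ch, method = "per-session")
  cov <- ch$covariates
  w_p <- est$w_hat[match(cov$session_id[cov$condition == "placebo"], est$session_id)]
  w_a <- est$w_hat[match(cov$session_id[cov$condition == "atomoxetine"], est$session_id)]
  # paired label-permutation test on the mean difference
  obs <- mean(w_a - w_p)
  set.seed(1)
  null <- replicate(999, mean((w_a - w_p) * sample(c(-1, 1), length(w_p), TRUE)))
  p <- mean(abs(null) >= abs(obs))
  expect_gt(p, 0.05)
})

test_that("impossible drug configurations raise domain errors", {
  op <- observer_params(sigma_prior = 0.05, sigma_evidence = 0.05,
                        delta_evidence = -0.06)
  expect_error(simulate_session(op, condition = "atomoxetine"), "not positive")
  expect_error(observer_params(sigma_prior = -1, sigma_evidence = 0.05), "positive")
  hyper <- group_hyper_params(mu_delta_evidence = -0.2, sd_delta_evidence = 1e-6)
  expect_error(
    simulate_cohort(cohort_config(n_pd = 5, n_controls = 0), hyper = hyper, seed = 2),
    "not positive"
  )
})

test_that("cohorts round-trip through CSV with byte-identical reruns", {
  dir1 <- tempfile(); dir2 <- tempfile()
  write_cohort(simulate_cohort(cohort_config(n_pd = 2, n_controls = 2), seed = 4), dir1)
  write_cohort(simulate_cohort(cohort_config(n_pd = 2, n_controls = 2), seed = 4), dir2)
  for (f in c("trials.csv", "covariates.csv")) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
  back <- read_cohort_tables(dir1)
  expect_equal(nrow(back$covariates), 6L)
  expect_equal(back$metadata$seed, 4L)
  expect_equal(sum(back$trials$trial_type == "estimation"), 6L * 40L)
})
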