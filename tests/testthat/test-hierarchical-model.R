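one_trial_data <- function(target = 0.4, ball = 0.5, estimate = 0.46) {
  trials1 <- data.frame(trial_type = "estimation", target_pos = target,
                        ball_pos = ball, estimate_pos = estimate)
  mk <- function(cond) structure(
    list(participant_id = "pd01", group = "PD", condition = cond,
         session_order = 1L,
         trials = cbind(trials1, index = 1, block = 1, effort = target,
                        reward = "off")),
    class = "session_data")
  prepare_model_data(list(mk("placebo"), mk("atomoxetine")))
}

simple_theta <- function(ids, sp = 0.08, se = 0.07, dp = 0.01, de = -0.005,
                         xs = 0.002) {
  list(group = list(mu_sigma_prior = 0.09, tau_sigma_prior = 0.02,
                    mu_sigma_evidence = 0.08, tau_sigma_evidence = 0.02,
                    mu_delta_prior = 0, tau_delta_prior = 0.02,
                    mu_delta_evidence = 0, tau_delta_evidence = 0.02,
                    mu_x_shift = 0, tau_x_shift = 0.01),
       participants = matrix(rep(c(sp, se, dp, de, xs), each = length(ids)),
                             nrow = length(ids),
                             dimnames = list(ids, c("sigma_prior", "sigma_evidence",
                                                    "delta_prior", "delta_evidence",
                                                    "x_shift"))))
}

test_that("the joint log density matches a hand computation for one participant", {
  md <- one_trial_data()
  m <- build_generative_model("full")
  th <- simple_theta(md$ids)
  got <- m$log_density(th, md)

  # manual arithmetic: hyperpriors + participant priors + two Gaussian trials
  half_norm <- function(x, s) dnorm(x, 0, s, log = TRUE) + log(2)
  tnorm <- function(x, m_, s) dnorm(x, m_, s, log = TRUE) -
    pnorm(0, m_, s, lower.tail = FALSE, log.p = TRUE)
  g <- th$group
  expected <- tnorm(g$mu_sigma_prior, 0, 0.2) + half_norm(g$tau_sigma_prior, 0.1) +
    tnorm(g$mu_sigma_evidence, 0, 0.2) + half_norm(g$tau_sigma_evidence, 0.1) +
    dnorm(g$mu_delta_prior, 0, 0.1, log = TRUE) + half_norm(g$tau_delta_prior, 0.1) +
    dnorm(g$mu_delta_evidence, 0, 0.1, log = TRUE) + half_norm(g$tau_delta_evidence, 0.1) +
    dnorm(g$mu_x_shift, 0, 0.1, log = TRUE) + half_norm(g$tau_x_shift, 0.1) +
    tnorm(0.08, g$mu_sigma_prior, g$tau_sigma_prior) +
    tnorm(0.07, g$mu_sigma_evidence, g$tau_sigma_evidence) +
    dnorm(0.01, 0, g$tau_delta_prior, log = TRUE) +
    dnorm(-0.005, 0, g$tau_delta_evidence, log = TRUE) +
    dnorm(0.002, 0, g$tau_x_shift, log = TRUE)
  lik1 <- {
    w <- 0.07^2 / (0.07^2 + 0.08^2)
    psd <- sqrt(0.07^2 * 0.08^2 / (0.07^2 + 0.08^2))
    dnorm(0.46, w * 0.4 + (1 - w) * (0.5 + 0.002), psd, log = TRUE)
  }
  lik2 <- {
    sp <- 0.08 + 0.01; se <- 0.07 - 0.005
    w <- se^2 / (se^2 + sp^2)
    psd <- sqrt(se^2 * sp^2 / (se^2 + sp^2))
    dnorm(0.46, w * 0.4 + (1 - w) * (0.5 + 0.002), psd, log = TRUE)
  }
  expect_equal(got, expected + lik1 + lik2, tolerance = 1e-10)
})

test_that("restricted variants ignore their structurally absent deltas", {
  md <- one_trial_data()
  m <- build_generative_model("no_delta")
  th1 <- simple_theta(md$ids, dp = 0.5, de = -0.02)
  th2 <- simple_theta(md$ids, dp = -0.3, de = 0.04)
  expect_equal(m$log_density(th1, md), m$log_density(th2, md))
  mp <- build_generative_model("prior_delta_only")
  th3 <- simple_theta(md$ids, de = 0.9)
  th4 <- simple_theta(md$ids, de = -0.9)
  expect_equal(mp$log_density(th3, md), mp$log_density(th4, md))
})

test_that("equal prior and evidence sds imply w = 0.5 inside the evaluator", {
  md <- one_trial_data(target = 0.4, ball = 0.5, estimate = 0.455)
  m <- build_generative_model("no_delta")
  th <- simple_theta(md$ids, sp = 0.06, se = 0.06, dp = 0, de = 0, xs = 0)
  ll <- m$pointwise_loglik(th, md)
  psd <- sqrt(0.06^2 / 2)
  expect_equal(ll[1], dnorm(0.455, 0.5 * 0.4 + 0.5 * 0.5, psd, log = TRUE))
})

test_that("non-positive session sds give -Inf log density, not an error", {
  md <- one_trial_data()
  m <- build_generative_model("full")
  th <- simple_theta(md$ids, sp = 0.05, dp = -0.06)
  expect_equal(m$log_density(th, md), -Inf)
})

test_that("the observer posterior matches brute-force integration of the Gaussian product", {
  # 1-D grid integration of prior x likelihood for one trial
  sp <- 0.07; se <- 0.05; target <- 0.38; ball <- 0.52
  grid <- seq(-0.5, 1.5, length.out = 200001)
  post <- dnorm(grid, target, sp) * dnorm(ball, grid, se)
  post <- post / sum(post)
  mean_oracle <- sum(grid * post)
  sd_oracle <- sqrt(sum((grid - mean_oracle)^2 * post))
  w <- prior_weighting(sp, se)
  expect_equal(w * target + (1 - w) * ball, mean_oracle, tolerance = 1e-6)
  expect_equal(posterior_sd(sp, se), sd_oracle, tolerance = 1e-6)
})

test_that("duplicating every trial duplicates pointwise columns and doubles the total", {
  ch <- small_pd_cohort(n_pd = 2, seed = 5)
  md <- prepare_model_data(ch)
  m <- build_generative_model("full")
  th <- simple_theta(md$ids)
  ll <- m$pointwise_loglik(th, md)
  expect_length(ll, md$n_trials)
  doubled <- lapply(ch$sessions, function(s) {
    est <- s$trials[s$trials$trial_type == "estimation", ]
    s$trials <- rbind(s$trials, est)
    s
  })
  md2 <- prepare_model_data(doubled)
  ll2 <- m$pointwise_loglik(th, md2)
  expect_equal(sum(ll2), 2 * sum(ll), tolerance = 1e-10)
  expect_equal(length(ll2), 2 * length(ll))
})

test_that("prior-pushforward simulation yields finite densities and w spanning (0,1)", {
  md <- prepare_model_data(small_pd_cohort(n_pd = 3, seed = 9))
  m <- build_generative_model("full")
  hy <- hyper_prior_spec()
  set.seed(4)
  ws <- c()
  for (k in 1:200) {
    g <- list()
    for (f in priorweight:::model_families) {
      h <- hy[[f]]
      mu <- if (h$mean_positive) abs(rnorm(1, h$mean_loc, h$mean_scale)) else
        rnorm(1, h$mean_loc, h$mean_scale)
      g[[paste0("mu_", f)]] <- mu
      g[[paste0("tau_", f)]] <- abs(rnorm(1, 0, h$sd_scale)) + 1e-4
    }
    pm <- sapply(priorweight:::model_families, function(f) {
      mu <- g[[paste0("mu_", f)]]; tau <- g[[paste0("tau_", f)]]
      if (f %in% c("sigma_prior", "sigma_evidence")) {
        v <- rnorm(1, mu, tau)
        while (v <= 0) v <- rnorm(1, mu, tau)
        v
      } else rnorm(1, mu, tau)
    })
    pm <- matrix(rep(pm, each = md$n), nrow = md$n,
                 dimnames = list(md$ids, priorweight:::model_families))
    th <- list(group = g, participants = pm)
    drug_ok <- all(pm[, "sigma_prior"] + pm[, "delta_prior"] > 0) &&
      all(pm[, "sigma_evidence"] + pm[, "delta_evidence"] > 0)
    ld <- m$log_density(th, md)
    if (drug_ok) {
      expect_true(is.finite(ld))
      ws <- c(ws, prior_weighting(pm[1, "sigma_prior"], pm[1, "sigma_evidence"]))
    } else {
      expect_equal(ld, -Inf)
    }
  }
  expect_gt(length(ws), 100)
  expect_lt(min(ws), 0.2)
  expect_gt(max(ws), 0.8)
  expect_true(all(ws > 0 & ws < 1))
})

test_that("R-hat behaves correctly on copies, separated chains, and the reference formula", {
  set.seed(3)
  x <- rnorm(500)
  expect_lt(compute_rhat(cbind(x, x, x)), 1.001)
  far <- cbind(rnorm(200, 0, 1), rnorm(200, 10, 1))
  expect_gt(compute_rhat(far), 1.5)
  expect_error(compute_rhat(matrix(rnorm(10), ncol = 1)), "2 chains")
  expect_error(compute_rhat(matrix(rnorm(6), ncol = 2)), "4 draws")

  # independent step-by-step reference implementation of rank-normalized
  # split R-hat
  ref_rhat <- function(mat) {
    half <- nrow(mat) %/% 2
    sp <- cbind(mat[1:half, ], mat[(nrow(mat) - half + 1):nrow(mat), ])
    r <- matrix(rank(sp), nrow(sp), ncol(sp))
    z <- qnorm((r - 3 / 8) / (length(sp) + 1 / 4))
    m <- ncol(z); nn <- nrow(z)
    means <- colMeans(z)
    vars <- apply(z, 2, var)
    B <- nn / (m - 1) * sum((means - mean(means))^2)
    W <- mean(vars)
    sqrt(((nn - 1) / nn * W + B / nn) / W)
  }
  for (seed in 1:10) {
    set.seed(seed)
    mat <- matrix(rnorm(400) + rep(rnorm(4, sd = 0.3), each = 100), ncol = 4)
    expect_equal(compute_rhat(mat), ref_rhat(mat), tolerance = 1e-8)
  }
})

test_that("WAIC matches a direct two-pass implementation of the formula", {
  set.seed(8)
  ll <- matrix(rnorm(200 * 25, mean = -1), 200, 25)
  got <- waic(ll)
  lppd <- sum(log(colMeans(exp(ll))))
  p <- sum(apply(ll, 2, var))
  expect_equal(got$waic, -2 * (lppd - p), tolerance = 1e-8)
  expect_equal(got$p_waic, p, tolerance = 1e-8)
  pw <- log(colMeans(exp(ll))) - apply(ll, 2, var)
  expect_equal(got$se, 2 * sqrt(25 * var(pw)), tolerance = 1e-8)
})

test_that("PSIS-LOO is finite, close to WAIC for well-behaved likelihoods, and normalized", {
  set.seed(9)
  ll <- matrix(rnorm(1000 * 20, mean = -1, sd = 0.1), 1000, 20)
  lo <- psis_loo(ll)
  wa <- waic(ll)
  expect_true(is.finite(lo$looic))
  expect_equal(lo$looic, wa$waic, tolerance = 0.05)
  sm <- psis_smooth(rnorm(1000))
  expect_equal(sum(exp(sm$log_weights)), 1, tolerance = 1e-10)
  expect_true(is.finite(sm$k))
})

test_that("posterior medians and draw extraction follow the sorting oracle", {
  fit <- fixture_fit()
  fl <- priorweight:::flatten_draws(fit)
  eff <- suppressWarnings(extract_participant_effects(fit))
  id <- fit$data$ids[1]
  dr <- fl[, sprintf("sigma_prior[%s]", id)]
  srt <- sort(dr)
  nn <- length(srt)
  med_oracle <- if (nn %% 2 == 1) srt[(nn + 1) / 2] else mean(srt[nn / 2 + 0:1])
  expect_equal(eff$sigma_prior[eff$participant_id == id], med_oracle)
  # median equivariance under monotone transforms (odd count: the median is
  # an order statistic, not an average of two)
  odd <- dr[seq_len(2 * (length(dr) %/% 2) - 1)]
  expect_equal(median(exp(odd)), exp(median(odd)), tolerance = 1e-12)
  # derived w is the median of the per-draw weighting, not the weighting of medians
  w_dr <- prior_weighting(dr, fl[, sprintf("sigma_evidence[%s]", id)])
  expect_equal(eff$w_placebo[eff$participant_id == id], median(w_dr))
})

test_that("a short fit returns aligned draws, diagnostics and pointwise log-likelihood", {
  fit <- fixture_fit()
  expect_s3_class(fit, "posterior_samples")
  expect_equal(dim(fit$draws)[2], 2L)
  expect_true(all(is.finite(fit$draws)))
  expect_equal(nrow(fit$diagnostics), length(fit$parameters))
  expect_equal(ncol(fit$loglik), fit$data$n_trials)
  expect_true(all(is.finite(fit$loglik)))
  expect_equal(nrow(fit$data$index), fit$data$n_trials)
  # stored pointwise log-likelihood agrees with the generative model evaluated
  # at the same draw
  m <- build_generative_model(fit$variant, fit$hyper)
  fl <- priorweight:::flatten_draws(fit)
  r <- fit$loglik_draw_index[3]
  th <- priorweight:::flat_to_theta(fl[r, ], fit$families, fit$data$ids)
  expect_equal(fit$loglik[3, ], m$pointwise_loglik(th, fit$data), tolerance = 1e-10)
})

test_that("posterior predictive checks are centred for a well-specified model", {
  fit <- fixture_fit()
  ppc <- posterior_predictive_check(fit, seed = 2, max_draws = 200)
  expect_equal(ppc$n_rep, 200L)
  expect_equal(ncol(ppc$residual_means), fit$data$n)
  for (i in seq_len(fit$data$n)) {
    expect_equal(nrow(ppc$replicated[[i]]), 200L)
    res <- ppc$residual_means[, i]
    expect_lt(abs(mean(res)), 0.5 * sd(res) + 0.02)
  }
})

test_that("a large unmodelled evidence shift is detected as misfit", {
  hyper <- group_hyper_params(mu_xshift = 0.06, sd_xshift = 1e-6)
  ch <- simulate_cohort(cohort_config(n_pd = 4, n_controls = 0),
                        hyper = hyper, seed = 13)
  md <- prepare_model_data(ch)
  # fix x_shift at (effectively) zero via a near-degenerate hyperprior
  hy <- hyper_prior_spec(x_shift = list(mean_loc = 0, mean_scale = 1e-6,
                                        mean_positive = FALSE, sd_scale = 1e-6))
  fit <- suppressWarnings(fit_hierarchical(md, "full",
    fit_config(chains = 2, iter = 800, warmup = 400, seed = 5,
               loglik = FALSE), hy))
  ppc <- posterior_predictive_check(fit, seed = 3, max_draws = 150)
  shifts <- colMeans(ppc$residual_means)
  # observed responses sit systematically to one side of the replicates
  expect_gt(mean(shifts), 0.01)
})

test_that("fits on misaligned data are refused by compare_models", {
  fit <- fixture_fit()
  other <- fit
  other$loglik <- other$loglik[, -1]
  expect_error(compare_models(list(a = fit, b = other)), "not aligned")
})
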