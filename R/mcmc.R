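#' Sampler configuration for the hierarchical model
#'
#' Defaults follow the study's sampler budget: 8 chains of 4000 iterations
#' each with the first 2000 discarded as warm-up. Reduced budgets (e.g. 4
#' chains of 2000 with 1000 warm-up) are appropriate for simulation studies.
#'
#' @param chains Number of chains.
#' @param iter Total iterations per chain (including warm-up).
#' @param warmup Warm-up iterations discarded from summaries; adaptation of
#'   the proposal covariances happens only here.
#' @param seed Integer seed; each chain uses a stream derived from it.
#' @param thin Keep every `thin`-th post-warm-up draw.
#' @param loglik Store the pointwise log-likelihood matrix?
#' @param loglik_max_draws Upper bound on the number of draws for which the
#'   pointwise log-likelihood is evaluated (evenly thinned).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(chains = 8L, iter = 4000L, warmup = 2000L, seed = 1L,
                       thin = 1L, loglik = TRUE, loglik_max_draws = 1000L) {
  stopifnot(chains >= 1, iter > warmup, warmup >= 0, thin >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 thin = as.integer(thin), loglik = isTRUE(loglik),
                 loglik_max_draws = as.integer(loglik_max_draws)),
            class = "fit_config")
}

# crude per-session moment estimates (w, posterior sd) used to initialise
# chains: raw no-intercept slope and residual sd of the estimation errors
init_point <- function(data) {
  t(vapply(data$participants, function(p) {
    est <- vapply(p, function(s) {
      if (length(s$estimate) < 3) return(c(w = 0.5, psd = 0.05))
      x <- s$ball - s$target
      y <- s$estimate - s$ball
      w <- -sum(x * y) / sum(x^2)
      w <- min(max(w, 0.05), 0.95)
      psd <- max(stats::sd(y + w * x), 0.01)
      c(w = w, psd = psd)
    }, numeric(2))
    c(w1 = est["w", 1], p1 = est["psd", 1], w2 = est["w", 2], p2 = est["psd", 2])
  }, numeric(4)))
}

# Gaussian-likelihood sufficient statistics per session: with u = estimate -
# ball and v = target - ball, the residual is u - w v - (1 - w) xs, so the
# sum of squares needs only (n, Suu, Suv, Svv, Su, Sv).
session_suffstats <- function(s) {
  u <- s$estimate - s$ball
  v <- s$target - s$ball
  list(n = length(u), Suu = sum(u * u), Suv = sum(u * v), Svv = sum(v * v),
       Su = sum(u), Sv = sum(v))
}

sess_loglik <- function(st, w, psd, xs) {
  if (st$n == 0L) return(0)
  sse <- st$Suu - 2 * w * st$Suv + w^2 * st$Svv -
    2 * (1 - w) * xs * (st$Su - w * st$Sv) + st$n * (1 - w)^2 * xs^2
  -st$n / 2 * log(2 * pi) - st$n * log(psd) - sse / (2 * psd^2)
}

# Participant block coordinates: per-session (logit w, log psd) pairs --
# which the data constrain nearly independently and on which the posterior
# is close to elliptical -- plus the evidence shift. Restricted variants tie
# the constrained drug-session sd to its placebo value and keep one free
# log-sd for the drug session. The change-of-variables term for
# (logit w, log psd) -> (sigma_prior, sigma_evidence) is
# 2 log psd - log 2 - 0.5 log(w (1 - w)); for a free drug-session log-sd it
# is the log-sd itself.
participant_map <- function(variant) {
  fams <- variant_families(variant)
  has_dp <- "delta_prior" %in% fams
  has_de <- "delta_evidence" %in% fams
  j1 <- function(a, b) {
    w <- stats::plogis(a)
    2 * b - log(2) - 0.5 * (log(w) + log1p(-w))
  }
  from_sig <- function(sp, se) {
    w <- se^2 / (se^2 + sp^2)
    c(stats::qlogis(w), log(se * sp / sqrt(se^2 + sp^2)))
  }
  # nat slots (unnamed, fixed order): sigma_prior, sigma_evidence,
  # delta_prior, delta_evidence, x_shift
  if (has_dp && has_de) { # full: both sessions free
    d <- 5L
    eval_t <- function(t) {
      w1 <- 1 / (1 + exp(-t[1])); p1 <- exp(t[2])
      w2 <- 1 / (1 + exp(-t[3])); p2 <- exp(t[4])
      sp1 <- p1 / sqrt(w1); se1 <- p1 / sqrt(1 - w1)
      sp2 <- p2 / sqrt(w2); se2 <- p2 / sqrt(1 - w2)
      list(nat = c(sp1, se1, sp2 - sp1, se2 - se1, t[5]),
           w = c(w1, w2), psd = c(p1, p2), sp = c(sp1, sp2), se = c(se1, se2),
           ok = TRUE,
           ljac = 2 * (t[2] + t[4]) - 2 * log(2) -
             0.5 * (log(w1) + log1p(-w1) + log(w2) + log1p(-w2)))
    }
    init_t <- function(ip) c(stats::qlogis(ip[1]), log(ip[2]),
                             stats::qlogis(ip[3]), log(ip[4]), 0)
    set_nat <- function(t, fam, value) {
      e <- eval_t(t)
      sp1 <- e$nat[1]; se1 <- e$nat[2]
      sp2 <- sp1 + e$nat[3]; se2 <- se1 + e$nat[4]
      if (fam == "sigma_prior") {
        if (value <= 0) return(NULL)
        sp2 <- sp2 + (value - sp1); sp1 <- value # hold the deltas fixed
      } else if (fam == "sigma_evidence") {
        if (value <= 0) return(NULL)
        se2 <- se2 + (value - se1); se1 <- value
      } else if (fam == "delta_prior") {
        sp2 <- sp1 + value
      } else if (fam == "delta_evidence") {
        se2 <- se1 + value
      } else {
        t[5] <- value
        return(t)
      }
      if (sp2 <= 0 || se2 <= 0) return(NULL)
      t[1:2] <- from_sig(sp1, se1)
      t[3:4] <- from_sig(sp2, se2)
      t
    }
  } else if (!has_dp && !has_de) { # no_delta: one shared session
    d <- 3L
    eval_t <- function(t) {
      w1 <- 1 / (1 + exp(-t[1])); p1 <- exp(t[2])
      sp1 <- p1 / sqrt(w1); se1 <- p1 / sqrt(1 - w1)
      list(nat = c(sp1, se1, 0, 0, t[3]),
           w = c(w1, w1), psd = c(p1, p1), sp = c(sp1, sp1), se = c(se1, se1),
           ok = TRUE,
           ljac = 2 * t[2] - log(2) - 0.5 * (log(w1) + log1p(-w1)))
    }
    init_t <- function(ip) c(stats::qlogis((ip[1] + ip[3]) / 2),
                             log((ip[2] + ip[4]) / 2), 0)
    set_nat <- function(t, fam, value) {
      if (fam == "x_shift") {
        t[3] <- value
        return(t)
      }
      e <- eval_t(t)
      sp1 <- e$nat[1]; se1 <- e$nat[2]
      if (value <= 0) return(NULL)
      if (fam == "sigma_prior") sp1 <- value else se1 <- value
      t[1:2] <- from_sig(sp1, se1)
      t
    }
  } else { # one free drug-session log-sd
    d <- 4L
    free_fam <- if (has_dp) "delta_prior" else "delta_evidence"
    eval_t <- function(t) {
      w1 <- 1 / (1 + exp(-t[1])); p1 <- exp(t[2])
      sp1 <- p1 / sqrt(w1); se1 <- p1 / sqrt(1 - w1)
      if (has_dp) {
        sp2 <- exp(t[3]); se2 <- se1
      } else {
        se2 <- exp(t[3]); sp2 <- sp1
      }
      w2 <- se2^2 / (se2^2 + sp2^2)
      p2 <- se2 * sp2 / sqrt(se2^2 + sp2^2)
      list(nat = c(sp1, se1, if (has_dp) sp2 - sp1 else 0,
                   if (has_de) se2 - se1 else 0, t[4]),
           w = c(w1, w2), psd = c(p1, p2), sp = c(sp1, sp2), se = c(se1, se2),
           ok = TRUE,
           ljac = 2 * t[2] - log(2) - 0.5 * (log(w1) + log1p(-w1)) + t[3])
    }
    init_t <- function(ip) {
      free2 <- if (has_dp) ip[4] / sqrt(ip[3]) else ip[4] / sqrt(1 - ip[3])
      c(stats::qlogis(ip[1]), log(ip[2]), log(free2), 0)
    }
    set_nat <- function(t, fam, value) {
      if (fam == "x_shift") {
        t[4] <- value
        return(t)
      }
      e <- eval_t(t)
      sp1 <- e$nat[1]; se1 <- e$nat[2]
      free2 <- exp(t[3])
      if (fam == free_fam) {
        base <- if (has_dp) sp1 else se1
        if (base + value <= 0) return(NULL)
        t[3] <- log(base + value)
        return(t)
      }
      if (value <= 0) return(NULL)
      if (fam == "sigma_prior") {
        if (has_dp) {
          if (free2 + (value - sp1) <= 0) return(NULL)
          t[3] <- log(free2 + (value - sp1))
        }
        sp1 <- value
      } else {
        if (has_de) {
          if (free2 + (value - se1) <= 0) return(NULL)
          t[3] <- log(free2 + (value - se1))
        }
        se1 <- value
      }
      t[1:2] <- from_sig(sp1, se1)
      t
    }
  }
  list(d = d, fams = fams, eval = eval_t, init = init_t, set_nat = set_nat)
}

#' Fit the hierarchical model by MCMC
#'
#' Samples the joint posterior of [build_generative_model()] with an adaptive
#' Metropolis-within-Gibbs scheme. Each participant's parameters are updated
#' jointly with a multivariate normal proposal (empirical-covariance
#' adaptation during warm-up, Robbins-Monro scale targeting 28% acceptance)
#' in per-session (prior weighting, posterior sd) coordinates plus raw drug
#' offsets; each group-level (mean, sd) pair is updated the same way. To
#' traverse the hierarchical funnel, every iteration additionally applies
#' interleaved rescale and location moves per parameter family, which move a
#' group-level parameter and all its participant-level values coherently.
#' Positive parameters are handled on the log scale with exact
#' change-of-variables terms. Poor convergence does not raise an error:
#' per-parameter split-R-hat and effective sample sizes are reported
#' alongside a `converged` flag (all R-hat < 1.01).
#'
#' @param data A [prepare_model_data()] result (or a `cohort`, converted
#'   automatically).
#' @param variant Model variant, see [build_generative_model()].
#' @param config A [fit_config()].
#' @param hyper A [hyper_prior_spec()].
#' @return An object of class `posterior_samples`: post-warm-up draws
#'   (array iterations x chains x parameters, natural scale), per-parameter
#'   diagnostics, the pointwise log-likelihood matrix (draws x estimation
#'   trials, columns ordered as `data$index`), and the sampler configuration.
#' @export
fit_hierarchical <- function(data, variant = "full", config = fit_config(),
                             hyper = hyper_prior_spec()) {
  if (inherits(data, "cohort")) data <- prepare_model_data(data)
  stopifnot(inherits(data, "model_data"), inherits(config, "fit_config"))
  model <- build_generative_model(variant, hyper)
  fams <- model$families
  nf <- length(fams)
  n <- data$n
  is_sigma <- fams %in% c("sigma_prior", "sigma_evidence")
  pmap <- participant_map(variant)

  fam_idx <- match(fams, model_families)
  has_dp <- "delta_prior" %in% fams
  has_de <- "delta_evidence" %in% fams
  stats_ps <- lapply(data$participants, function(p) lapply(p, session_suffstats))
  lik_part <- function(i, ev) {
    if (!ev$ok) return(-Inf)
    xs <- ev$nat[5]
    sess_loglik(stats_ps[[i]][[1]], ev$w[1], ev$psd[1], xs) +
      sess_loglik(stats_ps[[i]][[2]], ev$w[2], ev$psd[2], xs)
  }
  # participant x session sufficient-statistic matrices for vectorized
  # whole-cohort likelihood evaluations
  stM <- lapply(c(n = "n", uu = "Suu", uv = "Suv", vv = "Svv", u = "Su", v = "Sv"),
                function(f) {
                  matrix(vapply(1:2, function(j) {
                    vapply(stats_ps, function(s) s[[j]][[f]], 0)
                  }, numeric(n)), ncol = 2)
                })
  lik_all <- function(W, PSD, XS) {
    out <- numeric(n)
    for (j in 1:2) {
      wj <- W[, j]; pj <- PSD[, j]
      sse <- stM$uu[, j] - 2 * wj * stM$uv[, j] + wj^2 * stM$vv[, j] -
        2 * (1 - wj) * XS * (stM$u[, j] - wj * stM$v[, j]) +
        stM$n[, j] * (1 - wj)^2 * XS^2
      out <- out - stM$n[, j] / 2 * log(2 * pi) - stM$n[, j] * log(pj) -
        sse / (2 * pj^2)
    }
    out
  }

  init0 <- init_point(data)
  kept <- (config$iter - config$warmup) %/% config$thin
  par_names <- c(paste0("mu_", fams), paste0("tau_", fams),
                 as.vector(t(outer(fams, data$ids,
                                   function(f, id) sprintf("%s[%s]", f, id)))))
  chain_seeds <- with_seed(config$seed,
                           sample.int(.Machine$integer.max - 1L, config$chains))

  run_chain <- function(chain) {
    set.seed(chain_seeds[chain])
    gmu <- numeric(nf); gltau <- numeric(nf)
    for (k in seq_len(nf)) {
      if (is_sigma[k]) {
        gmu[k] <- log(stats::runif(1, 0.05, 0.13))
        gltau[k] <- log(stats::runif(1, 0.01, 0.05))
      } else {
        gmu[k] <- stats::rnorm(1, 0, 0.01)
        gltau[k] <- log(stats::runif(1, 0.005, 0.03))
      }
    }
    Tm <- matrix(0, n, pmap$d)
    jit <- c(rep(0.15, pmap$d - 1L), 0.01)
    for (i in seq_len(n)) {
      Tm[i, ] <- pmap$init(init0[i, ]) + stats::rnorm(pmap$d, 0, jit)
    }
    evs <- lapply(seq_len(n), function(i) pmap$eval(Tm[i, ]))
    Nmat <- t(vapply(evs, function(e) e$nat[fam_idx], numeric(nf)))

    nat_gmu <- function(k, v) if (is_sigma[k]) exp(v) else v
    # cached natural-scale group parameters and truncation log-normalizers
    gnat_mu <- numeric(nf); gnat_tau <- numeric(nf); gnorm <- numeric(nf)
    refresh_gcache <- function(k) {
      gnat_mu[k] <<- nat_gmu(k, gmu[k])
      gnat_tau[k] <<- exp(gltau[k])
      gnorm[k] <<- if (is_sigma[k]) {
        stats::pnorm(0, gnat_mu[k], gnat_tau[k], lower.tail = FALSE, log.p = TRUE)
      } else 0
    }
    calc_gp <- function(k, gmu_k, gltau_k) {
      h <- hyper[[fams[k]]]
      mu <- nat_gmu(k, gmu_k)
      tau <- exp(gltau_k)
      lp <- if (h$mean_positive) {
        ldtnorm_pos(mu, h$mean_loc, h$mean_scale) + gmu_k
      } else {
        stats::dnorm(mu, h$mean_loc, h$mean_scale, log = TRUE)
      }
      lp + stats::dnorm(tau, 0, h$sd_scale, log = TRUE) + log(2) + gltau_k
    }
    calc_pp <- function(k, mu, tau, x) {
      if (is_sigma[k]) {
        if (x <= 0) return(-Inf)
        stats::dnorm(x, mu, tau, log = TRUE) -
          stats::pnorm(0, mu, tau, lower.tail = FALSE, log.p = TRUE)
      } else {
        stats::dnorm(x, mu, tau, log = TRUE)
      }
    }
    calc_pp_col <- function(k, mu, tau, xv) {
      if (is_sigma[k]) {
        out <- stats::dnorm(xv, mu, tau, log = TRUE) -
          stats::pnorm(0, mu, tau, lower.tail = FALSE, log.p = TRUE)
        out[xv <= 0] <- -Inf
        out
      } else {
        stats::dnorm(xv, mu, tau, log = TRUE)
      }
    }

    for (k in seq_len(nf)) refresh_gcache(k)
    gp <- vapply(seq_len(nf), function(k) calc_gp(k, gmu[k], gltau[k]), 0)
    pp <- matrix(0, n, nf)
    for (k in seq_len(nf)) {
      pp[, k] <- calc_pp_col(k, gnat_mu[k], gnat_tau[k], Nmat[, k])
    }
    lik <- vapply(seq_len(n), function(i) lik_part(i, evs[[i]]), 0)
    ljac <- vapply(evs, `[[`, 0, "ljac")
    if (any(!is.finite(lik))) stop("non-finite likelihood at initial point", call. = FALSE)
    # array mirrors of the per-participant state for vectorized family moves
    SP <- matrix(vapply(evs, `[[`, numeric(2), "sp"), ncol = 2, byrow = TRUE)
    SE <- matrix(vapply(evs, `[[`, numeric(2), "se"), ncol = 2, byrow = TRUE)
    Wm <- matrix(vapply(evs, `[[`, numeric(2), "w"), ncol = 2, byrow = TRUE)
    PSDm <- matrix(vapply(evs, `[[`, numeric(2), "psd"), ncol = 2, byrow = TRUE)
    XS <- vapply(evs, function(e) e$nat[5], 0)
    # coordinates and change-of-variables terms from session-sigma state
    coords_vec <- function(SP1, SE1, SP2, SE2, XSv) {
      w1 <- SE1^2 / (SE1^2 + SP1^2)
      p1 <- SE1 * SP1 / sqrt(SE1^2 + SP1^2)
      a1 <- stats::qlogis(w1); b1 <- log(p1)
      lj <- 2 * b1 - log(2) - 0.5 * (log(w1) + log1p(-w1))
      if (has_dp && has_de) {
        w2 <- SE2^2 / (SE2^2 + SP2^2)
        p2 <- SE2 * SP2 / sqrt(SE2^2 + SP2^2)
        Tn <- cbind(a1, b1, stats::qlogis(w2), log(p2), XSv)
        lj <- lj + 2 * log(p2) - log(2) - 0.5 * (log(w2) + log1p(-w2))
      } else if (!has_dp && !has_de) {
        Tn <- cbind(a1, b1, XSv)
      } else if (has_dp) {
        Tn <- cbind(a1, b1, log(SP2), XSv)
        lj <- lj + log(SP2)
      } else {
        Tn <- cbind(a1, b1, log(SE2), XSv)
        lj <- lj + log(SE2)
      }
      list(T = Tn, ljac = lj)
    }

    # adaptive scales: participant blocks, group pairs, per-family
    # rescale/location interleaving moves
    nb <- n + nf
    bdim <- c(rep(pmap$d, n), rep(2L, nf))
    lsc <- rep(0, nb)
    bmean <- lapply(bdim, numeric)
    bcov <- lapply(bdim, function(d) matrix(0, d, d))
    bcnt <- integer(nb)
    bchol <- lapply(bdim, function(d) diag(0.05, d))
    asis_ls <- matrix(log(0.1), nf, 2) # cols: rescale, location
    update_moments <- function(b, x) {
      bcnt[b] <<- bcnt[b] + 1L
      d <- x - bmean[[b]]
      bmean[[b]] <<- bmean[[b]] + d / bcnt[b]
      bcov[[b]] <<- bcov[[b]] + outer(d, x - bmean[[b]])
    }
    refresh_chol <- function(b) {
      if (bcnt[b] > 2L * bdim[b]) {
        S <- bcov[[b]] / (bcnt[b] - 1L)
        S <- (2.38^2 / bdim[b]) * S + diag(1e-8, bdim[b])
        ch <- tryCatch(chol(S), error = function(e) NULL)
        if (!is.null(ch)) bchol[[b]] <<- t(ch)
      }
    }

    # family-wide interleaving move: transform every participant's natural
    # value for family k together with its group mean/sd, vectorized over
    # the cohort. The participant-side coordinate Jacobians cancel against
    # the prior change-of-variables terms, leaving `extra` (the move's own
    # log Jacobian, n*c for a rescale by exp(c)).
    family_move <- function(k, transform, gmu_new, gltau_new, extra) {
      fam <- fams[k]
      SP1n <- SP[, 1]; SE1n <- SE[, 1]; SP2n <- SP[, 2]; SE2n <- SE[, 2]
      XSn <- XS
      if (fam == "sigma_prior") {
        SP1n <- transform(SP[, 1])
        SP2n <- SP1n + (SP[, 2] - SP[, 1])
        if (any(SP1n <= 0) || any(SP2n <= 0)) return(FALSE)
      } else if (fam == "sigma_evidence") {
        SE1n <- transform(SE[, 1])
        SE2n <- SE1n + (SE[, 2] - SE[, 1])
        if (any(SE1n <= 0) || any(SE2n <= 0)) return(FALSE)
      } else if (fam == "delta_prior") {
        SP2n <- SP[, 1] + transform(SP[, 2] - SP[, 1])
        if (any(SP2n <= 0)) return(FALSE)
      } else if (fam == "delta_evidence") {
        SE2n <- SE[, 1] + transform(SE[, 2] - SE[, 1])
        if (any(SE2n <= 0)) return(FALSE)
      } else {
        XSn <- transform(XS)
      }
      Wn <- cbind(SE1n^2 / (SE1n^2 + SP1n^2), SE2n^2 / (SE2n^2 + SP2n^2))
      Pn <- cbind(SE1n * SP1n / sqrt(SE1n^2 + SP1n^2),
                  SE2n * SP2n / sqrt(SE2n^2 + SP2n^2))
      likn <- lik_all(Wn, Pn, XSn)
      new_col <- switch(fam, sigma_prior = SP1n, sigma_evidence = SE1n,
                        delta_prior = SP2n - SP1n, delta_evidence = SE2n - SE1n,
                        x_shift = XSn)
      ppn <- calc_pp_col(k, nat_gmu(k, gmu_new), exp(gltau_new), new_col)
      gpn <- calc_gp(k, gmu_new, gltau_new)
      dl <- (sum(ppn) + sum(likn) + gpn) - (sum(pp[, k]) + sum(lik) + gp[k]) + extra
      if (!is.finite(dl) || log(stats::runif(1)) >= dl) return(FALSE)
      cv <- coords_vec(SP1n, SE1n, SP2n, SE2n, XSn)
      Tm <<- cv$T
      ljac <<- cv$ljac
      SP <<- cbind(SP1n, SP2n)
      SE <<- cbind(SE1n, SE2n)
      Wm <<- Wn
      PSDm <<- Pn
      XS <<- XSn
      Nmat[, k] <<- new_col
      lik <<- likn
      pp[, k] <<- ppn
      gp[k] <<- gpn
      gmu[k] <<- gmu_new
      gltau[k] <<- gltau_new
      refresh_gcache(k)
      TRUE
    }

    store <- matrix(NA_real_, kept, length(par_names))
    keep_i <- 0L

    for (it in seq_len(config$iter)) {
      in_warm <- it <= config$warmup
      rm_step <- min(0.25, 3 / sqrt(it))
      if (config$warmup > 3L && it == config$warmup %/% 2L) {
        # discard early-phase history so proposal covariances are estimated
        # from adapted draws only
        for (b in seq_len(nb)) {
          bmean[[b]] <- numeric(bdim[b])
          bcov[[b]] <- matrix(0, bdim[b], bdim[b])
          bcnt[b] <- 0L
        }
      }

      # participant blocks
      for (i in seq_len(n)) {
        prop <- Tm[i, ] + exp(lsc[i]) * as.numeric(bchol[[i]] %*% stats::rnorm(pmap$d))
        ev <- pmap$eval(prop)
        likn <- lik_part(i, ev)
        if (is.finite(likn)) {
          natv <- ev$nat[fam_idx]
          ppn <- -0.918938533204673 - log(gnat_tau) -
            0.5 * ((natv - gnat_mu) / gnat_tau)^2 - gnorm
          ppn[is_sigma & natv <= 0] <- -Inf
          dl <- (sum(ppn) + likn + ev$ljac) - (sum(pp[i, ]) + lik[i] + ljac[i])
          acc <- is.finite(dl) && log(stats::runif(1)) < dl
        } else acc <- FALSE
        if (acc) {
          Tm[i, ] <- prop
          Nmat[i, ] <- natv
          pp[i, ] <- ppn
          lik[i] <- likn
          ljac[i] <- ev$ljac
          SP[i, ] <- ev$sp
          SE[i, ] <- ev$se
          Wm[i, ] <- ev$w
          PSDm[i, ] <- ev$psd
          XS[i] <- ev$nat[5]
        }
        if (in_warm) {
          lsc[i] <- lsc[i] + rm_step * ((if (acc) 1 else 0) - 0.28)
          update_moments(i, Tm[i, ])
          if (it %% 25L == 0L) refresh_chol(i)
        }
      }

      # group-level (mean, sd) pairs
      for (k in seq_len(nf)) {
        b <- n + k
        prop <- c(gmu[k], gltau[k]) +
          exp(lsc[b]) * as.numeric(bchol[[b]] %*% stats::rnorm(2))
        gpn <- calc_gp(k, prop[1], prop[2])
        ppn <- calc_pp_col(k, nat_gmu(k, prop[1]), exp(prop[2]), Nmat[, k])
        dl <- (gpn + sum(ppn)) - (gp[k] + sum(pp[, k]))
        acc <- is.finite(dl) && log(stats::runif(1)) < dl
        if (acc) {
          gmu[k] <- prop[1]; gltau[k] <- prop[2]
          gp[k] <- gpn; pp[, k] <- ppn
          refresh_gcache(k)
        }
        if (in_warm) {
          lsc[b] <- lsc[b] + rm_step * ((if (acc) 1 else 0) - 0.28)
          update_moments(b, c(gmu[k], gltau[k]))
          if (it %% 25L == 0L) refresh_chol(b)
        }
      }

      # interleaved family-wide moves (funnel traversal)
      for (k in seq_len(nf)) {
        mu_nat <- gnat_mu[k]
        # rescale: contract/expand deviations around the group mean together
        # with the group sd; log Jacobian of the deterministic part is n*c
        cc <- stats::rnorm(1, 0, exp(asis_ls[k, 1]))
        acc1 <- family_move(k, function(x) mu_nat + exp(cc) * (x - mu_nat),
                            gmu[k], gltau[k] + cc, n * cc)
        # location: shift the group mean and every participant value
        dd <- stats::rnorm(1, 0, exp(asis_ls[k, 2]))
        gmu_new <- gmu[k] + dd
        eps <- nat_gmu(k, gmu_new) - gnat_mu[k]
        acc2 <- family_move(k, function(x) x + eps, gmu_new, gltau[k], 0)
        if (in_warm) {
          asis_ls[k, 1] <- asis_ls[k, 1] + rm_step * ((if (acc1) 1 else 0) - 0.4)
          asis_ls[k, 2] <- asis_ls[k, 2] + rm_step * ((if (acc2) 1 else 0) - 0.4)
        }
      }

      if (!in_warm && (it - config$warmup) %% config$thin == 0L) {
        keep_i <- keep_i + 1L
        mus <- vapply(seq_len(nf), function(k) nat_gmu(k, gmu[k]), 0)
        store[keep_i, ] <- c(mus, exp(gltau), as.vector(Nmat))
      }
    }
    store
  }

  chains <- lapply(seq_len(config$chains), run_chain)
  draws <- array(NA_real_, dim = c(kept, config$chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (ch in seq_along(chains)) draws[, ch, ] <- chains[[ch]]

  diag_df <- data.frame(
    parameter = par_names,
    rhat = vapply(par_names, function(p) {
      if (config$chains < 2) return(NA_real_)
      compute_rhat(draws[, , p, drop = TRUE])
    }, 0),
    ess = vapply(par_names, function(p) compute_ess(as.matrix(draws[, , p, drop = TRUE])), 0),
    row.names = NULL
  )
  converged <- all(is.finite(diag_df$rhat)) && all(diag_df$rhat < 1.01)
  if (!converged) {
    warning(sprintf("convergence not confirmed: max split-R-hat = %.3f",
                    max(diag_df$rhat, na.rm = TRUE)), call. = FALSE)
  }

  ll <- NULL
  ll_draw_index <- NULL
  if (config$loglik) {
    total <- kept * config$chains
    take <- unique(round(seq(1, total, length.out = min(total, config$loglik_max_draws))))
    flat <- matrix(draws, nrow = total)
    colnames(flat) <- par_names
    ll <- matrix(NA_real_, length(take), data$n_trials)
    for (r in seq_along(take)) {
      theta <- flat_to_theta(flat[take[r], ], fams, data$ids)
      ll[r, ] <- model$pointwise_loglik(theta, data)
    }
    ll_draw_index <- take
  }

  structure(list(draws = draws, parameters = par_names,
                 diagnostics = diag_df, converged = converged,
                 loglik = ll, loglik_draw_index = ll_draw_index,
                 variant = variant, config = config, hyper = hyper,
                 data = data, families = fams),
            class = "posterior_samples")
}

# named flat draw -> theta list for the generative model interface
flat_to_theta <- function(v, fams, ids) {
  group <- as.list(v[c(paste0("mu_", fams), paste0("tau_", fams))])
  pm <- matrix(0, length(ids), length(fams), dimnames = list(ids, fams))
  for (f in fams) pm[, f] <- v[sprintf("%s[%s]", f, ids)]
  list(group = group, participants = pm)
}

#' @export
print.posterior_samples <- function(x, ...) {
  k <- dim(x$draws)
  cat(sprintf("posterior_samples: variant '%s', %d chains x %d draws, %d parameters\n",
              x$variant, k[2], k[1], k[3]))
  cat(sprintf("  max split-R-hat %.4f, min ESS %.0f, converged: %s\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE), x$converged))
  invisible(x)
}

#' Split-R-hat convergence diagnostic
#'
#' Rank-normalized split potential scale reduction: each chain is split in
#' half, all draws are rank-normalized with the standard normal quantile of
#' fractional ranks, and the classic between/within variance ratio is
#' computed on the result.
#'
#' @param x Matrix of draws (iterations x chains).
#' @return R-hat (scalar).
#' @export
compute_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("R-hat requires at least 2 chains", call. = FALSE)
  if (nrow(x) < 4) stop("R-hat requires at least 4 draws per chain", call. = FALSE)
  half <- nrow(x) %/% 2L
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(nrow(x) - half + 1L):nrow(x), , drop = FALSE])
  S <- length(xs)
  z <- stats::qnorm((rank(xs) - 3 / 8) / (S + 1 / 4))
  dim(z) <- dim(xs)
  n <- nrow(z)
  W <- mean(apply(z, 2, stats::var))
  B <- n * stats::var(colMeans(z))
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bulk effective sample size
#'
#' Rank-normalized split-chain effective sample size using Geyer's initial
#' monotone positive sequence of paired autocorrelations.
#'
#' @param x Matrix of draws (iterations x chains).
#' @return Effective sample size (scalar).
#' @export
compute_ess <- function(x) {
  x <- as.matrix(x)
  half <- nrow(x) %/% 2L
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(nrow(x) - half + 1L):nrow(x), , drop = FALSE])
  S <- length(xs)
  z <- stats::qnorm((rank(xs) - 3 / 8) / (S + 1 / 4))
  dim(z) <- dim(xs)
  n <- nrow(z); m <- ncol(z)
  W <- mean(apply(z, 2, stats::var))
  B <- n * stats::var(colMeans(z))
  varplus <- (n - 1) / n * W + B / n
  if (!is.finite(varplus) || varplus == 0) return(NA_real_)
  lag_max <- min(n - 1L, 500L)
  acov <- sapply(seq_len(m), function(j) {
    stats::acf(z[, j], lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov[-1]) / varplus
  tau <- 1
  t <- 1L
  prev_pair <- Inf
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    t <- t + 2L
  }
  min(n * m / tau, n * m)
}
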