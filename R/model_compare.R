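log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Widely applicable information criterion
#'
#' Computed from a pointwise log-likelihood matrix (draws x observations):
#' the log pointwise predictive density minus the variance-based
#' effective-parameter penalty, reported on the deviance scale
#' (`-2 * elpd`).
#'
#' @param loglik Matrix of pointwise log-likelihoods, draws in rows.
#' @return A list with `waic`, `se`, `elpd`, `p_waic` and the `pointwise`
#'   elpd contributions.
#' @export
waic <- function(loglik) {
  stopifnot(is.matrix(loglik), nrow(loglik) >= 2)
  lppd_i <- apply(loglik, 2, log_mean_exp)
  p_i <- apply(loglik, 2, stats::var)
  elpd_i <- lppd_i - p_i
  n <- ncol(loglik)
  list(waic = -2 * sum(elpd_i), se = 2 * sqrt(n * stats::var(elpd_i)),
       elpd = sum(elpd_i), p_waic = sum(p_i), pointwise = elpd_i)
}

# Generalized Pareto fit to exceedances (Zhang & Stephens 2009 posterior-mean
# estimator with the weakly informative prior on k used for PSIS smoothing).
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  b <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_of_b <- vapply(b, function(bi) -mean(log1p(-bi * x)), 0)
  L <- n * (log(b / k_of_b) + k_of_b - 1)
  w <- exp(L - max(L))
  w <- w / sum(w)
  b_hat <- sum(b * w)
  xi <- mean(log1p(-b_hat * x)) # GPD shape
  sigma <- -xi / b_hat
  xi <- (n * xi + 5) / (n + 10) # shrink the shape toward 0.5
  list(k = xi, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

#' Pareto-smoothed importance sampling
#'
#' Stabilises a vector of log importance weights by fitting a generalized
#' Pareto distribution to the largest weights and replacing them with
#' expected order statistics of the fit, truncated at the raw maximum.
#'
#' @param lw Vector of log weights (unnormalized).
#' @return A list with `log_weights` (same length, normalized to
#'   `logsumexp = 0`) and the Pareto shape diagnostic `k`.
#' @export
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  k <- NA_real_
  if (M >= 5 && S - M >= 1) {
    ord <- order(lw)
    tail_ids <- ord[(S - M + 1L):S]
    cut <- lw[ord[S - M]]
    exc <- exp(lw[tail_ids]) - exp(cut)
    if (all(is.finite(exc)) && stats::sd(exc) > 0) {
      fit <- gpd_fit(exc)
      k <- fit$k
      if (is.finite(k) && k < 0.7) {
        qq <- vapply((seq_len(M) - 0.5) / M, qgpd, 0, k = fit$k, sigma = fit$sigma)
        sm <- log(exp(cut) + qq)
        sm <- pmin(sm, 0) # truncate at the raw maximum (already shifted to 0)
        lw[tail_ids[order(lw[tail_ids])]] <- sm
      }
    }
  }
  norm <- log(sum(exp(lw)))
  list(log_weights = lw - norm, k = k)
}

#' Leave-one-out cross-validation by PSIS
#'
#' @param loglik Matrix of pointwise log-likelihoods, draws in rows.
#' @return A list with `looic`, `se`, `elpd`, per-observation `pointwise`
#'   elpd and Pareto `k` diagnostics.
#' @export
psis_loo <- function(loglik) {
  stopifnot(is.matrix(loglik), nrow(loglik) >= 2)
  n <- ncol(loglik)
  elpd_i <- numeric(n)
  k_i <- numeric(n)
  for (j in seq_len(n)) {
    sm <- psis_smooth(-loglik[, j])
    elpd_i[j] <- log(sum(exp(sm$log_weights + loglik[, j])))
    k_i[j] <- sm$k
  }
  list(looic = -2 * sum(elpd_i), se = 2 * sqrt(n * stats::var(elpd_i)),
       elpd = sum(elpd_i), pointwise = elpd_i, pareto_k = k_i)
}

#' Compare fitted model variants by WAIC and PSIS-LOO
#'
#' All fits must be on identical data (same estimation trials in the same
#' order). Criteria are on the deviance scale; pairwise differences against
#' the best variant are computed pointwise with their standard errors.
#'
#' @param fits Named list of `posterior_samples` objects.
#' @return An object of class `information_criteria_table`: a data frame with
#'   per-variant WAIC and LOOIC, their SEs, and differences (with SEs) versus
#'   the best variant by each criterion.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1, !is.null(names(fits)))
  lls <- lapply(fits, function(f) {
    if (is.null(f$loglik)) stop("fit lacks a pointwise log-likelihood matrix", call. = FALSE)
    f$loglik
  })
  ncols <- vapply(lls, ncol, 0L)
  if (length(unique(ncols)) != 1L) {
    stop("fits are not aligned: pointwise log-likelihood column counts differ", call. = FALSE)
  }
  idx <- lapply(fits, function(f) f$data$index)
  for (i in seq_along(idx)[-1]) {
    if (!identical(idx[[1]], idx[[i]])) {
      stop("fits are not aligned: trial index maps differ", call. = FALSE)
    }
  }
  w <- lapply(lls, waic)
  l <- lapply(lls, psis_loo)
  tab <- data.frame(
    variant = names(fits),
    waic = vapply(w, `[[`, 0, "waic"), waic_se = vapply(w, `[[`, 0, "se"),
    looic = vapply(l, `[[`, 0, "looic"), looic_se = vapply(l, `[[`, 0, "se"),
    p_waic = vapply(w, `[[`, 0, "p_waic"),
    max_pareto_k = vapply(l, function(x) max(x$pareto_k, na.rm = TRUE), 0),
    stringsAsFactors = FALSE
  )
  n <- ncols[[1]]
  diff_vs_best <- function(point_list, best) {
    vapply(seq_along(point_list), function(i) {
      d <- point_list[[best]] - point_list[[i]] # elpd scale, >= 0 for best
      c(diff = 2 * sum(d), se = 2 * sqrt(n * stats::var(d)))
    }, numeric(2))
  }
  bw <- which.min(tab$waic)
  bl <- which.min(tab$looic)
  dw <- diff_vs_best(lapply(w, `[[`, "pointwise"), bw)
  dl <- diff_vs_best(lapply(l, `[[`, "pointwise"), bl)
  tab$waic_diff <- dw["diff", ]
  tab$waic_diff_se <- dw["se", ]
  tab$looic_diff <- dl["diff", ]
  tab$looic_diff_se <- dl["se", ]
  structure(tab, class = c("information_criteria_table", "data.frame"))
}
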