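#' Force trace
#'
#' A force trace is a vector of force samples (newtons) recorded at a fixed
#' rate. The study hardware sampled at 60 Hz; sample `i` is timestamped
#' `(i - 1) / rate` seconds.
#'
#' @param samples Numeric vector of force values in newtons.
#' @param rate Sampling rate in Hz.
#' @return An object of class `force_trace` with fields `samples`, `rate` and
#'   `duration` (seconds).
#' @export
force_trace <- function(samples, rate = 60) {
  stopifnot(is.numeric(samples), length(samples) > 0, rate > 0)
  structure(list(samples = as.numeric(samples), rate = rate,
                 duration = length(samples) / rate),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("force_trace: %d samples at %g Hz (%.2f s), mean %.2f N\n",
              length(x$samples), x$rate, x$duration, mean(x$samples)))
  invisible(x)
}

#' Maximum-force calibration
#'
#' For each calibration trace, slides a window of `window_s` seconds over the
#' samples (advancing one sample at a time), selects the window with the
#' lowest variance, and takes its mean force. The participant's maximum force
#' is the largest of these means across traces. The study used three 10-second
#' maximal holds with a 5-second window.
#'
#' @param traces A list of [force_trace()] objects (a single trace is
#'   accepted).
#' @param window_s Window length in seconds.
#' @return Maximum force in newtons.
#' @export
calibrate_max_force <- function(traces, window_s = 5) {
  if (inherits(traces, "force_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1)
  vals <- vapply(traces, function(tr) {
    stopifnot(inherits(tr, "force_trace"))
    w <- as.integer(round(window_s * tr$rate))
    n <- length(tr$samples)
    if (w < 1L || w > n) {
      stop("trace shorter than the calibration window", call. = FALSE)
    }
    x <- tr$samples
    cs <- c(0, cumsum(x))
    cs2 <- c(0, cumsum(x^2))
    starts <- seq_len(n - w + 1L)
    m <- (cs[starts + w] - cs[starts]) / w
    # population variance; the argmin is what matters, the convention is fixed
    v <- (cs2[starts + w] - cs2[starts]) / w - m^2
    v <- pmax(v, 0)
    m[which.min(v)]
  }, numeric(1))
  max(vals)
}

#' Relative force response
#'
#' Mean force over a time window (default 1.5 to 2.5 seconds, half-open on the
#' right) divided by the participant's maximum force.
#'
#' @param trace A [force_trace()].
#' @param max_force Maximum force in newtons; must be positive.
#' @param window Length-2 numeric, window in seconds `[start, end)`.
#' @return Relative force (dimensionless, >= 0 for non-negative traces).
#' @export
compute_force_response <- function(trace, max_force, window = c(1.5, 2.5)) {
  stopifnot(inherits(trace, "force_trace"), length(window) == 2)
  if (max_force <= 0) stop("max_force must be positive", call. = FALSE)
  t <- (seq_along(trace$samples) - 1) / trace$rate
  sel <- t >= window[1] & t < window[2]
  if (!any(sel)) stop("trace does not span the response window", call. = FALSE)
  mean(trace$samples[sel]) / max_force
}

#' Signed force error in percentage points
#'
#' Difference between the force response and the relative force required to
#' stop the ball exactly on target, expressed in percentage points of maximum
#' force.
#'
#' @param force_response Relative force actually produced.
#' @param required_force Relative force required for a perfect trial.
#' @return Signed percentage points.
#' @export
compute_force_error <- function(force_response, required_force) {
  (force_response - required_force) * 100
}
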