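# Time-causal temporal smoothing: cascades of first-order integrators
# (truncated exponential filters with time constants mu_k), plus non-causal
# temporal Gaussians for batch spatio-temporal analysis.
#
# Discretization: the discrete cascade kernel is defined as the impulse
# response of the cascade of exact-exponential-step integrators, i.e. each
# stage contributes geometric weights (1 - a) a^n with a = exp(-dt/mu_k).
# These weights equal the bin integrals of the continuous exponential over
# [n dt, (n+1) dt], so tap times carry one half-step shift per stage,
# (n + K/2) dt for a K-stage cascade;
# with that convention the discrete mean and variance match the continuous
# cascade (sum mu_k and sum mu_k^2) to O((dt/mu)^2).  This construction makes
# streaming recursive updating and batch convolution agree exactly, keeps DC
# gain exactly 1, and is causal bitwise: there are no taps at t < 0.

#' Sampled time-causal exponential-cascade kernel
#'
#' The temporal smoothing kernel formed by coupling first-order integrators
#' with time constants `mu` in cascade. The returned object holds the
#' discrete taps (summing to 1 after tail truncation and renormalization),
#' their bin-centred times, and the sampling step.
#'
#' @param mu vector of time constants (frames), all > 0.
#' @param dt sampling step; defaults to `min(1, min(mu)/8)` so the fastest
#'   stage is resolved by at least 8 samples.
#' @param tail_mass truncation: the kernel is cut where the remaining tail
#'   holds less than this mass.
#' @return Object of class `temporal_kernel` with fields `taps`, `times`,
#'   `dt`, `mu`, `causal = TRUE`.
#' @export
exp_cascade_kernel <- function(mu, dt = NULL, tail_mass = 1e-8) {
  if (length(mu) < 1 || any(!is.finite(mu)) || any(mu <= 0))
    stop("exp_cascade_kernel: need at least one positive time constant")
  if (is.null(dt)) dt <- min(1, min(mu) / 8)
  if (dt <= 0) stop("exp_cascade_kernel: dt must be positive")
  # support: grow until the truncated tail mass (exactly 1 - sum(taps) for
  # the geometric cascade) falls below tail_mass; the tail carries the
  # second moment, so a generous horizon is needed for variance fidelity
  n <- max(ceiling((sum(mu) + 8 * sqrt(sum(mu^2))) / dt), 8L)
  repeat {
    taps <- c(1, rep(0, n - 1))
    for (m in mu) {
      a <- exp(-dt / m)
      taps <- as.numeric(stats::filter(taps * (1 - a), filter = a,
                                       method = "recursive"))
    }
    if (1 - sum(taps) < tail_mass || n > 5e6) break
    n <- 2L * n
  }
  keep <- max(which(rev(cumsum(rev(taps))) > tail_mass), 2L)
  taps <- taps[seq_len(min(keep, n))]
  taps <- taps / sum(taps)
  # tap times: each of the K bin-integration stages centres its bin, so the
  # discrete cascade sits at (n + K/2) dt; with this convention discrete
  # mean and variance match sum(mu) and sum(mu^2) to O((dt/mu)^2)
  structure(list(taps = taps,
                 times = (seq_along(taps) - 1 + length(mu) / 2) * dt,
                 dt = dt, mu = mu, causal = TRUE),
            class = "temporal_kernel")
}

#' Sampled non-causal temporal Gaussian kernel
#'
#' 1-D Gaussian of variance `temporal_variance` with optional delay `delay`,
#' sampled at step `dt`, optionally differentiated analytically (orders 0-2).
#'
#' @param temporal_variance variance (frame^2), > 0.
#' @param delay temporal delay of the kernel centre (frames).
#' @param order temporal differentiation order, 0, 1 or 2.
#' @param dt sampling step (frames).
#' @param truncate support radius in standard deviations.
#' @return `temporal_kernel` with `causal = FALSE`; zero-order taps sum to 1,
#'   derivative taps to 0.
#' @export
temporal_gaussian_kernel <- function(temporal_variance, delay = 0, order = 0,
                                     dt = 1, truncate = 5) {
  if (temporal_variance <= 0)
    stop("temporal_gaussian_kernel: variance must be positive")
  if (!order %in% 0:2)
    stop("temporal_gaussian_kernel: temporal order must be 0, 1 or 2")
  sdv <- sqrt(temporal_variance)
  r <- ceiling((truncate * sdv + abs(delay)) / dt)
  times <- seq(-r, r) * dt
  tc <- times - delay
  g <- exp(-tc^2 / (2 * temporal_variance)) /
    sqrt(2 * pi * temporal_variance)
  taps <- switch(as.character(order),
                 "0" = g,
                 "1" = -tc / temporal_variance * g,
                 "2" = (tc^2 / temporal_variance^2 -
                          1 / temporal_variance) * g)
  taps <- taps * dt
  if (order == 0) taps <- taps / sum(taps) else taps <- taps - mean(taps)
  structure(list(taps = taps, times = times, dt = dt,
                 temporal_variance = temporal_variance, delay = delay,
                 order = order, causal = FALSE),
            class = "temporal_kernel")
}

#' @export
print.temporal_kernel <- function(x, ...) {
  cat(sprintf("<temporal_kernel %s, %d taps, dt = %g, sum %.3g>\n",
              if (x$causal) "causal" else "non-causal",
              length(x$taps), x$dt, sum(x$taps)))
  invisible(x)
}

# moments of a temporal kernel (about its tap times)
temporal_kernel_moments <- function(k) {
  w <- k$taps / sum(k$taps)
  m <- sum(w * k$times)
  v <- sum(w * (k$times - m)^2)
  list(mean = m, variance = v)
}

#' One step of the recursive first-order temporal integrator
#'
#' The streaming update between adjacent temporal scale levels: with the
#' exact exponential step `a = exp(-dt/mu)`,
#' `out = a * previous_output + (1 - a) * new_input`. Applying the update
#' over a sequence is equivalent to convolution with the corresponding
#' cascade kernel, preserves DC gain exactly, and is unconditionally stable
#' for any `mu`.
#'
#' @param previous_output scalar field (numeric scalar, vector, matrix) at
#'   the previous time step.
#' @param new_input scalar field at the current time step.
#' @param mu time constant (> 0).
#' @param dt time step (> 0).
#' @return updated scalar field, same shape as the input.
#' @export
recursive_temporal_update <- function(previous_output, new_input, mu, dt = 1) {
  if (mu <= 0 || dt <= 0)
    stop("recursive_temporal_update: mu and dt must be positive")
  a <- exp(-dt / mu)
  a * previous_output + (1 - a) * new_input
}

#' Stream a signal through an integrator cascade
#'
#' Applies [recursive_temporal_update()] for each time constant in `mu` in
#' cascade along a sampled signal (vector) or along the first axis of a 3-D
#' array. Initial internal states are zero.
#'
#' @param x numeric vector, or 3-D array `(t, y, x)`.
#' @param mu vector of time constants.
#' @param dt sampling step.
#' @return filtered object of the same shape.
#' @export
stream_exp_cascade <- function(x, mu, dt = 1) {
  a <- exp(-dt / mu)
  if (is.array(x) && length(dim(x)) == 3) {
    d <- dim(x)
    states <- lapply(mu, function(m) matrix(0, d[2], d[3]))
    out <- array(0, d)
    for (t in seq_len(d[1])) {
      cur <- x[t, , ]
      for (k in seq_along(mu)) {
        states[[k]] <- a[k] * states[[k]] + (1 - a[k]) * cur
        cur <- states[[k]]
      }
      out[t, , ] <- cur
    }
    out
  } else {
    cur <- as.numeric(x)
    for (k in seq_along(mu))
      cur <- as.numeric(stats::filter(cur * (1 - a[k]), filter = a[k],
                                      method = "recursive"))
    cur
  }
}

# n-th discrete temporal derivative of a causal temporal kernel: backward
# differences (preserve causality), mean-corrected to exact zero sum.
causal_temporal_derivative <- function(k, order) {
  taps <- k$taps
  for (i in seq_len(order)) taps <- (taps - c(0, taps[-length(taps)])) / k$dt
  taps <- taps - mean(taps)
  structure(list(taps = taps, times = k$times, dt = k$dt, mu = k$mu,
                 causal = TRUE, order = order),
            class = "temporal_kernel")
}
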