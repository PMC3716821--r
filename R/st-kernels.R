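# Spatio-temporal receptive-field kernels.  The zero-order kernel factorizes
# as a velocity-translating affine spatial Gaussian times a temporal
# smoother,
#     T(x, y, t) = g(x - v t; Sigma) h(t - delta),
# where h is either a non-causal 1-D Gaussian or the time-causal
# exponential-cascade kernel.  Spatial derivatives act on the Gaussian
# factor; the velocity-adapted temporal derivative
# dt_bar = vx dx + vy dy + dt annihilates the translating Gaussian factor,
# so dt_bar^n T = [spatial factor] h^(n)(t - delta).

#' Spatio-temporal covariance specification
#'
#' Bundles the spatial covariance, image velocity and temporal variance of a
#' spatio-temporal receptive field. The induced 3x3 space-time covariance
#' (over `(x, y, t)`) is
#' `rbind(cbind(Sigma + lt v v', lt v), c(lt v', lt))`,
#' which is symmetric positive definite whenever `Sigma` is SPD and
#' `lt > 0`.
#'
#' @param spatial a `spatial_covariance` (or 2x2 SPD matrix / scalar
#'   variance).
#' @param velocity image velocity `(vx, vy)` in pixels/frame; positive `vx`
#'   is rightward motion (increasing column index).
#' @param temporal_variance temporal variance `lt` (frame^2).
#' @return Object of class `st_covariance` with fields `spatial`,
#'   `velocity`, `temporal_variance` and the induced `matrix`.
#' @export
st_covariance <- function(spatial, velocity = c(0, 0), temporal_variance = 1) {
  spatial <- as_spatial_covariance(spatial)
  v <- as.numeric(velocity)
  if (length(v) != 2 || any(!is.finite(v)))
    stop("st_covariance: velocity must be (vx, vy)")
  if (temporal_variance <= 0)
    stop("st_covariance: temporal variance must be positive")
  M <- rbind(cbind(spatial$sigma + temporal_variance * tcrossprod(v),
                   temporal_variance * v),
             c(temporal_variance * v, temporal_variance))
  if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("st_covariance: induced space-time covariance is not PD")
  structure(list(spatial = spatial, velocity = v,
                 temporal_variance = temporal_variance, matrix = M),
            class = "st_covariance")
}

#' @export
print.st_covariance <- function(x, ...) {
  cat(sprintf("<st_covariance v = (%g, %g), temporal variance %g>\n",
              x$velocity[1], x$velocity[2], x$temporal_variance))
  print(x$spatial)
  invisible(x)
}

st_kernel_obj <- function(values, frame_offsets, spec) {
  structure(values, frame_offsets = frame_offsets, spec = spec,
            class = c("st_kernel", "array"))
}

#' @export
print.st_kernel <- function(x, ...) {
  d <- dim(x)
  fo <- attr(x, "frame_offsets")
  cat(sprintf("<st_kernel %d frames (offsets %d..%d) of %d x %d, sum %.3g>\n",
              d[1], min(fo), max(fo), d[2], d[3], sum(x)))
  invisible(x)
}

# shared builder for both causal and non-causal spatio-temporal kernels
build_st_kernel <- function(spatial_cov, velocity, temporal_taps,
                            frame_offsets, spatial_orders, phi, truncate,
                            spec) {
  cov <- as_spatial_covariance(spatial_cov)
  m1 <- spatial_orders[1]; m2 <- spatial_orders[2]
  check_orders(m1, m2)
  if (is.null(phi)) phi <- cov$theta
  C <- if (m1 + m2 > 0) deriv_polynomial(m1, m2, phi, solve(cov$sigma))
       else NULL
  r <- kernel_radii(cov$sigma, truncate)
  tmax <- max(abs(frame_offsets))
  rx <- r[["rx"]] + ceiling(abs(velocity[1]) * tmax)
  ry <- r[["ry"]] + ceiling(abs(velocity[2]) * tmax)
  xs <- seq(-rx, rx); ys <- seq(-ry, ry)
  vals <- array(0, c(length(frame_offsets), length(ys), length(xs)))
  for (i in seq_along(frame_offsets)) {
    t <- frame_offsets[i]
    slice <- gauss_poly_grid(cov$sigma, C,
                             xs - velocity[1] * t, ys - velocity[2] * t)
    if (m1 + m2 > 0) slice <- slice - mean(slice) # per-frame zero DC
    vals[i, , ] <- temporal_taps[i] * slice
  }
  total_order <- m1 + m2 + (spec$temporal_order %||% 0)
  if (total_order == 0) vals <- vals / sum(vals)
  st_kernel_obj(vals, frame_offsets, spec)
}

#' Non-causal Gaussian spatio-temporal kernel
#'
#' Samples the 3-D Gaussian receptive field with spatial covariance `Sigma`,
#' image velocity `v` and temporal variance `lt`, with mean
#' `(delay * v, delay)`: a velocity-translating affine spatial Gaussian
#' times a delayed temporal Gaussian. Spatial derivative orders act along
#' `phi` / `phi + pi/2`; the temporal order applies the velocity-adapted
#' temporal derivative `dt_bar = vx dx + vy dy + dt`, realized analytically
#' as the n-th derivative of the temporal Gaussian factor.
#'
#' @param covariance an `st_covariance` (or arguments acceptable to one via
#'   `spatial`).
#' @param spatial_orders `(m1, m2)`, total at most 4.
#' @param temporal_order n, at most 2.
#' @param delay temporal delay (frames).
#' @param phi first spatial differentiation axis; defaults to the
#'   major-axis orientation of the spatial covariance.
#' @param truncate support radius in standard deviations.
#' @return `st_kernel`: 3-D array `(t, y, x)` with attribute
#'   `frame_offsets`.
#' @export
gaussian_st_kernel <- function(covariance, spatial_orders = c(0, 0),
                               temporal_order = 0, delay = 0, phi = NULL,
                               truncate = 5) {
  if (!inherits(covariance, "st_covariance"))
    stop("gaussian_st_kernel: covariance must be an st_covariance")
  if (!temporal_order %in% 0:2)
    stop("gaussian_st_kernel: temporal order must be 0, 1 or 2")
  h <- temporal_gaussian_kernel(covariance$temporal_variance, delay = delay,
                                order = temporal_order, dt = 1,
                                truncate = truncate)
  build_st_kernel(covariance$spatial, covariance$velocity, h$taps,
                  as.integer(round(h$times)), spatial_orders, phi, truncate,
                  spec = list(type = "st_gauss", covariance = covariance,
                              spatial_orders = spatial_orders,
                              temporal_order = temporal_order,
                              delay = delay, causal = FALSE))
}

#' Time-causal spatio-temporal kernel
#'
#' The product of a velocity-translating affine spatial Gaussian
#' `g(x - v t; Sigma)` and the time-causal exponential-cascade temporal
#' kernel with time constants `mu` (one tap per frame). All taps at `t < 0`
#' are exactly zero. Temporal derivatives are realized as mean-corrected
#' backward differences of the cascade taps, preserving causality.
#'
#' @param covariance an `st_covariance`; its `temporal_variance` is ignored
#'   in favour of `mu`.
#' @param mu time constants of the integrator cascade (frames).
#' @param spatial_orders `(m1, m2)`.
#' @param temporal_order n, at most 2.
#' @param phi spatial differentiation axis.
#' @param truncate spatial support radius in standard deviations.
#' @return `st_kernel` with `frame_offsets` starting at 0.
#' @export
time_causal_st_kernel <- function(covariance, mu, spatial_orders = c(0, 0),
                                  temporal_order = 0, phi = NULL,
                                  truncate = 5) {
  if (!inherits(covariance, "st_covariance"))
    stop("time_causal_st_kernel: covariance must be an st_covariance")
  if (!temporal_order %in% 0:2)
    stop("time_causal_st_kernel: temporal order must be 0, 1 or 2")
  h <- exp_cascade_kernel(mu, dt = 1, tail_mass = 1e-6)
  if (temporal_order > 0) h <- causal_temporal_derivative(h, temporal_order)
  build_st_kernel(covariance$spatial, covariance$velocity, h$taps,
                  seq_along(h$taps) - 1L, spatial_orders, phi, truncate,
                  spec = list(type = "st_causal", covariance = covariance,
                              mu = mu, spatial_orders = spatial_orders,
                              temporal_order = temporal_order,
                              causal = TRUE))
}

#' Spatio-temporal derivative kernel
#'
#' Applies spatial directional derivatives and the velocity-adapted temporal
#' derivative to the zero-order spatio-temporal kernel; dispatches to
#' [gaussian_st_kernel()] or [time_causal_st_kernel()] according to
#' `causal`.
#'
#' @inheritParams gaussian_st_kernel
#' @param causal use the time-causal cascade smoother.
#' @param mu time constants (causal case).
#' @return `st_kernel`.
#' @export
st_derivative_kernel <- function(covariance, spatial_orders = c(0, 0),
                                 temporal_order = 0, causal = FALSE,
                                 mu = NULL, delay = 0, phi = NULL,
                                 truncate = 5) {
  if (causal) {
    if (is.null(mu))
      stop("st_derivative_kernel: causal kernels need time constants mu")
    time_causal_st_kernel(covariance, mu, spatial_orders, temporal_order,
                          phi, truncate)
  } else {
    gaussian_st_kernel(covariance, spatial_orders, temporal_order, delay,
                       phi, truncate)
  }
}

#' Convolve an image sequence with a spatio-temporal kernel
#'
#' Full 2+1-D convolution: for each temporal tap the corresponding spatial
#' slice is applied by 2-D convolution and the results are accumulated over
#' frame offsets, `out(t) = sum_tau conv2(seq(t - tau), K(tau))`. Boundary
#' handling is mirror in space; in time either mirror (non-causal kernels)
#' or replicate of the first frame (causal kernels, emulating a sequence
#' that starts from rest).
#'
#' @param seq an `image_sequence`.
#' @param kernel an `st_kernel`.
#' @param boundary_t temporal boundary, `"mirror"` or `"replicate"`.
#' @return `image_sequence` of responses, same size.
#' @export
st_convolve <- function(seq, kernel, boundary_t = NULL) {
  stopifnot(inherits(seq, "image_sequence"), inherits(kernel, "st_kernel"))
  spec <- attr(kernel, "spec")
  if (is.null(boundary_t))
    boundary_t <- if (isTRUE(spec$causal)) "replicate" else "mirror"
  fo <- attr(kernel, "frame_offsets")
  d <- dim(seq); nt <- d[1]
  # pre-filter each frame with each distinct spatial slice is wasteful;
  # instead convolve each frame once per needed (frame, slice) pairing
  out <- array(0, d)
  raw <- unclass(seq)
  for (i in seq_along(fo)) {
    slice <- kernel2d_from_slice(kernel, i)
    if (all(slice == 0)) next
    src <- seq_len(nt) - fo[i]
    src <- if (boundary_t == "mirror") mirror_index(src, nt)
           else replicate_index(src, nt)
    uf <- unique(src)
    convs <- lapply(uf, function(f) unclass(convolve2(raw[f, , ], slice)))
    for (t in seq_len(nt))
      out[t, , ] <- out[t, , ] + convs[[match(src[t], uf)]]
  }
  image_sequence(out, frame_spacing = attr(seq, "frame_spacing"),
                 pixel_spacing = attr(seq, "pixel_spacing"))
}

kernel2d_from_slice <- function(stk, i) {
  m <- unclass(stk)[i, , ]
  kernel2d(m)
}
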