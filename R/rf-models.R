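# Idealized phenomenological receptive-field models: LGN center-surround
# cells as (sign) x Laplacian-of-Gaussian composed with temporal smoothing /
# differentiation, and V1 simple cells as directional derivatives of affine
# Gaussians, optionally velocity-adapted over space-time.
#
# Polarity convention: on-center cells are modelled as -laplacian(g), whose
# response to a bright central blob is positive (centre-positive response);
# off-center cells flip the sign.

#' Idealized LGN centre-surround kernel
#'
#' `polarity * (-laplacian g)(x, y; s)`, optionally composed with the n-th
#' temporal derivative of a temporal smoother (space-time separable). With
#' `polarity = +1` the kernel is on-centre: centre-positive response to a
#' bright blob. The spatial taps sum exactly to zero, so any constant
#' stimulus yields a zero response.
#'
#' @param spatial_scale variance s > 0 (pixel^2).
#' @param polarity +1 (on-centre) or -1 (off-centre).
#' @param temporal `NULL` for a purely spatial kernel, or a
#'   `temporal_kernel` (from [exp_cascade_kernel()] or
#'   [temporal_gaussian_kernel()]).
#' @param temporal_order temporal differentiation order n >= 0.
#' @param truncate support radius in standard deviations.
#' @return a `kernel2d` when `temporal` is NULL, otherwise an `st_kernel`.
#' @export
lgn_kernel <- function(spatial_scale, polarity = 1, temporal = NULL,
                       temporal_order = 0, truncate = 5) {
  if (!polarity %in% c(-1, 1)) stop("lgn_kernel: polarity must be +1 or -1")
  sp <- log_kernel(spatial_scale, truncate = truncate)
  sp_vals <- -polarity * unclass(sp)
  if (is.null(temporal)) {
    return(kernel2d(sp_vals, spec = list(type = "lgn",
                                         spatial_scale = spatial_scale,
                                         polarity = polarity)))
  }
  h <- temporal
  if (temporal_order > 0) {
    h <- if (h$causal) causal_temporal_derivative(h, temporal_order)
         else temporal_gaussian_kernel(h$temporal_variance,
                                       delay = h$delay %||% 0,
                                       order = temporal_order, dt = h$dt)
  }
  fo <- if (h$causal) seq_along(h$taps) - 1L else as.integer(round(h$times))
  vals <- array(0, c(length(h$taps), nrow(sp_vals), ncol(sp_vals)))
  for (i in seq_along(h$taps)) vals[i, , ] <- h$taps[i] * sp_vals
  st_kernel_obj(vals, fo,
                spec = list(type = "lgn", spatial_scale = spatial_scale,
                            polarity = polarity,
                            temporal_order = temporal_order,
                            causal = h$causal))
}

#' Difference-of-Gaussians kernel
#'
#' `g(.; s2) - g(.; s1)` with `s2 > s1`, the classical centre-surround
#' approximation to the scaled Laplacian `(s2 - s1)/2 * laplacian g` at the
#' mid-scale, via the diffusion equation `ds g = 1/2 laplacian g`.
#'
#' @param s1,s2 variances, `s2 > s1 > 0`.
#' @param truncate support radius in standard deviations.
#' @return `kernel2d` with zero tap sum.
#' @export
dog_kernel <- function(s1, s2, truncate = 5) {
  if (!(s2 > s1 && s1 > 0)) stop("dog_kernel: need s2 > s1 > 0")
  k2 <- gaussian_kernel(s2, truncate)
  k1 <- gaussian_kernel(s1, truncate)
  r2 <- attr(k2, "support_radius"); r1 <- attr(k1, "support_radius")
  v1 <- pad_matrix(unclass(k1), r2[1] - r1[1], r2[2] - r1[2], "constant")
  kernel2d(unclass(k2) - v1, spec = list(type = "dog", s1 = s1, s2 = s2))
}

#' Relative discrepancy between a DoG and the scaled Laplacian
#'
#' L2-relative error between `dog_kernel(s1, s2)` and
#' `(s2 - s1) * 1/2 * laplacian g` at the mid-scale `(s1 + s2)/2`; tends to
#' zero as `s2/s1 -> 1`.
#'
#' @inheritParams dog_kernel
#' @return scalar relative L2 error.
#' @export
log_dog_discrepancy <- function(s1, s2, truncate = 5) {
  dog <- dog_kernel(s1, s2, truncate)
  lg <- log_kernel((s1 + s2) / 2, truncate)
  rd <- attr(dog, "support_radius"); rl <- attr(lg, "support_radius")
  r <- pmax(rd, rl)
  a <- pad_matrix(unclass(dog), r[1] - rd[1], r[2] - rd[2], "constant")
  b <- pad_matrix(unclass(lg), r[1] - rl[1], r[2] - rl[2], "constant") *
    (s2 - s1) / 2
  sqrt(sum((a - b)^2) / sum(b^2))
}

#' Idealized V1 simple-cell kernel
#'
#' Purely spatial form: the directional derivative of an affine Gaussian,
#' `d_phi^m1 d_phiperp^m2 g(x; Sigma)` (an oriented odd- or even-symmetric
#' profile). With a temporal part: the velocity-adapted spatio-temporal
#' derivative kernel, delegating to [st_derivative_kernel()].
#'
#' @param covariance `spatial_covariance` (or matrix / scalar variance).
#' @param spatial_orders `(m1, m2)`.
#' @param phi preferred orientation; defaults to the covariance
#'   orientation.
#' @param velocity image velocity `(vx, vy)` for velocity-adapted cells.
#' @param temporal `NULL` for purely spatial, else a list with either
#'   `temporal_variance` (+ optional `delay`) for the non-causal Gaussian or
#'   `mu` for the time-causal cascade.
#' @param temporal_order temporal differentiation order.
#' @param truncate support radius in standard deviations.
#' @return `kernel2d` (spatial) or `st_kernel` (spatio-temporal).
#' @export
v1_simple_kernel <- function(covariance, spatial_orders = c(1, 0),
                             phi = NULL, velocity = c(0, 0),
                             temporal = NULL, temporal_order = 0,
                             truncate = 5) {
  cov <- as_spatial_covariance(covariance)
  if (is.null(temporal)) {
    return(directional_derivative_kernel(cov, spatial_orders, phi,
                                         truncate))
  }
  if (!is.null(temporal$mu)) {
    stc <- st_covariance(cov, velocity, temporal_variance = sum(temporal$mu^2))
    st_derivative_kernel(stc, spatial_orders, temporal_order, causal = TRUE,
                         mu = temporal$mu, phi = phi, truncate = truncate)
  } else {
    stc <- st_covariance(cov, velocity, temporal$temporal_variance)
    st_derivative_kernel(stc, spatial_orders, temporal_order,
                         causal = FALSE, delay = temporal$delay %||% 0,
                         phi = phi, truncate = truncate)
  }
}

#' Sample affine covariances as seen from a uniform hemisphere
#'
#' Draws surface normals uniformly on the upper hemisphere; perspective
#' foreshortening of an isotropic surface patch seen from slant `sigma`
#' compresses the minor axis by `cos(slant)`, so the covariance eigenvalue
#' ratio is `lambda2/lambda1 = cos^2(slant)` with the major axis along the
#' tilt azimuth.
#'
#' @param n number of draws.
#' @param lambda1 major-axis variance (pixel^2) of every sample.
#' @param seed integer seed for reproducibility.
#' @return list of `spatial_covariance`, with attributes `slant` and
#'   `azimuth` (radians).
#' @export
hemisphere_covariances <- function(n, lambda1 = 16, seed = 1) {
  set.seed(seed)
  # uniform on hemisphere: cos(slant) ~ sqrt(U), azimuth ~ U(0, 2 pi)
  u <- stats::runif(n)
  slant <- acos(sqrt(u))
  azimuth <- stats::runif(n, 0, 2 * pi)
  covs <- lapply(seq_len(n), function(i)
    spatial_covariance(lambda1 = lambda1,
                       lambda2 = lambda1 * cos(slant[i])^2,
                       theta = azimuth[i] %% pi))
  attr(covs, "slant") <- slant
  attr(covs, "azimuth") <- azimuth
  covs
}

#' Enumerate a gallery of receptive-field kernels
#'
#' Deterministically enumerates the Cartesian grid of parameters and renders
#' one kernel per combination, returning the kernels and a manifest
#' data frame whose `name` column encodes the parameters.
#'
#' @param orientations vector of kernel orientations (radians).
#' @param scales vector of major-axis variances (pixel^2).
#' @param eccentricity ratio lambda2/lambda1 in (0, 1].
#' @param spatial_orders `(m1, m2)` applied to every kernel.
#' @return list with `kernels` (named list of `kernel2d`) and `manifest`
#'   (data frame of parameters in enumeration order).
#' @export
rf_gallery <- function(orientations, scales, eccentricity = 0.25,
                       spatial_orders = c(1, 0)) {
  grid <- expand.grid(theta = orientations, scale = scales,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0)
    return(list(kernels = list(),
                manifest = data.frame(name = character(),
                                      theta = numeric(),
                                      scale = numeric())))
  kernels <- vector("list", nrow(grid))
  names_ <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cov <- spatial_covariance(lambda1 = grid$scale[i],
                              lambda2 = grid$scale[i] * eccentricity,
                              theta = grid$theta[i])
    kernels[[i]] <- directional_derivative_kernel(cov, spatial_orders)
    names_[i] <- sprintf("rf_m%d%d_s%g_th%.3f", spatial_orders[1],
                         spatial_orders[2], grid$scale[i], grid$theta[i])
  }
  names(kernels) <- names_
  list(kernels = kernels,
       manifest = data.frame(name = names_, theta = grid$theta,
                             scale = grid$scale))
}
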