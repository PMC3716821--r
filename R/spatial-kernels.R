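# Analytic machinery: every Gaussian-derivative kernel in the family is a
# polynomial times the zero-order Gaussian,
#     D_u1^m1 D_u2^m2 g(x; Sigma) = P(x) g(x; Sigma),
# and applying one more directional derivative along u maps
#     P  ->  D_u P - P * (u^T Sigma^{-1} x),
# which is closed over bivariate polynomials.  Polynomials are stored as a
# coefficient matrix C with C[i+1, j+1] the coefficient of x^i y^j.

poly_const <- function(value = 1) matrix(value, 1, 1)

poly_pad <- function(C, nx, ny) {
  out <- matrix(0, nx, ny)
  out[seq_len(nrow(C)), seq_len(ncol(C))] <- C
  out
}

poly_add <- function(A, B) {
  nx <- max(nrow(A), nrow(B)); ny <- max(ncol(A), ncol(B))
  poly_pad(A, nx, ny) + poly_pad(B, nx, ny)
}

# d/dx and d/dy of a coefficient matrix
poly_dx <- function(C) {
  if (nrow(C) == 1) return(poly_const(0))
  C2 <- C[-1, , drop = FALSE]
  C2 * (seq_len(nrow(C2)))
}
poly_dy <- function(C) {
  if (ncol(C) == 1) return(poly_const(0))
  C2 <- C[, -1, drop = FALSE]
  sweep(C2, 2, seq_len(ncol(C2)), `*`)
}

# multiply polynomial by (b1*x + b2*y)
poly_mul_linear <- function(C, b1, b2) {
  out <- matrix(0, nrow(C) + 1, ncol(C) + 1)
  if (b1 != 0) out[2:(nrow(C) + 1), 1:ncol(C)] <-
      out[2:(nrow(C) + 1), 1:ncol(C)] + b1 * C
  if (b2 != 0) out[1:nrow(C), 2:(ncol(C) + 1)] <-
      out[1:nrow(C), 2:(ncol(C) + 1)] + b2 * C
  out
}

# one directional derivative of P * g(.; Sigma) along unit vector u
poly_dir_deriv <- function(C, u, sigma_inv) {
  b <- as.numeric(sigma_inv %*% u)
  dP <- poly_add(u[1] * poly_dx(C), u[2] * poly_dy(C))
  poly_add(dP, -poly_mul_linear(C, b[1], b[2]))
}

# evaluate coefficient matrix at vectors x, y (outer grid): returns matrix
# indexed [y, x] to match image storage
poly_eval_grid <- function(C, x, y) {
  acc <- matrix(0, length(y), length(x))
  xp <- outer(seq_len(nrow(C)) - 1, x, function(i, xx) xx^i) # (i, x)
  yp <- outer(seq_len(ncol(C)) - 1, y, function(j, yy) yy^j) # (j, y)
  for (i in seq_len(nrow(C)))
    for (j in seq_len(ncol(C)))
      if (C[i, j] != 0)
        acc <- acc + C[i, j] * outer(yp[j, ], xp[i, ])
  acc
}

# polynomial for D_phi^m1 D_phiperp^m2 applied to g(.; Sigma)
deriv_polynomial <- function(m1, m2, phi, sigma_inv) {
  C <- poly_const(1)
  u1 <- c(cos(phi), sin(phi))
  u2 <- c(-sin(phi), cos(phi))
  for (k in seq_len(m1)) C <- poly_dir_deriv(C, u1, sigma_inv)
  for (k in seq_len(m2)) C <- poly_dir_deriv(C, u2, sigma_inv)
  C
}

check_orders <- function(m1, m2, max_total = 4) {
  if (length(m1) != 1 || length(m2) != 1 ||
      m1 < 0 || m2 < 0 || m1 != round(m1) || m2 != round(m2))
    stop("differentiation orders must be non-negative integers")
  if (m1 + m2 > max_total)
    stop(sprintf("unsupported derivative order: m1 + m2 = %d exceeds %d",
                 m1 + m2, max_total))
}

# kernel support radius: ceil(truncate * per-axis marginal std)
kernel_radii <- function(sigma, truncate = 5) {
  c(ry = ceiling(truncate * sqrt(sigma[2, 2])),
    rx = ceiling(truncate * sqrt(sigma[1, 1])))
}

# Evaluate P(x, y) * g(x, y; Sigma) on the grid spanned by coordinate
# vectors xs, ys (matrix indexed [y, x]); used both for integer-sampled
# spatial kernels and for velocity-shifted spatio-temporal slices.
gauss_poly_grid <- function(sigma, C, xs, ys) {
  si <- solve(sigma)
  q <- outer(ys^2 * si[2, 2], xs^2 * si[1, 1], `+`) +
    2 * si[1, 2] * outer(ys, xs)
  g <- exp(-q / 2) / (2 * pi * sqrt(det(sigma)))
  if (is.null(C) || (nrow(C) == 1 && ncol(C) == 1 && C[1, 1] == 1)) return(g)
  poly_eval_grid(C, xs, ys) * g
}

# Shared sampler: P(x, y) * g(x, y; Sigma) at integer pixel offsets.
# Zero-order kernels are renormalized to unit sum; derivative kernels are
# mean-corrected to exact zero sum (truncation otherwise leaves a small DC
# leak that would break constant-annihilation).
sample_gauss_kernel <- function(sigma, C = poly_const(1), order_total = 0,
                                truncate = 5, spec = NULL) {
  r <- kernel_radii(sigma, truncate)
  x <- seq(-r[["rx"]], r[["rx"]])
  y <- seq(-r[["ry"]], r[["ry"]])
  vals <- gauss_poly_grid(sigma, if (order_total == 0) NULL else C, x, y)
  if (order_total == 0) {
    vals <- vals / sum(vals)
  } else {
    vals <- vals - mean(vals)
  }
  kernel2d(vals, spec = spec)
}

#' Isotropic Gaussian smoothing kernel
#'
#' Samples the rotationally symmetric Gaussian
#' \eqn{g(x, y; s) = \exp(-(x^2+y^2)/2s) / (2\pi s)} at pixel centres,
#' truncated at radius `ceiling(truncate * sqrt(s))` and renormalized to unit
#' tap sum. The scale parameter `s` is a variance (pixel^2) throughout the
#' package; for a standard deviation sigma use `s = sigma^2`.
#'
#' @param scale variance s > 0 in pixel^2.
#' @param truncate support radius in units of the standard deviation.
#' @return `kernel2d` with unit tap sum.
#' @export
gaussian_kernel <- function(scale, truncate = 5) {
  if (!is.numeric(scale) || length(scale) != 1 || !is.finite(scale) ||
      scale <= 0)
    stop("gaussian_kernel: scale must be a positive scalar variance")
  sample_gauss_kernel(diag(2) * scale, truncate = truncate,
                      spec = list(type = "gauss", scale = scale))
}

#' Isotropic Gaussian derivative kernel
#'
#' Samples the analytic partial derivative
#' \eqn{\partial_{u}^{m_1} \partial_{u_\perp}^{m_2} g(x, y; s)} where the
#' first differentiation axis `u` points along angle `phi`. Supported up to
#' total order 4. Derivative kernels are mean-corrected to an exact zero tap
#' sum; odd-order kernels are antisymmetric about their axis.
#'
#' @param orders integer vector `(m1, m2)` of differentiation orders along
#'   `phi` and `phi + pi/2`.
#' @param scale variance s > 0 (pixel^2).
#' @param phi direction of the first differentiation axis (radians).
#' @param truncate support radius in standard deviations.
#' @return `kernel2d` with zero tap sum (or a smoothing kernel if
#'   `orders = c(0, 0)`).
#' @export
gaussian_derivative_kernel <- function(orders, scale, phi = 0, truncate = 5) {
  m1 <- orders[1]; m2 <- orders[2]
  check_orders(m1, m2)
  if (scale <= 0) stop("gaussian_derivative_kernel: scale must be positive")
  sigma <- diag(2) * scale
  C <- deriv_polynomial(m1, m2, phi, solve(sigma))
  sample_gauss_kernel(sigma, C, m1 + m2, truncate,
                      spec = list(type = "dgauss", orders = c(m1, m2),
                                  scale = scale, phi = phi))
}

#' Affine (anisotropic) Gaussian smoothing kernel
#'
#' Samples \eqn{g(x; \Sigma) = \exp(-x^T \Sigma^{-1} x / 2) /
#' (2\pi \sqrt{\det \Sigma})} with the support radius per axis set from the
#' per-axis marginal standard deviation. Orientation is handled analytically
#' through `Sigma = R(theta) diag(lambda1, lambda2) R(theta)^T`; no image
#' resampling is involved.
#'
#' @param covariance a `spatial_covariance`, a 2x2 SPD matrix, or a scalar
#'   variance (isotropic case).
#' @param truncate support radius in marginal standard deviations.
#' @return `kernel2d` with unit tap sum.
#' @export
affine_gaussian_kernel <- function(covariance, truncate = 5) {
  cov <- as_spatial_covariance(covariance)
  sample_gauss_kernel(cov$sigma, truncate = truncate,
                      spec = list(type = "affine", covariance = cov))
}

#' Directional derivative of an affine Gaussian kernel
#'
#' Samples \eqn{\partial_\phi^{m_1} \partial_{\phi_\perp}^{m_2}
#' g(x; \Sigma)}, the directional derivatives along the axis at angle `phi`
#' and its orthogonal complement, expanded analytically as polynomial
#' combinations of partial derivatives (cos/sin powers of `phi`).
#' By default `phi` is the orientation `theta` of the covariance.
#'
#' @param covariance a `spatial_covariance` (or matrix / scalar variance).
#' @param orders integer vector `(m1, m2)`.
#' @param phi first differentiation direction (radians); defaults to the
#'   major-axis orientation of the covariance.
#' @param truncate support radius in marginal standard deviations.
#' @return `kernel2d` with zero tap sum when `m1 + m2 >= 1`.
#' @export
directional_derivative_kernel <- function(covariance, orders, phi = NULL,
                                          truncate = 5) {
  cov <- as_spatial_covariance(covariance)
  m1 <- orders[1]; m2 <- orders[2]
  check_orders(m1, m2)
  if (is.null(phi)) phi <- cov$theta
  C <- deriv_polynomial(m1, m2, phi, solve(cov$sigma))
  sample_gauss_kernel(cov$sigma, C, m1 + m2, truncate,
                      spec = list(type = "dir", covariance = cov,
                                  orders = c(m1, m2), phi = phi))
}

#' Laplacian-of-Gaussian kernel
#'
#' \eqn{\nabla^2 g = g_{xx} + g_{yy}} at scale `s`; the centre tap of the
#' continuous kernel is \eqn{-1/(\pi s^2)}.
#'
#' @inheritParams gaussian_kernel
#' @return `kernel2d` with zero tap sum.
#' @export
log_kernel <- function(scale, truncate = 5) {
  sigma <- diag(2) * scale
  si <- solve(sigma)
  C <- poly_add(deriv_polynomial(2, 0, 0, si), deriv_polynomial(0, 2, 0, si))
  sample_gauss_kernel(sigma, C, 2, truncate,
                      spec = list(type = "log", scale = scale))
}
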