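# Scale-normalized derivatives and automatic scale selection.  Derivative
# responses are multiplied by s^{gamma * order / 2}; local extrema over
# scale of the normalized responses are preserved under spatial rescalings
# (s transforms as c^2 s), which is the basis for scale-invariant
# measurement.  For a Gaussian blob rendered as g(.; t0) the scale-
# normalized Laplacian magnitude at the blob centre is s / (pi (s + t0)^2)
# and the normalized Hessian determinant is s^2 / (4 pi^2 (s + t0)^4), both
# maximal at s = t0 for gamma = 1; these closed forms are the calibration
# oracles for the module.

#' Scale-normalized Gaussian derivative response
#'
#' `s^(gamma (m1 + m2) / 2) * (d^m1_x d^m2_y L)(.; s)`. At `gamma = 1` the
#' normalization corresponds to constant L1-norm of the underlying
#' derivative kernels over scale, and extrema over scale are scale
#' covariant.
#'
#' @param image `image2d` or matrix.
#' @param orders `(m1, m2)` differentiation orders.
#' @param s scale (variance, pixel^2).
#' @param gamma normalization power, default 1.
#' @param phi differentiation axis angle.
#' @return `image2d` of normalized responses.
#' @export
normalized_derivative_response <- function(image, orders, s, gamma = 1,
                                           phi = 0) {
  if (s <= 0 || gamma <= 0)
    stop("normalized_derivative_response: s and gamma must be positive")
  k <- gaussian_derivative_kernel(orders, s, phi)
  resp <- convolve2(image, k)
  as_image2d(unclass(resp) * s^(gamma * sum(orders) / 2), template = resp)
}

#' Scale-normalized Laplacian response
#'
#' `s^gamma * (Lxx + Lyy)` at scale `s`.
#'
#' @inheritParams normalized_derivative_response
#' @return `image2d`.
#' @export
norm_laplacian <- function(image, s, gamma = 1) {
  if (s <= 0) stop("norm_laplacian: s must be positive")
  resp <- convolve2(image, log_kernel(s))
  as_image2d(unclass(resp) * s^gamma, template = resp)
}

#' Scale-normalized determinant-of-Hessian response
#'
#' `s^(2 gamma) * (Lxx Lyy - Lxy^2)` at scale `s`.
#'
#' @inheritParams normalized_derivative_response
#' @return `image2d`.
#' @export
norm_det_hessian <- function(image, s, gamma = 1) {
  if (s <= 0) stop("norm_det_hessian: s must be positive")
  lxx <- unclass(convolve2(image, gaussian_derivative_kernel(c(2, 0), s)))
  lyy <- unclass(convolve2(image, gaussian_derivative_kernel(c(0, 2), s)))
  lxy <- unclass(convolve2(image, gaussian_derivative_kernel(c(1, 1), s)))
  as_image2d((lxx * lyy - lxy^2) * s^(2 * gamma),
             template = if (inherits(image, "image2d")) image else NULL)
}

scale_operator <- function(operator) {
  switch(operator,
         laplacian = norm_laplacian,
         dethess = norm_det_hessian,
         stop("unknown operator: ", operator,
              " (use 'laplacian' or 'dethess')"))
}

#' Logarithmic scale grid
#'
#' @param s_min,s_max scale range (variance units).
#' @param per_octave scale levels per octave (doubling of variance).
#' @return numeric vector of scales.
#' @export
scale_grid <- function(s_min = 1, s_max = 256, per_octave = 2) {
  n <- ceiling(log2(s_max / s_min) * per_octave)
  s_min * 2^(seq(0, n) / per_octave)
}

#' Scale-space signature at a point
#'
#' Samples a scale-normalized operator response at one image point across a
#' scale grid and localizes interior extrema over scale by three-point
#' quadratic interpolation in `log s`.
#'
#' @param image `image2d`.
#' @param point `(x, y)` in 0-based math coordinates; must be interior.
#' @param operator `"laplacian"` or `"dethess"`.
#' @param scales increasing vector of at least 3 scales (log-spaced
#'   recommended, see [scale_grid()]).
#' @param gamma normalization power.
#' @return Object of class `scale_signature`: list with `point`, `samples`
#'   (data frame `s`, `value`), and `extrema` (data frame `s_hat`, `value`,
#'   `type`), ordered by decreasing `|value|`.
#' @export
scale_signature <- function(image, point, operator = "laplacian",
                            scales = scale_grid(), gamma = 1) {
  m <- unclass(as.matrix(image))
  if (length(scales) < 3 || any(diff(scales) <= 0))
    stop("scale_signature: need >= 3 strictly increasing scales")
  x <- point[1]; y <- point[2]
  if (x < 1 || y < 1 || x > ncol(m) - 2 || y > nrow(m) - 2)
    stop("scale_signature: point is on or outside the image border")
  op <- scale_operator(operator)
  vals <- vapply(scales, function(s) {
    r <- unclass(op(m, s, gamma))
    bilinear_sample(r, x, y)
  }, numeric(1))
  ext <- find_scale_extrema(scales, vals)
  structure(list(point = point, operator = operator, gamma = gamma,
                 samples = data.frame(s = scales, value = vals),
                 extrema = ext),
            class = "scale_signature")
}

#' @export
print.scale_signature <- function(x, ...) {
  cat(sprintf("<scale_signature %s at (%g, %g): %d scales, %d extrema>\n",
              x$operator, x$point[1], x$point[2], nrow(x$samples),
              nrow(x$extrema)))
  if (nrow(x$extrema)) print(x$extrema)
  invisible(x)
}

# interior extrema of (scales, values) with quadratic refinement in log s
find_scale_extrema <- function(scales, vals) {
  n <- length(vals)
  out <- data.frame(s_hat = numeric(), value = numeric(),
                    type = character())
  ls <- log(scales)
  for (i in 2:(n - 1)) {
    is_max <- vals[i] > vals[i - 1] && vals[i] > vals[i + 1]
    is_min <- vals[i] < vals[i - 1] && vals[i] < vals[i + 1]
    if (!is_max && !is_min) next
    # quadratic fit through the three points in (log s, value)
    x0 <- ls[i - 1] - ls[i]; x2 <- ls[i + 1] - ls[i]
    y0 <- vals[i - 1]; y1 <- vals[i]; y2 <- vals[i + 1]
    denom <- x0 * x2 * (x0 - x2)
    a <- (x2 * (y0 - y1) - x0 * (y2 - y1)) / denom
    b <- (x0^2 * (y2 - y1) - x2^2 * (y0 - y1)) / denom
    dx <- if (abs(a) > 0) -b / (2 * a) else 0
    dx <- max(min(dx, x2), x0)
    vhat <- y1 + b * dx + a * dx^2
    out <- rbind(out, data.frame(s_hat = exp(ls[i] + dx), value = vhat,
                                 type = if (is_max) "max" else "min"))
  }
  out[order(-abs(out$value)), , drop = FALSE]
}

#' Select scale at a point and cut a scale-normalized patch
#'
#' Runs [scale_signature()], selects the strongest interior extremum over
#' scale (largest `|normalized value|`), and resamples a patch around the
#' point by the zoom factor `sqrt(reference_scale / s_hat)` so that
#' structures selected at different scales land in a common reference
#' frame. Two images related by `f'(x) = f(x / c)` yield (up to
#' interpolation) identical normalized patches.
#'
#' @inheritParams scale_signature
#' @param reference_scale scale of the common reference frame (variance
#'   units).
#' @param patch_radius half-width of the output patch (pixels).
#' @return list with `s_hat`, `value`, `type`, `patch` (matrix of side
#'   `2 * patch_radius + 1`) and the full `signature`.
#' @export
select_scale_and_normalize <- function(image, point, operator = "laplacian",
                                       scales = scale_grid(), gamma = 1,
                                       reference_scale = 16,
                                       patch_radius = 16) {
  sig <- scale_signature(image, point, operator, scales, gamma)
  if (nrow(sig$extrema) == 0)
    stop("select_scale_and_normalize: no interior extremum over scale; ",
         "signature is monotone over [", min(scales), ", ", max(scales),
         "]")
  best <- sig$extrema[1, ]
  zoom <- sqrt(best$s_hat / reference_scale) # patch coord -> image offset
  B <- diag(2) * zoom
  patch <- sample_patch(image, point, B, patch_radius)
  list(s_hat = best$s_hat, value = best$value, type = best$type,
       patch = patch, signature = sig)
}
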