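# Logarithmic luminosity and invariance of derivative responses under
# multiplicative intensity transformations.  On a log scale a global gain
# f -> c f becomes an additive offset log c, which every derivative kernel
# (zero tap sum) annihilates exactly; zero-order responses shift by log c
# (equivariance, not invariance).  For a scene f = albedo * illumination,
# log f = log a + log i, so wherever the illumination field is constant
# over the kernel support, derivative responses to log f equal responses to
# the log albedo alone.

#' Logarithmic luminosity transform
#'
#' Natural log of the luminance values after clamping at a positive floor.
#' Values below the floor are counted and clamped (reported in the
#' `clamped` attribute) rather than producing non-finite output.
#'
#' @param image matrix or `image2d` of linear luminances.
#' @param floor positive clamp applied before the log; interpreted as a
#'   fraction of the dynamic range when `relative_floor = TRUE` (default),
#'   else as an absolute luminance.
#' @param relative_floor see `floor`.
#' @return `image2d` of log luminances with attribute `clamped` (count of
#'   clamped pixels).
#' @export
log_transform <- function(image, floor = 1e-6, relative_floor = TRUE) {
  m <- unclass(as.matrix(image))
  eps <- if (relative_floor) floor * max(max(m) - min(m), .Machine$double.eps)
         else floor
  if (eps <= 0) stop("log_transform: floor must be positive")
  n_clamped <- sum(m < eps)
  if (n_clamped > 0)
    warning(sprintf("log_transform: %d value(s) below floor %g were clamped",
                    n_clamped, eps))
  out <- as_image2d(log(pmax(m, eps)),
                    template = if (inherits(image, "image2d")) image else NULL)
  attr(out, "clamped") <- n_clamped
  out
}

#' Check invariance of a derivative response under a global gain
#'
#' Compares the derivative response of `log(f)` with that of `log(c f)` and
#' returns the maximum absolute discrepancy (exactly zero in the continuum;
#' machine precision discretely, because a derivative kernel has zero tap
#' sum and `log(c f) = log f + log c`). Zero-order kernels are rejected:
#' their response shifts by `log c` and is not invariant.
#'
#' @param image strictly positive luminance image.
#' @param orders derivative orders `(m1, m2)` with `m1 + m2 >= 1`.
#' @param scale kernel scale (variance, pixel^2).
#' @param factor the multiplicative gain c > 0.
#' @return maximum absolute discrepancy between the two response fields.
#' @export
multiplicative_invariance_check <- function(image, orders, scale, factor) {
  if (sum(orders) < 1)
    stop("multiplicative_invariance_check: a zero-order receptive field ",
         "is affected by a multiplicative intensity transformation; ",
         "invariance requires derivative order >= 1")
  if (factor <= 0) stop("multiplicative_invariance_check: factor must be > 0")
  m <- unclass(as.matrix(image))
  if (min(m) <= 0)
    stop("multiplicative_invariance_check: image must be strictly positive")
  k <- gaussian_derivative_kernel(orders, scale)
  r1 <- unclass(convolve2(log(m), k))
  r2 <- unclass(convolve2(log(factor * m), k))
  max(abs(r1 - r2))
}

#' Synthetic albedo-times-illumination scene
#'
#' Composes a reflectance map `albedo` in (0, 1] with a smooth positive
#' illumination field into the observed luminance `f = albedo * illum`.
#'
#' @param albedo matrix in (0, 1].
#' @param illum positive matrix, same size.
#' @return Object of class `illumination_scene`: list with `albedo`,
#'   `illum`, `composed`.
#' @export
illumination_scene <- function(albedo, illum) {
  albedo <- unclass(as.matrix(albedo)); illum <- unclass(as.matrix(illum))
  if (!all(dim(albedo) == dim(illum)))
    stop("illumination_scene: albedo and illumination sizes differ")
  if (min(albedo) <= 0 || max(albedo) > 1)
    stop("illumination_scene: albedo must lie in (0, 1]")
  if (min(illum) <= 0)
    stop("illumination_scene: illumination must be strictly positive")
  structure(list(albedo = albedo, illum = illum,
                 composed = albedo * illum),
            class = "illumination_scene")
}

#' @export
print.illumination_scene <- function(x, ...) {
  cat(sprintf("<illumination_scene %d x %d, illum range [%g, %g]>\n",
              nrow(x$composed), ncol(x$composed), min(x$illum),
              max(x$illum)))
  invisible(x)
}

#' Decompose a scene response into image and albedo contributions
#'
#' Computes the derivative response of `log(f)` (the observed log
#' luminance) and of `log(albedo)` for a scene `f = albedo * illum`. When
#' the illumination field is constant over the kernel support the two
#' responses coincide; for slowly varying illumination the discrepancy is
#' bounded by the illumination log-gradient over the support.
#'
#' @param scene an `illumination_scene`.
#' @param orders derivative orders `(m1, m2)`, total >= 1, or the string
#'   `"laplacian"`.
#' @param scale kernel scale (variance).
#' @return list with `response_f`, `response_albedo` (matrices) and
#'   `rel_discrepancy` (relative L2 difference).
#' @export
scene_response_decomposition <- function(scene, orders = c(1, 0),
                                         scale = 4) {
  stopifnot(inherits(scene, "illumination_scene"))
  k <- if (identical(orders, "laplacian")) log_kernel(scale)
       else {
         if (sum(orders) < 1)
           stop("scene_response_decomposition: derivative order >= 1 required")
         gaussian_derivative_kernel(orders, scale)
       }
  rf <- unclass(convolve2(log(scene$composed), k))
  ra <- unclass(convolve2(log(scene$albedo), k))
  list(response_f = rf, response_albedo = ra,
       rel_discrepancy = sqrt(sum((rf - ra)^2) / max(sum(ra^2),
                                                     .Machine$double.eps)))
}
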