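#' Dense 2-D grayscale image
#'
#' Lightweight container for a single-channel image: a numeric matrix with
#' rows indexing the y (row) axis and columns indexing the x (column) axis.
#' The mathematical convention used throughout the package is `x = column`,
#' `y = row`, with the origin at the centre of the top-left pixel (0, 0).
#'
#' @param values numeric matrix of intensities (arbitrary linear units).
#' @param pixel_spacing physical length per pixel (> 0); defaults to 1.
#' @return An object of class `image2d`: the matrix with a `pixel_spacing`
#'   attribute.
#' @export
image2d <- function(values, pixel_spacing = 1) {
  values <- as.matrix(values)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("image2d: values must be finite numeric")
  if (nrow(values) < 3 || ncol(values) < 3)
    stop("image2d: image must be at least 3x3")
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1 ||
      pixel_spacing <= 0)
    stop("image2d: pixel_spacing must be a positive scalar")
  structure(values, pixel_spacing = pixel_spacing,
            class = c("image2d", "matrix", "array"))
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d %d x %d, pixel_spacing = %g, range [%g, %g]>\n",
              nrow(x), ncol(x), attr(x, "pixel_spacing"),
              min(x), max(x)))
  invisible(x)
}

as_image2d <- function(x, template = NULL) {
  ps <- if (!is.null(template)) attr(template, "pixel_spacing") %||% 1 else 1
  image2d(unclass(as.matrix(x)), pixel_spacing = ps)
}

#' Dense 2+1-D image sequence
#'
#' A 3-D numeric array indexed `(t, y, x)` (frame, row, column) with frame
#' and pixel spacings.
#'
#' @param frames 3-D numeric array, first index is the frame.
#' @param frame_spacing time per frame (> 0).
#' @param pixel_spacing length per pixel (> 0).
#' @return An object of class `image_sequence`.
#' @export
image_sequence <- function(frames, frame_spacing = 1, pixel_spacing = 1) {
  if (!is.array(frames) || length(dim(frames)) != 3)
    stop("image_sequence: frames must be a 3-D array (t, y, x)")
  if (any(!is.finite(frames))) stop("image_sequence: values must be finite")
  if (dim(frames)[1] < 3) stop("image_sequence: need at least 3 frames")
  if (frame_spacing <= 0 || pixel_spacing <= 0)
    stop("image_sequence: spacings must be positive")
  structure(frames, frame_spacing = frame_spacing,
            pixel_spacing = pixel_spacing,
            class = c("image_sequence", "array"))
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_sequence %d frames of %d x %d, frame_spacing = %g>\n",
              d[1], d[2], d[3], attr(x, "frame_spacing")))
  invisible(x)
}

#' Extract one frame of a sequence as an image2d
#' @param seq an `image_sequence`.
#' @param t frame index (1-based).
#' @return `image2d`.
#' @export
sequence_frame <- function(seq, t) {
  stopifnot(inherits(seq, "image_sequence"), t >= 1, t <= dim(seq)[1])
  image2d(unclass(seq)[t, , ], pixel_spacing = attr(seq, "pixel_spacing"))
}

#' Spatial covariance matrix of an affine Gaussian kernel
#'
#' A 2x2 symmetric positive-definite matrix Sigma, parameterizable either
#' directly or through its eigenvalues `(lambda1, lambda2)` (variances in
#' pixel^2, lambda1 >= lambda2 > 0) and the orientation `theta` of the
#' lambda1 eigenvector:
#' `Sigma = R(theta) diag(lambda1, lambda2) R(theta)^T`.
#'
#' @param sigma_matrix 2x2 symmetric positive-definite matrix, or NULL.
#' @param lambda1,lambda2 eigenvalues (pixel^2), used when `sigma_matrix` is
#'   NULL.
#' @param theta orientation of the major axis in radians, mapped to `[0, pi)`.
#' @return Object of class `spatial_covariance` with fields `sigma`,
#'   `lambda1`, `lambda2`, `theta`.
#' @export
spatial_covariance <- function(sigma_matrix = NULL, lambda1 = NULL,
                               lambda2 = NULL, theta = 0) {
  if (is.null(sigma_matrix)) {
    if (is.null(lambda1) || is.null(lambda2))
      stop("spatial_covariance: give sigma_matrix or (lambda1, lambda2)")
    if (lambda1 <= 0 || lambda2 <= 0)
      stop("spatial_covariance: eigenvalues must be strictly positive")
    if (lambda1 < lambda2) { tmp <- lambda1; lambda1 <- lambda2; lambda2 <- tmp
                             theta <- theta + pi / 2 }
    theta <- theta %% pi
    R <- rot2(theta)
    sigma_matrix <- R %*% diag(c(lambda1, lambda2)) %*% t(R)
  } else {
    sigma_matrix <- as.matrix(sigma_matrix)
    if (!all(dim(sigma_matrix) == c(2, 2)) ||
        abs(sigma_matrix[1, 2] - sigma_matrix[2, 1]) > 1e-12 * sum(abs(sigma_matrix)))
      stop("spatial_covariance: sigma_matrix must be 2x2 symmetric")
    sigma_matrix <- (sigma_matrix + t(sigma_matrix)) / 2
    e <- eigen(sigma_matrix, symmetric = TRUE)
    if (min(e$values) <= 0)
      stop("spatial_covariance: matrix must be positive definite")
    lambda1 <- e$values[1]; lambda2 <- e$values[2]
    v <- e$vectors[, 1]
    theta <- atan2(v[2], v[1]) %% pi
  }
  structure(list(sigma = sigma_matrix, lambda1 = lambda1, lambda2 = lambda2,
                 theta = theta),
            class = "spatial_covariance")
}

#' @export
print.spatial_covariance <- function(x, ...) {
  cat(sprintf("<spatial_covariance lambda1 = %g, lambda2 = %g, theta = %g rad>\n",
              x$lambda1, x$lambda2, x$theta))
  invisible(x)
}

# Coerce a scalar scale or matrix to spatial_covariance
as_spatial_covariance <- function(x) {
  if (inherits(x, "spatial_covariance")) return(x)
  if (is.matrix(x)) return(spatial_covariance(sigma_matrix = x))
  if (is.numeric(x) && length(x) == 1 && x > 0)
    return(spatial_covariance(sigma_matrix = diag(2) * x))
  stop("cannot interpret as a spatial covariance")
}

#' Sampled 2-D convolution kernel
#'
#' A kernel tap matrix with odd side lengths and its origin at the central
#' tap. Zero-order (smoothing) kernels have unit tap sum; derivative kernels
#' have zero tap sum.
#'
#' @param values numeric matrix of taps, odd side lengths.
#' @param spec optional list of the parameters that generated the kernel.
#' @return Object of class `kernel2d`.
#' @export
kernel2d <- function(values, spec = NULL) {
  values <- as.matrix(values)
  if (nrow(values) %% 2 == 0 || ncol(values) %% 2 == 0)
    stop("kernel2d: side lengths must be odd")
  structure(values,
            support_radius = c((nrow(values) - 1) / 2, (ncol(values) - 1) / 2),
            spec = spec,
            class = c("kernel2d", "matrix", "array"))
}

#' @export
print.kernel2d <- function(x, ...) {
  r <- attr(x, "support_radius")
  cat(sprintf("<kernel2d %d x %d (radius %d, %d), tap sum %.3g>\n",
              nrow(x), ncol(x), r[1], r[2], sum(x)))
  invisible(x)
}

# 2x2 rotation matrix
rot2 <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

# symmetric principal square root / inverse of a 2x2 (or general) SPD matrix
sqrtm_spd <- function(M, inverse = FALSE) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(e$values) <= 0) stop("matrix is not positive definite")
  p <- if (inverse) -0.5 else 0.5
  e$vectors %*% diag(e$values^p, length(e$values)) %*% t(e$vectors)
}

# normalize an SPD matrix to unit determinant
unit_det <- function(M) M / sqrt(det(M))

`%||%` <- function(a, b) if (is.null(a)) b else a
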