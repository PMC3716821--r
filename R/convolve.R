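# Convolution engine and pull-back warps.  2-D convolution is delegated to
# EBImage::filter2 (FFT) on an explicitly padded image so that the boundary
# semantics (mirror / replicate / constant) are owned here; filter2 itself
# only provides circular wrapping.

# reflect-101 index mapping into 1..n (mirror about the border pixel centres)
mirror_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- (i - 1L) %% p
  j <- ifelse(j >= n, p - j, j)
  j + 1L
}

replicate_index <- function(i, n) pmin(pmax(i, 1L), n)

pad_matrix <- function(m, ry, rx, boundary = "mirror", value = 0) {
  n_r <- nrow(m); n_c <- ncol(m)
  ri <- seq(1L - ry, n_r + ry)
  ci <- seq(1L - rx, n_c + rx)
  if (boundary == "mirror") {
    m[mirror_index(ri, n_r), mirror_index(ci, n_c), drop = FALSE]
  } else if (boundary == "replicate") {
    m[replicate_index(ri, n_r), replicate_index(ci, n_c), drop = FALSE]
  } else if (boundary == "constant") {
    out <- matrix(value, length(ri), length(ci))
    out[ry + seq_len(n_r), rx + seq_len(n_c)] <- m
    out
  } else stop("unknown boundary mode: ", boundary)
}

#' Convolve an image with a kernel
#'
#' Discrete 2-D convolution \eqn{(f * k)(x) = \sum_u f(x - u) k(u)} with
#' selectable boundary handling, returning an image of the same size.
#' Boundary modes: `"mirror"` (reflect-101, the default; preserves constants
#' and limits border artifacts), `"replicate"` (edge extension) and
#' `"constant"` (pad with `value`).
#'
#' @param image an `image2d` (or plain matrix).
#' @param kernel a `kernel2d` (or odd-sized matrix).
#' @param boundary one of `"mirror"`, `"replicate"`, `"constant"`.
#' @param value pad value for `boundary = "constant"`.
#' @return `image2d` of the same size as the input.
#' @export
convolve2 <- function(image, kernel, boundary = c("mirror", "replicate",
                                                  "constant"), value = 0) {
  boundary <- match.arg(boundary)
  m <- unclass(as.matrix(image))
  k <- unclass(as.matrix(kernel))
  if (nrow(k) %% 2 == 0 || ncol(k) %% 2 == 0)
    stop("convolve2: kernel side lengths must be odd")
  ry <- (nrow(k) - 1L) / 2L; rx <- (ncol(k) - 1L) / 2L
  # mirror/replicate padding extends the image by the kernel radius, so
  # kernels moderately larger than the image are well defined; beyond 3x
  # the padding only repeats reflected content and the sizes are declared
  # incompatible
  if (nrow(k) > 3L * nrow(m) || ncol(k) > 3L * ncol(m))
    stop("convolve2: kernel larger than the padded image")
  padded <- pad_matrix(m, ry, rx, boundary, value)
  out <- EBImage::filter2(padded, k, boundary = "circular")
  out <- out[ry + seq_len(nrow(m)), rx + seq_len(ncol(m)), drop = FALSE]
  as_image2d(out, template = if (inherits(image, "image2d")) image else NULL)
}

# 1-D convolution along the time axis of a sequence array (t, y, x).
# taps: numeric vector; offsets: integer tap offsets u (response uses
# frame t - u). Mirror boundary along time.
convolve_time <- function(frames, taps, offsets,
                          boundary = c("mirror", "replicate", "constant"),
                          value = 0) {
  boundary <- match.arg(boundary)
  d <- dim(frames); nt <- d[1]
  out <- array(0, d)
  for (j in seq_along(taps)) {
    if (taps[j] == 0) next
    src <- seq_len(nt) - offsets[j]
    src <- switch(boundary,
                  mirror = mirror_index(src, nt),
                  replicate = replicate_index(src, nt),
                  constant = src)
    if (boundary == "constant") {
      ok <- src >= 1 & src <= nt
      out[ok, , ] <- out[ok, , ] + taps[j] * frames[src[ok], , ]
      if (value != 0 && any(!ok))
        out[!ok, , ] <- out[!ok, , ] + taps[j] * value
    } else {
      out <- out + taps[j] * frames[src, , , drop = FALSE]
    }
  }
  out
}

# Bilinear sampling of matrix m at (non-integer) 0-based math coordinates
# (x = col - 1, y = row - 1), mirror boundary. x, y equal-length vectors.
bilinear_sample <- function(m, x, y) {
  n_r <- nrow(m); n_c <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  c0 <- mirror_index(x0 + 1L, n_c); c1 <- mirror_index(x0 + 2L, n_c)
  r0 <- mirror_index(y0 + 1L, n_r); r1 <- mirror_index(y0 + 2L, n_r)
  i00 <- cbind(r0, c0); i01 <- cbind(r0, c1)
  i10 <- cbind(r1, c0); i11 <- cbind(r1, c1)
  (1 - fy) * ((1 - fx) * m[i00] + fx * m[i01]) +
    fy * ((1 - fx) * m[i10] + fx * m[i11])
}

# Keys cubic-convolution weights (a = -1/2, Catmull-Rom) for fraction t
cubic_weights <- function(t) {
  a <- -0.5
  list(a * (t^3 - 2 * t^2 + t),
       (a + 2) * t^3 - (a + 3) * t^2 + 1,
       -(a + 2) * t^3 + (2 * a + 3) * t^2 - a * t,
       -a * t^3 + a * t^2)
}

# Bicubic sampling, same conventions as bilinear_sample; the default
# interpolator for all image warps
bicubic_sample <- function(m, x, y) {
  n_r <- nrow(m); n_c <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  wx <- cubic_weights(x - x0)
  wy <- cubic_weights(y - y0)
  out <- numeric(length(x))
  for (j in 1:4) {
    rr <- mirror_index(y0 + j - 1L, n_r)
    acc <- numeric(length(x))
    for (i in 1:4) {
      cc <- mirror_index(x0 + i - 1L, n_c)
      acc <- acc + wx[[i]] * m[cbind(rr, cc)]
    }
    out <- out + wy[[j]] * acc
  }
  out
}

#' Affine pull-back warp of an image
#'
#' Resamples `image` under the affine map so that
#' `output(x) = input(A (x - center_out) + center_in + offset)` with bicubic
#' (Catmull-Rom) interpolation and mirror boundary. With the default centres (image
#' centre), `warp_affine(f, A)` realizes the pattern transformation
#' `f'(x) = f(A x)` about the centre.
#'
#' @param image `image2d` or matrix.
#' @param A 2x2 matrix acting on math coordinates `(x, y)`.
#' @param offset length-2 translation added in input coordinates.
#' @param center_out,center_in map centres in 0-based `(x, y)` coordinates;
#'   default the image centres.
#' @param out_dim output `c(rows, cols)`; defaults to the input size.
#' @return warped `image2d`.
#' @export
warp_affine <- function(image, A, offset = c(0, 0), center_out = NULL,
                        center_in = NULL, out_dim = NULL) {
  m <- unclass(as.matrix(image))
  if (is.null(out_dim)) out_dim <- dim(m)
  if (is.null(center_in)) center_in <- c((ncol(m) - 1) / 2, (nrow(m) - 1) / 2)
  if (is.null(center_out)) center_out <- c((out_dim[2] - 1) / 2,
                                           (out_dim[1] - 1) / 2)
  xs <- seq_len(out_dim[2]) - 1 - center_out[1]
  ys <- seq_len(out_dim[1]) - 1 - center_out[2]
  gx <- matrix(rep(xs, each = out_dim[1]), out_dim[1], out_dim[2])
  gy <- matrix(rep(ys, times = out_dim[2]), out_dim[1], out_dim[2])
  sx <- A[1, 1] * gx + A[1, 2] * gy + center_in[1] + offset[1]
  sy <- A[2, 1] * gx + A[2, 2] * gy + center_in[2] + offset[2]
  out <- matrix(bicubic_sample(m, as.numeric(sx), as.numeric(sy)),
                out_dim[1], out_dim[2])
  as_image2d(out, template = if (inherits(image, "image2d")) image else NULL)
}

# Extract a patch: patch(u) = image(point + B u), u on a (2r+1)^2 grid.
# point is 0-based (x, y); B maps patch coordinates to image offsets.
sample_patch <- function(image, point, B, radius) {
  m <- unclass(as.matrix(image))
  u <- seq(-radius, radius)
  n <- length(u)
  gx <- matrix(rep(u, each = n), n, n)
  gy <- matrix(rep(u, times = n), n, n)
  sx <- B[1, 1] * gx + B[1, 2] * gy + point[1]
  sy <- B[2, 1] * gx + B[2, 2] * gy + point[2]
  matrix(bicubic_sample(m, as.numeric(sx), as.numeric(sy)), n, n)
}
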