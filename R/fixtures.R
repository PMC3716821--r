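# Seeded synthetic fixtures: every acceptance-level property in the package
# is exercised on images and sequences generated here, with ground truth
# (blob variance t0, warp matrix A, velocity v, albedo/illumination fields)
# carried as attributes.  All randomness goes through the `seed` argument;
# the same spec and seed reproduce bitwise-identical output.

#' Render an analytic Gaussian blob image
#'
#' `f(x, y) = g(x - cx, y - cy; t0)`, the closed-form Gaussian of variance
#' `t0`, evaluated exactly at pixel centres (no sampling noise). The blob
#' centre may be sub-pixel.
#'
#' @param t0 blob variance (pixel^2).
#' @param size image side length (pixels) or `c(rows, cols)`.
#' @param center blob centre `(x, y)` in 0-based coordinates; defaults to
#'   the image centre.
#' @param amplitude peak factor multiplying the unit-mass Gaussian.
#' @return `image2d` with attribute `t0`.
#' @export
fixture_blob <- function(t0, size = 128, center = NULL, amplitude = 1) {
  if (t0 <= 0) stop("fixture_blob: t0 must be positive")
  sz <- if (length(size) == 1) c(size, size) else size
  if (is.null(center)) center <- c((sz[2] - 1) / 2, (sz[1] - 1) / 2)
  xs <- seq_len(sz[2]) - 1 - center[1]
  ys <- seq_len(sz[1]) - 1 - center[2]
  vals <- amplitude * exp(-outer(ys^2, xs^2, `+`) / (2 * t0)) /
    (2 * pi * t0)
  out <- image2d(vals)
  attr(out, "t0") <- t0
  attr(out, "center") <- center
  out
}

#' Render a sinusoidal grating
#'
#' `f(x, y) = offset + amplitude * sin(2 pi (x cos a + y sin a)/wavelength
#' + phase)`.
#'
#' @param wavelength spatial wavelength (pixels).
#' @param size side length or `c(rows, cols)`.
#' @param angle normal direction of the grating (radians; 0 varies along
#'   x).
#' @param phase phase offset (radians).
#' @param amplitude,offset intensity parameters.
#' @return `image2d` with attribute `wavelength`.
#' @export
fixture_grating <- function(wavelength, size = 128, angle = 0, phase = 0,
                            amplitude = 1, offset = 0) {
  if (wavelength <= 0) stop("fixture_grating: wavelength must be positive")
  sz <- if (length(size) == 1) c(size, size) else size
  xs <- seq_len(sz[2]) - 1
  ys <- seq_len(sz[1]) - 1
  u <- outer(ys * sin(angle), xs * cos(angle), `+`)
  out <- image2d(offset + amplitude * sin(2 * pi * u / wavelength + phase))
  attr(out, "wavelength") <- wavelength
  out
}

#' Seeded smooth random texture
#'
#' White Gaussian noise smoothed at the correlation scale and standardized
#' to the requested mean and standard deviation; the standard smooth test
#' image for property checks.
#'
#' @param size side length or `c(rows, cols)`.
#' @param correlation_scale smoothing variance (pixel^2).
#' @param seed integer seed.
#' @param mean,sd target intensity mean and spread.
#' @return `image2d`.
#' @export
fixture_texture <- function(size = 128, correlation_scale = 4, seed = 1,
                            mean = 0.5, sd = 0.15) {
  sz <- if (length(size) == 1) c(size, size) else size
  set.seed(seed)
  noise <- matrix(stats::rnorm(prod(sz)), sz[1], sz[2])
  sm <- unclass(convolve2(noise, gaussian_kernel(correlation_scale)))
  sm <- (sm - base::mean(sm)) / stats::sd(sm)
  image2d(mean + sd * sm)
}

#' Weakly isotropic broadband rosette pattern
#'
#' A deterministic sum of sinusoidal plane waves at evenly spaced
#' orientations and several wavelengths with seeded random phases. Its
#' orientation-averaged structure tensor is proportional to the identity
#' (the "weakly isotropic" pattern assumption of affine shape adaptation),
#' and the multiple bands keep the pattern measurable across a wide range
#' of derivative scales and affine warps.
#'
#' @param size side length or `c(rows, cols)`.
#' @param wavelengths spatial wavelengths of the bands (pixels).
#' @param n_orient plane-wave orientations per band, evenly spaced over
#'   `[0, pi)`.
#' @param seed seed for the phases.
#' @return `image2d` with unit standard deviation.
#' @export
fixture_rosette <- function(size = 160, wavelengths = c(5, 10, 20),
                            n_orient = 12, seed = 1) {
  sz <- if (length(size) == 1) c(size, size) else size
  set.seed(seed)
  m <- matrix(0, sz[1], sz[2])
  xs <- seq_len(sz[2]) - 1
  ys <- seq_len(sz[1]) - 1
  for (wl in wavelengths) for (k in seq_len(n_orient)) {
    th <- (k - 1) * pi / n_orient
    ph <- stats::runif(1, 0, 2 * pi)
    m <- m + sin(2 * pi * outer(ys * sin(th), xs * cos(th), `+`) / wl + ph)
  }
  image2d(m / stats::sd(m))
}

#' Weakly isotropic ring-wave (Bessel) pattern
#'
#' `J0(2 pi |x - c| / wavelength)`, a single-frequency wave over all
#' orientations. Its gradient structure tensor at the centre is exactly
#' isotropic for any rotationally symmetric window, which makes it the
#' reference "weakly isotropic pattern" for affine shape adaptation. An
#' affine warp can be rendered analytically through the quadratic form
#' `|A x|`, with the warp matrix carried as an attribute.
#'
#' @param size side length or `c(rows, cols)`.
#' @param wavelength radial wavelength (pixels).
#' @param warp optional 2x2 matrix: renders `f(A x)` exactly.
#' @return `image2d` with attributes `wavelength` and (if given) `warp_A`.
#' @export
fixture_ring_wave <- function(size = 161, wavelength = 12, warp = NULL) {
  if (wavelength <= 0) stop("fixture_ring_wave: wavelength must be positive")
  sz <- if (length(size) == 1) c(size, size) else size
  A <- if (is.null(warp)) diag(2) else warp
  Q <- t(A) %*% A
  xs <- seq_len(sz[2]) - 1 - (sz[2] - 1) / 2
  ys <- seq_len(sz[1]) - 1 - (sz[1] - 1) / 2
  q <- outer(ys^2 * Q[2, 2], xs^2 * Q[1, 1], `+`) + 2 * Q[1, 2] * outer(ys, xs)
  out <- image2d(besselJ(2 * pi * sqrt(q) / wavelength, 0))
  attr(out, "wavelength") <- wavelength
  if (!is.null(warp)) attr(out, "warp_A") <- warp
  out
}

#' Affine-warped copy of an image
#'
#' Realizes `f'(x) = f(A x)` about the image centre via pull-back
#' resampling; the warp matrix is carried as an attribute for oracles.
#'
#' @param image `image2d`.
#' @param A 2x2 warp matrix.
#' @return warped `image2d` with attribute `warp_A`.
#' @export
fixture_affine_warp <- function(image, A) {
  out <- warp_affine(image, A)
  attr(out, "warp_A") <- A
  out
}

#' Translating image sequence
#'
#' Frame `k` (1-based) shows the pattern displaced by `v * (k - 1)` pixels.
#' Blob patterns are re-rendered analytically at each sub-pixel position
#' (no interpolation error); arbitrary images are displaced by bicubic
#' warping of the first frame.
#'
#' @param v velocity `(vx, vy)` in pixels/frame.
#' @param n_frames number of frames (>= 3).
#' @param image pattern for the first frame, or NULL to use an analytic
#'   blob.
#' @param t0 blob variance when `image` is NULL.
#' @param size spatial size when `image` is NULL.
#' @return `image_sequence` with attribute `velocity`.
#' @export
fixture_translating_sequence <- function(v, n_frames = 16, image = NULL,
                                         t0 = 8, size = 64) {
  if (n_frames < 3) stop("fixture_translating_sequence: need >= 3 frames")
  if (is.null(image)) {
    sz <- if (length(size) == 1) c(size, size) else size
    c0 <- c((sz[2] - 1) / 2, (sz[1] - 1) / 2)
    frames <- array(0, c(n_frames, sz[1], sz[2]))
    for (k in seq_len(n_frames))
      frames[k, , ] <- unclass(fixture_blob(t0, sz,
                                            center = c0 + v * (k - 1)))
  } else {
    m <- unclass(as.matrix(image))
    frames <- array(0, c(n_frames, nrow(m), ncol(m)))
    for (k in seq_len(n_frames))
      frames[k, , ] <- unclass(warp_affine(m, diag(2),
                                           offset = -v * (k - 1),
                                           center_out = c(0, 0),
                                           center_in = c(0, 0)))
  }
  out <- image_sequence(frames)
  attr(out, "velocity") <- v
  out
}

#' Synthetic illumination scene fixture
#'
#' A seeded texture albedo (rescaled into (0, 1]) under one of three
#' illumination layouts: `"constant"`, a linear `"ramp"` of given log
#' gradient, or a sun/shade `"step"` with the given intensity ratio between
#' the left and right halves (the step softened over a few pixels).
#'
#' @param size side length.
#' @param layout `"constant"`, `"ramp"` or `"step"`.
#' @param seed seed for the albedo texture.
#' @param ramp_gradient illumination relative gradient per pixel (ramp).
#' @param step_ratio bright/dark illumination ratio (step).
#' @param step_softness half-width of the softened step edge in pixels.
#' @return `illumination_scene` with attribute `layout`.
#' @export
fixture_illumination_scene <- function(size = 128, layout = "step",
                                       seed = 1, ramp_gradient = 1e-3,
                                       step_ratio = 4, step_softness = 2) {
  # albedo contrast matches typical natural surface textures
  # (log-reflectance spread around 0.3)
  albedo <- unclass(fixture_texture(size, correlation_scale = 1.5,
                                    seed = seed, mean = 0.5, sd = 0.15))
  albedo <- pmin(pmax(albedo, 0.05), 1)
  sz <- dim(albedo)
  xs <- seq_len(sz[2]) - 1
  illum_row <- switch(layout,
    constant = rep(1, sz[2]),
    ramp = 1 + ramp_gradient * (xs - base::mean(xs)),
    step = {
      edge <- (sz[2] - 1) / 2
      w <- stats::plogis((xs - edge) / step_softness)
      step_ratio * (1 - w) + 1 * w
    },
    stop("fixture_illumination_scene: unknown layout ", layout))
  if (min(illum_row) <= 0)
    stop("fixture_illumination_scene: illumination must stay positive")
  illum <- matrix(rep(illum_row, each = sz[1]), sz[1], sz[2])
  out <- illumination_scene(albedo, illum)
  attr(out, "layout") <- layout
  out
}

#' Generate a fixture from a declarative spec
#'
#' Single entry point over the fixture generators, keyed by `kind`:
#' `blob`, `grating`, `smooth_noise_texture`, `rosette`, `ring_wave`,
#' `affine_warp`, `translate_seq`, `illum_scene`. Identical spec and seed
#' give bitwise identical output.
#'
#' @param kind fixture kind (see above).
#' @param ... parameters forwarded to the corresponding `fixture_*`
#'   generator.
#' @return `image2d`, `image_sequence` or `illumination_scene`.
#' @export
make_fixture <- function(kind, ...) {
  switch(kind,
         blob = fixture_blob(...),
         grating = fixture_grating(...),
         smooth_noise_texture = fixture_texture(...),
         rosette = fixture_rosette(...),
         ring_wave = fixture_ring_wave(...),
         affine_warp = fixture_affine_warp(...),
         translate_seq = fixture_translating_sequence(...),
         illum_scene = fixture_illumination_scene(...),
         stop("make_fixture: unknown kind ", kind))
}
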