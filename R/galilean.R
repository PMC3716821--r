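# Spatio-temporal second-moment measurement and Galilean diagonalization.
# For a pattern translating at constant velocity v the advection identity
# Lt = -v . grad(L) holds identically, so the velocity that zeroes the
# mixed space-time entries of the spatio-temporal second-moment matrix is
# the unique solution of the structure-tensor normal equations
#     [mu_xx mu_xy; mu_xy mu_yy] v = -[mu_xt; mu_yt],
# and that velocity is additive under superimposed Galilean transforms.

#' Spatio-temporal second-moment matrix at a point
#'
#' Weighted averages of the six first-derivative products over `(x, y, t)`:
#' derivatives from a spatio-temporal Gaussian at the derivative scales
#' (optionally the time-causal cascade smoother), integrated under a
#' space-time Gaussian window with covariances `r^2` times the derivative
#' covariances, evaluated at `point`.
#'
#' @param seq an `image_sequence`.
#' @param point `(x, y, t)`: 0-based spatial math coordinates and 1-based
#'   frame index.
#' @param spatial_scale derivative scale in space (variance, pixel^2).
#' @param temporal_scale derivative scale in time (variance, frame^2), or
#'   time constants `mu` when `causal = TRUE`.
#' @param r integration-to-derivative scale ratio.
#' @param causal use the exponential-cascade temporal smoother for the
#'   derivative stage.
#' @return Object of class `second_moment3d`: list with `mu` (3x3, order
#'   x, y, t) plus the scales used.
#' @export
st_second_moment <- function(seq, point, spatial_scale = 4,
                             temporal_scale = 2, r = 2, causal = FALSE) {
  stopifnot(inherits(seq, "image_sequence"))
  d <- dim(seq); nt <- d[1]
  t0 <- point[3]
  if (t0 < 2 || t0 > nt - 1)
    stop("st_second_moment: frame index must be interior")
  raw <- unclass(seq)
  # spatial derivative responses per frame
  kx <- gaussian_derivative_kernel(c(1, 0), spatial_scale)
  ky <- gaussian_derivative_kernel(c(0, 1), spatial_scale)
  ks <- gaussian_kernel(spatial_scale)
  conv_frames <- function(frames, k) {
    out <- array(0, dim(frames))
    for (t in seq_len(dim(frames)[1]))
      out[t, , ] <- unclass(convolve2(frames[t, , ], k))
    out
  }
  lx <- conv_frames(raw, kx)
  ly <- conv_frames(raw, ky)
  lsm <- conv_frames(raw, ks)
  if (causal) {
    mu_c <- temporal_scale
    h0 <- exp_cascade_kernel(mu_c, dt = 1, tail_mass = 1e-6)
    h1 <- causal_temporal_derivative(h0, 1)
    boundary_t <- "replicate"
    tsmooth <- function(a, h) convolve_time(a, h$taps,
                                            seq_along(h$taps) - 1L,
                                            boundary_t)
    lx <- tsmooth(lx, h0); ly <- tsmooth(ly, h0)
    lt <- tsmooth(lsm, h1)
    int_var_t <- r^2 * sum(mu_c^2)
  } else {
    h0 <- temporal_gaussian_kernel(temporal_scale)
    h1 <- temporal_gaussian_kernel(temporal_scale, order = 1)
    off0 <- as.integer(round(h0$times)); off1 <- as.integer(round(h1$times))
    lx <- convolve_time(lx, h0$taps, off0, "mirror")
    ly <- convolve_time(ly, h0$taps, off0, "mirror")
    lt <- convolve_time(lsm, h1$taps, off1, "mirror")
    int_var_t <- r^2 * temporal_scale
  }
  # integration: Gaussian window over space-time
  wsp <- gaussian_kernel(r^2 * spatial_scale)
  wt <- temporal_gaussian_kernel(int_var_t)
  offw <- as.integer(round(wt$times))
  prods <- list(xx = lx * lx, xy = lx * ly, yy = ly * ly,
                xt = lx * lt, yt = ly * lt, tt = lt * lt)
  avg <- lapply(prods, function(p) {
    p <- convolve_time(p, wt$taps, offw, "mirror")
    bilinear_sample(unclass(convolve2(p[t0, , ], wsp)),
                    point[1], point[2])
  })
  mu <- matrix(c(avg$xx, avg$xy, avg$xt,
                 avg$xy, avg$yy, avg$yt,
                 avg$xt, avg$yt, avg$tt), 3, 3)
  structure(list(mu = mu, spatial_scale = spatial_scale,
                 temporal_scale = temporal_scale, r = r, causal = causal,
                 point = point),
            class = "second_moment3d")
}

#' @export
print.second_moment3d <- function(x, ...) {
  cat("<second_moment3d (x, y, t)>\n"); print(x$mu); invisible(x)
}

#' Estimate image velocity by Galilean diagonalization
#'
#' Solves the structure-tensor normal equations for the velocity whose
#' Galilean transform zeroes the mixed space-time entries of the
#' spatio-temporal second-moment matrix. Degenerate spatial structure (the
#' aperture problem) is reported as an error naming the deficient
#' direction.
#'
#' @param mu a `second_moment3d` (or plain 3x3 matrix, order x, y, t).
#' @param cond_cap condition-number cap on the spatial 2x2 block beyond
#'   which the aperture problem is declared.
#' @return Object of class `velocity_estimate`: list with `v = (vx, vy)`,
#'   `diag_residual` (largest mixed entry after diagonalization, relative
#'   to the spatial block norm) and `condition`.
#' @export
estimate_velocity <- function(mu, cond_cap = 1e4) {
  M <- if (inherits(mu, "second_moment3d")) mu$mu else as.matrix(mu)
  S <- M[1:2, 1:2]; b <- M[1:2, 3]
  if (max(abs(M)) == 0) {
    # completely structureless input: treat as static
    return(structure(list(v = c(0, 0), diag_residual = 0,
                          condition = 1), class = "velocity_estimate"))
  }
  ev <- eigen(S, symmetric = TRUE)
  cond <- ev$values[1] / max(ev$values[2], .Machine$double.eps)
  if (!is.finite(cond) || cond > cond_cap) {
    dir_ <- ev$vectors[, 2]
    stop(sprintf(paste0("estimate_velocity: aperture problem - spatial ",
                        "block is rank deficient along direction ",
                        "(%.3f, %.3f) (condition %.3g)"),
                 dir_[1], dir_[2], cond))
  }
  v <- as.numeric(solve(S, -b))
  Md <- galilean_transform_moment(M, v)
  res <- max(abs(Md[1, 3]), abs(Md[2, 3])) / max(abs(S))
  structure(list(v = v, diag_residual = res, condition = cond),
            class = "velocity_estimate")
}

#' @export
print.velocity_estimate <- function(x, ...) {
  cat(sprintf("<velocity_estimate v = (%.4f, %.4f), residual %.3g>\n",
              x$v[1], x$v[2], x$diag_residual))
  invisible(x)
}

# G' mu G with G the Galilean derivative transform for stabilizing
# velocity v: (Lx, Ly, Lt) -> (Lx, Ly, Lt + vx Lx + vy Ly)
galilean_transform_moment <- function(M, v) {
  G <- diag(3)
  G[3, 1] <- v[1]; G[3, 2] <- v[2]
  G %*% M %*% t(G)
}

#' Apply a Galilean transformation to a second-moment matrix
#'
#' Transforms `mu` as measured in the frame co-moving at velocity `v`; with
#' `v` from [estimate_velocity()] the mixed space-time entries vanish
#' (Galilean block diagonalization). `v = 0` returns the input unchanged.
#'
#' @param mu `second_moment3d` or 3x3 matrix.
#' @param v velocity `(vx, vy)`.
#' @return 3x3 matrix.
#' @export
galilean_diagonalize <- function(mu, v) {
  M <- if (inherits(mu, "second_moment3d")) mu$mu else as.matrix(mu)
  galilean_transform_moment(M, as.numeric(v))
}

#' Stabilize a sequence for a known velocity
#'
#' Resamples every frame by the Galilean shear `x -> x + v (t - t_ref)`
#' (bicubic, mirror boundary), so a pattern translating at `v` becomes
#' static.
#'
#' @param seq an `image_sequence`.
#' @param v velocity `(vx, vy)` in pixels/frame.
#' @param t_ref reference frame index (1-based) that is left unchanged.
#' @return stabilized `image_sequence`.
#' @export
velocity_stabilize <- function(seq, v, t_ref = 1) {
  stopifnot(inherits(seq, "image_sequence"))
  d <- dim(seq)
  if (max(abs(v[1]) * (d[1] - 1), 0) > d[3] ||
      max(abs(v[2]) * (d[1] - 1), 0) > d[2])
    stop("velocity_stabilize: warp exceeds image bounds over the sequence")
  raw <- unclass(seq)
  out <- array(0, d)
  for (t in seq_len(d[1])) {
    dtf <- t - t_ref
    if (v[1] == 0 && v[2] == 0 || dtf == 0) { out[t, , ] <- raw[t, , ]; next }
    out[t, , ] <- unclass(warp_affine(raw[t, , ], diag(2),
                                      offset = c(v[1] * dtf, v[2] * dtf),
                                      center_out = c(0, 0),
                                      center_in = c(0, 0)))
  }
  image_sequence(out, frame_spacing = attr(seq, "frame_spacing"),
                 pixel_spacing = attr(seq, "pixel_spacing"))
}
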