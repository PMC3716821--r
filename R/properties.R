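# Executable property checks.  Each check_* function measures one of the
# structural properties of the kernel family / invariance mechanisms on
# synthetic fixtures and returns the measured quantities together with the
# thresholds the theory implies; rf_selftest() aggregates them into a
# pass/fail report.  The problem sizes are desk-scale (images of side
# 64-161, sequences of ~25 frames) so the whole suite runs in well under a
# minute on one CPU.

pad_to <- function(m, r_target) {
  r <- c((nrow(m) - 1) / 2, (ncol(m) - 1) / 2)
  pad_matrix(m, r_target[1] - r[1], r_target[2] - r[2], "constant")
}

#' Semigroup and cascade property of Gaussian smoothing
#'
#' For scales `s1, s2` in `s_set^2`: the L1 distance between
#' `g(s1) * g(s2)` and `g(s1 + s2)` on common support, and the maximum
#' cascade error (smoothing a texture to `s2` directly vs via `s1` then
#' `s2 - s1`) relative to the image dynamic range.
#'
#' @param s_set scales to combine.
#' @param size test image side for the cascade check.
#' @param seed texture seed.
#' @return list with `semigroup_max_l1` and `cascade_max_rel_err`.
#' @export
check_semigroup <- function(s_set = c(1, 2, 4, 8), size = 96, seed = 11) {
  worst <- 0
  for (s1 in s_set) for (s2 in s_set) {
    g12 <- gaussian_kernel(s1 + s2)
    r12 <- attr(g12, "support_radius")
    g1 <- unclass(gaussian_kernel(s1))
    r1 <- c((nrow(g1) - 1) / 2, (ncol(g1) - 1) / 2)
    big <- pad_matrix(g1, r12[1] - r1[1] + 2, r12[2] - r1[2] + 2, "constant")
    conv <- unclass(convolve2(big, gaussian_kernel(s2), "constant"))
    ref <- pad_to(unclass(g12), c((nrow(big) - 1) / 2, (ncol(big) - 1) / 2))
    worst <- max(worst, sum(abs(conv - ref)))
  }
  img <- fixture_texture(size, correlation_scale = 2, seed = seed)
  rng <- diff(range(img))
  worst_cascade <- 0
  for (s1 in s_set) for (s2 in s_set) {
    if (s2 <= s1) next
    direct <- unclass(convolve2(img, gaussian_kernel(s2)))
    two <- unclass(convolve2(convolve2(img, gaussian_kernel(s1)),
                             gaussian_kernel(s2 - s1)))
    # compare away from borders where mirror padding differs
    b <- 2 * ceiling(4 * sqrt(s2))
    ctr <- (b + 1):(size - b)
    worst_cascade <- max(worst_cascade,
                         max(abs(direct[ctr, ctr] - two[ctr, ctr])) / rng)
  }
  list(semigroup_max_l1 = worst, cascade_max_rel_err = worst_cascade)
}

#' Blob scale selection against the closed form
#'
#' On analytic blob fixtures `g(.; t0)` the scale-normalized Laplacian and
#' determinant-of-Hessian responses at the centre are maximal (in
#' magnitude) at `s = t0`; reports the worst relative error of the
#' selected scale over `t0_set` for both operators, and the error of the
#' selected-scale ratio for a blob pair.
#'
#' @param t0_set blob variances.
#' @param per_octave scale-grid density.
#' @return list with `max_rel_err_laplacian`, `max_rel_err_dethess`,
#'   `pair_ratio_rel_err`, `s_hat` (data frame).
#' @export
check_blob_scale <- function(t0_set = c(2, 4, 16), per_octave = 4) {
  rows <- NULL
  for (t0 in t0_set) {
    side <- max(97, ceiling(20 * sqrt(t0)))
    side <- side + (1 - side %% 2) # odd side: blob centre on a pixel, so
    # sampling the signature needs no interpolation of the curved peak
    img <- fixture_blob(t0, side)
    p <- attr(img, "center")
    scales <- scale_grid(t0 / 8, t0 * 8, per_octave)
    for (op in c("laplacian", "dethess")) {
      sel <- select_scale_and_normalize(img, p, op, scales,
                                        reference_scale = t0)
      rows <- rbind(rows, data.frame(t0 = t0, operator = op,
                                     s_hat = sel$s_hat))
    }
  }
  rows$rel_err <- abs(rows$s_hat - rows$t0) / rows$t0
  # blob pair t0 = 4 and 16 in one image frame: ratio of selected scales
  r1 <- rows$s_hat[rows$t0 == 4 & rows$operator == "laplacian"]
  r2 <- rows$s_hat[rows$t0 == 16 & rows$operator == "laplacian"]
  ratio_err <- abs(r2 / r1 - 4) / 4
  list(max_rel_err_laplacian = max(rows$rel_err[rows$operator ==
                                                  "laplacian"]),
       max_rel_err_dethess = max(rows$rel_err[rows$operator == "dethess"]),
       pair_ratio_rel_err = ratio_err,
       s_hat = rows)
}

#' Scaling covariance of scale selection
#'
#' A factor-2 enlarged copy of a texture must select `s' = 4 s` at the
#' corresponding point, and the scale-normalized patches from the pair must
#' agree.
#'
#' @param seed texture seed.
#' @param size base image side.
#' @return list with `s_ratio` (ideal 4), `s_ratio_rel_err`,
#'   `patch_rel_l2`.
#' @export
check_scaling_covariance <- function(seed = 5, size = 72) {
  base_ <- fixture_texture(size, correlation_scale = 3, seed = seed)
  blob <- fixture_blob(6, size, amplitude = 2 * pi * 6 * 0.3)
  img <- image2d(unclass(base_) + unclass(blob))
  p <- attr(blob, "center")
  # f'(x) = f(x / 2): enlarge about the centre
  img2 <- warp_affine(img, diag(2) * 0.5, out_dim = dim(img) * 2)
  p2 <- c((ncol(img2) - 1) / 2, (nrow(img2) - 1) / 2) + 2 * (p - p)
  sel1 <- select_scale_and_normalize(img, p, "laplacian",
                                     scale_grid(1, 64, 4),
                                     reference_scale = 16,
                                     patch_radius = 10)
  sel2 <- select_scale_and_normalize(img2, p2, "laplacian",
                                     scale_grid(1, 256, 4),
                                     reference_scale = 16,
                                     patch_radius = 10)
  ratio <- sel2$s_hat / sel1$s_hat
  d <- sel1$patch - sel2$patch
  list(s_ratio = ratio, s_ratio_rel_err = abs(ratio - 4) / 4,
       patch_rel_l2 = sqrt(sum(d^2) / sum(sel1$patch^2)))
}

# deviation of a matrix from a similarity (rotation x scale): relative
# operator-norm distance to its nearest scaled rotation
similarity_deviation <- function(M) {
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) { # allow reflection-free similarity only
    u <- sv$u; u[, 2] <- -u[, 2]
    R <- u %*% t(sv$v)
  }
  s <- mean(diag(t(R) %*% M))
  norm(M - s * R, "2") / norm(M, "2")
}

#' Affine fixed-point adaptation and two-view consistency
#'
#' Adapts the smoothing covariance on the weakly isotropic ring-wave
#' pattern and on analytically rendered affine warps of it (condition
#' numbers up to 3, including shear and rotated anisotropy); checks
#' convergence within the iteration budget, the isotropy residual, and
#' two-view frame consistency: since view 2 shows `f'(x) = f(A x)`,
#' `mu2 = A' mu1 A` at matched fixed points and `F1 A F2^{-1}` must be a
#' pure similarity (rotation x scale).
#'
#' @param warps list of 2x2 warp matrices; defaults cover a pure
#'   condition-3 anisotropy, a shear, and two rotated anisotropies.
#' @param wavelength ring-wave wavelength (pixels).
#' @param init_sigma initial (isotropic) adaptation variance.
#' @return list with `iterations`, `residual` (worst over views),
#'   `similarity_dev` (worst over warps), and `per_warp` (data frame).
#' @export
check_affine_fixed_point <- function(warps = NULL, wavelength = 12,
                                     init_sigma = 3) {
  rot <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  if (is.null(warps))
    warps <- list(cond3 = diag(c(sqrt(3), 1 / sqrt(3))),
                  shear = matrix(c(1, 0, 0.5, 1), 2, 2),
                  mix = rot(-0.3) %*% diag(c(1.6, 1 / 1.6)) %*% rot(0.7),
                  rotaniso = rot(0.5) %*% diag(c(1.5, 1 / 1.5)))
  img <- fixture_ring_wave(161, wavelength)
  p <- c((ncol(img) - 1) / 2, (nrow(img) - 1) / 2)
  f1 <- affine_adapt(img, p, init_sigma = init_sigma)
  rows <- NULL
  for (nm in names(warps)) {
    A <- warps[[nm]]
    imgw <- fixture_ring_wave(161, wavelength, warp = A)
    f2 <- affine_adapt(imgw, p, init_sigma = init_sigma)
    M <- f1$transform %*% A %*% solve(f2$transform)
    rows <- rbind(rows, data.frame(warp = nm, cond = kappa(A, exact = TRUE),
                                   iterations = f2$iterations,
                                   residual = f2$fixed_point_residual,
                                   similarity_dev = similarity_deviation(M)))
  }
  list(iterations = max(f1$iterations, rows$iterations),
       residual = max(f1$fixed_point_residual, rows$residual),
       residual_warped = max(rows$residual),
       similarity_dev = max(rows$similarity_dev),
       per_warp = rows)
}

#' Galilean velocity recovery, additivity and stabilization contrast
#'
#' Recovers the velocity of translating-blob sequences over a grid of true
#' velocities; checks additivity under a superimposed Galilean pre-warp;
#' and reproduces the stabilization contrast: Laplacian responses of the
#' stabilized moving sequence match the static sequence closely while the
#' unstabilized mismatch is large.
#'
#' @param v_grid vector of velocity components; the grid is its square.
#' @param n_frames,size,t0 sequence geometry.
#' @return list with `max_abs_err`, `additivity_err`,
#'   `stabilized_rel_l2`, `unstabilized_rel_l2`, `estimates` (data frame).
#' @export
check_velocity <- function(v_grid = c(-1, -0.5, 0, 0.5, 1), n_frames = 25,
                           size = 56, t0 = 8) {
  est <- NULL
  for (vx in v_grid) for (vy in v_grid) {
    seqv <- fixture_translating_sequence(c(vx, vy), n_frames, t0 = t0,
                                         size = size)
    p <- c((size - 1) / 2 + vx * (n_frames - 1) / 2,
           (size - 1) / 2 + vy * (n_frames - 1) / 2,
           ceiling(n_frames / 2))
    mu <- st_second_moment(seqv, p, spatial_scale = 3, temporal_scale = 1.5)
    ve <- estimate_velocity(mu)
    est <- rbind(est, data.frame(vx = vx, vy = vy, vx_hat = ve$v[1],
                                 vy_hat = ve$v[2],
                                 residual = ve$diag_residual))
  }
  max_err <- max(abs(est$vx_hat - est$vx), abs(est$vy_hat - est$vy))
  # additivity: pre-warp a v-sequence by u and re-estimate
  v <- c(0.5, 0); u <- c(0.5, 0.25)
  seqv <- fixture_translating_sequence(v, n_frames, t0 = t0, size = size)
  # superimpose a Galilean transform with velocity u (stabilizing at -u
  # adds u to the pattern velocity)
  seq2 <- velocity_stabilize(seqv, -u, t_ref = 1)
  pmid <- c((size - 1) / 2 + (v[1] + u[1]) * (n_frames - 1) / 2,
            (size - 1) / 2 + (v[2] + u[2]) * (n_frames - 1) / 2,
            ceiling(n_frames / 2))
  ve2 <- estimate_velocity(st_second_moment(seq2, pmid, 3, 1.5))
  additivity_err <- max(abs(ve2$v - (v + u)))
  # stabilization contrast at |v| = 1
  v1 <- c(1, 0)
  moving <- fixture_translating_sequence(v1, n_frames, t0 = t0, size = size)
  stab <- velocity_stabilize(moving, v1,
                             t_ref = ceiling(n_frames / 2))
  # recentre: after stabilizing about the middle frame the blob sits where
  # the moving blob was at t_ref
  shift <- v1 * (ceiling(n_frames / 2) - 1)
  bl <- unclass(fixture_blob(t0, size,
                             center = c((size - 1) / 2 + shift[1],
                                        (size - 1) / 2 + shift[2])))
  arr <- array(0, c(n_frames, size, size))
  for (k in seq_len(n_frames)) arr[k, , ] <- bl
  static_sh <- image_sequence(arr)
  stc <- st_covariance(2, c(0, 0), 4)
  lap_seq <- function(s) {
    sm <- st_convolve(s, gaussian_st_kernel(stc))
    tmid <- ceiling(n_frames / 2)
    unclass(convolve2(unclass(sm)[tmid, , ], log_kernel(2)))
  }
  ref <- lap_seq(static_sh)
  rs <- lap_seq(stab)
  rm <- lap_seq(moving)
  crop <- (size %/% 4):(size - size %/% 4)
  rel <- function(a, b) sqrt(sum((a[crop, crop] - b[crop, crop])^2) /
                               sum(b[crop, crop]^2))
  list(max_abs_err = max_err, additivity_err = additivity_err,
       stabilized_rel_l2 = rel(rs, ref),
       unstabilized_rel_l2 = rel(rm, ref),
       estimates = est)
}

#' Time-causality, cascade variance additivity and streaming equivalence
#'
#' Causality is bitwise (no taps before t = 0); the K-fold cascade variance
#' equals `sum(mu^2)` within discretization error; streaming recursive
#' updating equals batch convolution.
#'
#' @param mu_sets list of time-constant vectors (K up to 8).
#' @param seed seed for the streaming test signal.
#' @return list with `causal_ok`, `max_variance_rel_err`,
#'   `stream_batch_max_diff`.
#' @export
check_time_causal <- function(mu_sets = list(2, c(1, 2), c(1, 1, 1, 1),
                                             c(0.5, 1, 2, 4),
                                             rep(1, 8)), seed = 3) {
  stk <- time_causal_st_kernel(st_covariance(2, c(0.5, 0), 1), mu = c(1, 2))
  causal_ok <- all(attr(stk, "frame_offsets") >= 0)
  verr <- 0
  for (mu in mu_sets) {
    k <- exp_cascade_kernel(mu)
    m <- temporal_kernel_moments(k)
    verr <- max(verr, abs(m$variance - sum(mu^2)) / sum(mu^2))
  }
  set.seed(seed)
  x <- stats::rnorm(400)
  mu <- c(1, 2); dt <- 0.25
  y_stream <- stream_exp_cascade(x, mu, dt)
  k <- exp_cascade_kernel(mu, dt = dt, tail_mass = 1e-12)
  xp <- c(rep(0, length(k$taps)), x)
  y_batch <- as.numeric(stats::filter(xp, k$taps, sides = 1))
  y_batch <- y_batch[-seq_len(length(k$taps))]
  ok <- !is.na(y_batch)
  list(causal_ok = causal_ok, max_variance_rel_err = verr,
       stream_batch_max_diff = max(abs(y_stream[ok] - y_batch[ok])))
}

#' Non-enhancement of local extrema under smoothing
#'
#' On seeded smooth random images, values at interior spatial maxima of the
#' scale-space representation never increase with scale, and minima never
#' decrease.
#'
#' @param n_images number of seeded textures.
#' @param scales increasing scale levels.
#' @param size image side.
#' @param seed_base textures use seeds `seed_base + 1 .. seed_base + n`.
#' @return list with `max_violation` (most positive increase of a maximum /
#'   decrease of a minimum; <= 0 means no violation) and `n_extrema`.
#' @export
check_non_enhancement <- function(n_images = 20, scales = c(1, 2, 4, 8, 16),
                                  size = 64, seed_base = 100) {
  worst <- -Inf
  count <- 0
  for (seed in seq_len(n_images)) {
    img <- fixture_texture(size, correlation_scale = 2,
                           seed = seed_base + seed)
    levels <- list(unclass(convolve2(img, gaussian_kernel(scales[1]))))
    for (i in 2:length(scales))
      levels[[i]] <- unclass(convolve2(levels[[i - 1]],
                                       gaussian_kernel(scales[i] -
                                                         scales[i - 1])))
    for (i in seq_len(length(scales) - 1)) {
      L <- levels[[i]]; Lnext <- levels[[i + 1]]
      inner <- 2:(size - 1)
      for (r in inner) for (cc in inner) {
        v <- L[r, cc]
        nb <- L[(r - 1):(r + 1), (cc - 1):(cc + 1)]
        if (v >= max(nb) && sum(nb == v) == 1) {
          worst <- max(worst, Lnext[r, cc] - v); count <- count + 1
        } else if (v <= min(nb) && sum(nb == v) == 1) {
          worst <- max(worst, v - Lnext[r, cc]); count <- count + 1
        }
      }
    }
  }
  list(max_violation = worst, n_extrema = count)
}

#' Illumination invariance on the log scale
#'
#' Derivative responses of `log(c f)` equal those of `log f` to machine
#' precision; on a sun/shade scene the Laplacian magnitude contrast between
#' halves is large on the linear scale and near 1 on the log scale.
#'
#' @param factors multiplicative gains to test.
#' @param seed seed for the texture and scene fixtures.
#' @return list with `max_gain_discrepancy`, `linear_ratio`, `log_ratio`.
#' @export
check_illumination <- function(factors = c(0.1, 3, 1000), seed = 21) {
  img <- fixture_texture(96, correlation_scale = 2, seed = seed,
                         mean = 0.5, sd = 0.1)
  worst <- 0
  for (c_ in factors)
    worst <- max(worst,
                 multiplicative_invariance_check(img, c(1, 0), 4, c_))
  scene <- fixture_illumination_scene(128, "step", seed = seed + 1,
                                      step_ratio = 4)
  f <- scene$composed
  half_ratio <- function(resp) {
    n <- ncol(resp); b <- 8
    left <- abs(resp[, b:(n / 2 - b)])
    right <- abs(resp[, (n / 2 + b):(n - b)])
    mean(left) / mean(right)
  }
  lin <- unclass(convolve2(f, log_kernel(4)))
  lg <- unclass(convolve2(unclass(log_transform(f)), log_kernel(4)))
  rl <- half_ratio(lin); rg <- half_ratio(lg)
  list(max_gain_discrepancy = worst,
       linear_ratio = max(rl, 1 / rl), log_ratio = max(rg, 1 / rg))
}

#' DoG to scaled-Laplacian convergence
#'
#' The relative discrepancy between `dog_kernel(s1, s2)` and
#' `(s2 - s1)/2 * laplacian g` decreases monotonically as `s2/s1 -> 1`.
#'
#' @param ratios decreasing sequence of `s2/s1`.
#' @param s1 base scale.
#' @return list with `discrepancies` (named by ratio) and `monotone`.
#' @export
check_dog_convergence <- function(ratios = c(1.5, 1.2, 1.1, 1.05), s1 = 4) {
  d <- vapply(ratios, function(r) log_dog_discrepancy(s1, s1 * r),
              numeric(1))
  names(d) <- as.character(ratios)
  list(discrepancies = d, monotone = all(diff(d) < 0))
}

#' Run the package property suite
#'
#' Executes the executable property checks (semigroup/cascade, blob scale
#' selection, scaling covariance, affine fixed point, Galilean velocity,
#' time causality, non-enhancement, illumination invariance, DoG
#' convergence) and reports one pass/fail row per property.
#'
#' @param quick reduce problem sizes (fewer velocities / images) for a
#'   fast smoke run.
#' @param seed base seed for all seeded fixtures.
#' @return data frame with columns `property`, `value`, `threshold`,
#'   `pass`; attribute `details` holds the raw check outputs.
#' @export
rf_selftest <- function(quick = FALSE, seed = 1) {
  res <- list()
  res$semigroup <- check_semigroup(seed = seed + 10)
  res$blob <- check_blob_scale(if (quick) c(4, 16) else c(2, 4, 16))
  res$scaling <- check_scaling_covariance(seed = seed + 4)
  res$affine <- check_affine_fixed_point()
  res$velocity <- check_velocity(if (quick) c(-1, 0, 1) else
                                   c(-1, -0.5, 0, 0.5, 1))
  res$causal <- check_time_causal(seed = seed + 2)
  res$nonenh <- check_non_enhancement(if (quick) 5 else 20,
                                      seed_base = seed + 99)
  res$illum <- check_illumination(seed = seed + 20)
  res$dog <- check_dog_convergence()
  rows <- rbind(
    data.frame(property = "semigroup_l1", value = res$semigroup$semigroup_max_l1,
               threshold = 1e-3),
    data.frame(property = "cascade_rel_err",
               value = res$semigroup$cascade_max_rel_err, threshold = 1e-6),
    data.frame(property = "blob_scale_laplacian",
               value = res$blob$max_rel_err_laplacian, threshold = 0.05),
    data.frame(property = "blob_scale_dethess",
               value = res$blob$max_rel_err_dethess, threshold = 0.05),
    data.frame(property = "blob_pair_ratio",
               value = res$blob$pair_ratio_rel_err, threshold = 0.10),
    data.frame(property = "scaling_covariance_s_ratio",
               value = res$scaling$s_ratio_rel_err, threshold = 0.10),
    data.frame(property = "scaling_covariance_patch",
               value = res$scaling$patch_rel_l2, threshold = 0.05),
    data.frame(property = "affine_residual",
               value = max(res$affine$residual,
                           res$affine$residual_warped), threshold = 0.05),
    data.frame(property = "affine_similarity",
               value = res$affine$similarity_dev, threshold = 0.05),
    data.frame(property = "velocity_recovery",
               value = res$velocity$max_abs_err, threshold = 0.05),
    data.frame(property = "velocity_additivity",
               value = res$velocity$additivity_err, threshold = 0.05),
    data.frame(property = "stabilized_match",
               value = res$velocity$stabilized_rel_l2, threshold = 0.05),
    data.frame(property = "unstabilized_mismatch_exceeds",
               value = res$velocity$unstabilized_rel_l2, threshold = 0.15),
    data.frame(property = "causality_bitwise",
               value = as.numeric(!res$causal$causal_ok), threshold = 0.5),
    data.frame(property = "cascade_variance",
               value = res$causal$max_variance_rel_err, threshold = 0.02),
    data.frame(property = "stream_equals_batch",
               value = res$causal$stream_batch_max_diff, threshold = 1e-6),
    data.frame(property = "non_enhancement",
               value = res$nonenh$max_violation, threshold = 1e-9),
    data.frame(property = "illumination_gain",
               value = res$illum$max_gain_discrepancy, threshold = 1e-10),
    data.frame(property = "sunshade_linear_ratio_exceeds",
               value = res$illum$linear_ratio, threshold = 2),
    data.frame(property = "sunshade_log_ratio",
               value = res$illum$log_ratio, threshold = 1.1),
    data.frame(property = "dog_log_convergence",
               value = unname(res$dog$discrepancies["1.05"]),
               threshold = 0.02))
  rows$pass <- rows$value < rows$threshold
  # "exceeds" rows assert a lower bound
  exceeds <- grepl("_exceeds$", rows$property)
  rows$pass[exceeds] <- rows$value[exceeds] > rows$threshold[exceeds]
  structure(rows, details = res)
}
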