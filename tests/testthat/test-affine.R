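test_that("second moment reflects local pattern symmetry", {
  # rotationally symmetric blob: mu proportional to the identity
  img <- fixture_blob(8, 97, amplitude = 100)
  p <- attr(img, "center")
  sm <- second_moment(img, p, 2, 8)
  expect_lt(abs(sm$mu[1, 2]), 1e-3 * sum(diag(sm$mu)))
  expect_equal(sm$mu[1, 1], sm$mu[2, 2], tolerance = 1e-6 * sm$mu[1, 1])
  # grating varying along x only: all energy in mu_xx
  gr <- fixture_grating(8, 97, angle = 0)
  smg <- second_moment(gr, c(48, 48), 2, 8)
  expect_lt(smg$mu[2, 2] / smg$mu[1, 1], 1e-3)
  # flat region: zero matrix
  flat <- image2d(matrix(1, 49, 49))
  smf <- second_moment(flat, c(24, 24), 2, 8)
  expect_lt(max(abs(smf$mu)), 1e-12)
  expect_error(second_moment(img, p, 4, 2), "integration_scale")
  expect_error(second_moment(img, c(0, 0), 2, 8), "border")
})

test_that("second moment rotates with the pattern", {
  img <- fixture_grating(10, 161, angle = 0)
  alpha <- pi / 5
  imgr <- fixture_grating(10, 161, angle = alpha)
  p <- c(80, 80)
  mu0 <- second_moment(img, p, 2, 18)$mu
  mur <- second_moment(imgr, p, 2, 18)$mu
  pred <- rot2(alpha) %*% mu0 %*% t(rot2(alpha))
  expect_lt(norm(mur - pred, "2") / norm(mu0, "2"), 0.02)
})

test_that("affine second moment reduces to the isotropic one and obeys the
           affine transformation law", {
  img <- fixture_ring_wave(161, 12)
  p <- c(80, 80)
  iso <- second_moment(img, p, 3, 12)$mu
  aff <- affine_second_moment(img, p, diag(2) * 3, diag(2) * 12)$mu
  expect_equal(aff, iso, tolerance = 1e-12)
  # warp oracle: view 2 shows f'(x) = f(A x) rendered analytically; with
  # matched covariances Sigma' = A^{-1} Sigma A^{-T} the second moments
  # satisfy mu' = A^T mu A with no determinant factor
  A <- matrix(c(1.4, 0.1, 0.3, 0.8), 2, 2)
  imgw <- fixture_ring_wave(161, 12, warp = A)
  Ai <- solve(A)
  muw <- affine_second_moment(imgw, p, Ai %*% (diag(2) * 3) %*% t(Ai),
                              Ai %*% (diag(2) * 12) %*% t(Ai))$mu
  pred <- t(A) %*% iso %*% A
  expect_lt(norm(muw - pred, "2") / norm(pred, "2"), 0.03)
})

test_that("adaptation on an isotropic pattern converges immediately", {
  img <- fixture_ring_wave(121, 12)
  fr <- affine_adapt(img, c(60, 60), init_sigma = 3)
  expect_equal(fr$iterations, 1)
  expect_lt(fr$fixed_point_residual, 0.05)
  expect_equal(det(fr$transform), 1, tolerance = 1e-10)
  # frame of an isotropic pattern is (close to) the identity
  expect_lt(norm(fr$transform - diag(2), "2"), 0.05)
})

test_that("adaptation reaches the fixed point for cond <= 3 warps and the
           two-view frames agree up to a similarity", {
  res <- check_affine_fixed_point()
  expect_lte(res$iterations, 20)
  expect_lt(res$residual, 0.05)
  expect_lt(res$similarity_dev, 0.05)
  expect_true(all(res$per_warp$cond <= 3 + 1e-9))
})

test_that("accepted iterations decrease the isotropy residual
           monotonically", {
  A <- diag(c(sqrt(3), 1 / sqrt(3)))
  img <- fixture_ring_wave(161, 12, warp = A)
  fr <- affine_adapt(img, c(80, 80), init_sigma = 3)
  expect_true(all(diff(fr$residual_trace) < 0))
})

test_that("structureless patches trigger a degeneracy error, never a
           silent frame", {
  flat <- image2d(matrix(1, 97, 97))
  expect_error(affine_adapt(flat, c(48, 48), init_sigma = 3),
               "degenerate|stalled|convergence")
})

test_that("affine patch normalization: identity frame crops directly and
           the applied transform has unit determinant", {
  img <- fixture_ring_wave(121, 12)
  fr <- affine_adapt(img, c(60, 60), init_sigma = 3)
  patch <- affine_normalize_patch(img, c(60, 60), fr, patch_radius = 10)
  expect_equal(dim(patch), c(21, 21))
  expect_equal(det(solve(fr$transform)), 1, tolerance = 1e-10)
  # frame near identity: patch approximately equals the direct crop
  direct <- unclass(img)[51:71, 51:71]
  expect_lt(rel_l2(patch, direct), 0.05)
  big <- matrix(c(40, 0, 0, 1 / 40), 2, 2)
  frb <- structure(list(transform = big), class = "affine_frame")
  expect_error(affine_normalize_patch(img, c(60, 60), frb,
                                      patch_radius = 30), "outside")
})

test_that("normalized patches from two affine views align up to a
           rotation", {
  A <- matrix(c(1, 0, 0.5, 1), 2, 2) %*% diag(c(1.3, 1 / 1.3))
  img <- fixture_ring_wave(161, 12)
  imgw <- fixture_ring_wave(161, 12, warp = A)
  p <- c(80, 80)
  f1 <- affine_adapt(img, p, init_sigma = 3)
  f2 <- affine_adapt(imgw, p, init_sigma = 3)
  p1 <- affine_normalize_patch(img, p, f1, patch_radius = 14)
  p2 <- affine_normalize_patch(imgw, p, f2, patch_radius = 14)
  # search the residual rotation
  best <- Inf
  for (ang in seq(0, 2 * pi, length.out = 73)) {
    p2r <- unclass(warp_affine(p2, rot2(ang)))
    ctr <- 8:22
    best <- min(best, rel_l2(p2r[ctr, ctr], p1[ctr, ctr]))
  }
  expect_lt(best, 0.08)
})
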