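test_that("gaussian kernel matches the closed form and its symmetries", {
  k <- gaussian_kernel(2)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  # renormalization after 5-sd truncation perturbs the centre tap by < 1e-5
  expect_equal(center_tap(k), 1 / (4 * pi), tolerance = 1e-4)
  k4 <- taps(gaussian_kernel(4))
  expect_identical(k4, t(k4))                       # transpose symmetry
  expect_identical(k4, k4[nrow(k4):1, ])            # 180/90 degree grid
  expect_identical(k4, k4[, ncol(k4):1])            # rotations are exact
  expect_error(gaussian_kernel(-1), "positive")
  expect_error(gaussian_kernel(0), "positive")
})

test_that("semigroup holds numerically: g(s1)*g(s2) ~ g(s1+s2)", {
  for (pair in list(c(1, 3), c(2, 2), c(4, 8))) {
    s1 <- pair[1]; s2 <- pair[2]
    g12 <- gaussian_kernel(s1 + s2)
    r12 <- attr(g12, "support_radius")
    big <- image2d(pad_kernel_to(gaussian_kernel(s1), r12 + 3))
    conv <- unclass(convolve2(big, gaussian_kernel(s2), "constant"))
    ref <- pad_kernel_to(g12, r12 + 3)
    expect_lt(sum(abs(conv - ref)), 1e-3)
  }
})

test_that("derivative kernels obey parity, rotation identity and zero sum", {
  d10 <- gaussian_derivative_kernel(c(1, 0), 2)
  expect_identical(center_tap(d10) == 0, FALSE) # centre is analytically 0
  expect_lt(abs(center_tap(d10)), 1e-15)
  expect_lt(abs(sum(d10)), 1e-6)
  m <- taps(d10)
  expect_equal(m, -m[, ncol(m):1], tolerance = 1e-12) # odd along x
  # the (0,1) kernel at phi = 0 equals the (1,0) kernel at phi = pi/2
  d01 <- gaussian_derivative_kernel(c(0, 1), 2, phi = 0)
  d10r <- gaussian_derivative_kernel(c(1, 0), 2, phi = pi / 2)
  expect_equal(taps(d01), taps(d10r), tolerance = 1e-12)
  expect_error(gaussian_derivative_kernel(c(3, 2), 2), "unsupported")
})

test_that("second-derivative kernels sum to the Laplacian of Gaussian", {
  dxx <- gaussian_derivative_kernel(c(2, 0), 2)
  dyy <- gaussian_derivative_kernel(c(0, 2), 2)
  # nabla^2 g at the origin is -1/(pi s^2) = -1/(4 pi) for s = 2
  expect_equal(center_tap(dxx) + center_tap(dyy), -1 / (4 * pi),
               tolerance = 1e-4)
  lg <- log_kernel(2)
  expect_equal(taps(lg), taps(dxx) + taps(dyy), tolerance = 1e-12)
})

test_that("affine kernel reduces to the isotropic case and recovers its
           covariance from tap moments", {
  iso <- affine_gaussian_kernel(spatial_covariance(lambda1 = 2, lambda2 = 2))
  expect_equal(taps(iso), taps(gaussian_kernel(2)), tolerance = 1e-14)
  for (theta in c(0, pi / 4)) {
    cov <- spatial_covariance(lambda1 = 8, lambda2 = 2, theta = theta)
    k <- affine_gaussian_kernel(cov)
    m <- unclass(k); r <- attr(k, "support_radius")
    xs <- seq(-r[2], r[2]); ys <- seq(-r[1], r[1])
    mxx <- sum(outer(ys^0, xs^2) * m)
    myy <- sum(outer(ys^2, xs^0) * m)
    mxy <- sum(outer(ys, xs) * m)
    M <- matrix(c(mxx, mxy, mxy, myy), 2, 2)
    expect_lt(norm(M - cov$sigma, "2") / norm(cov$sigma, "2"), 0.02)
  }
  expect_error(affine_gaussian_kernel(matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
})

test_that("rotating the covariance equals resampling the kernel", {
  k0 <- affine_gaussian_kernel(spatial_covariance(lambda1 = 8, lambda2 = 2,
                                                  theta = 0))
  k45 <- affine_gaussian_kernel(spatial_covariance(lambda1 = 8, lambda2 = 2,
                                                   theta = pi / 4))
  r <- pmax(attr(k0, "support_radius"), attr(k45, "support_radius"))
  a <- pad_kernel_to(k0, r)
  b <- pad_kernel_to(k45, r)
  # resample the theta = 0 kernel under a -45 degree rotation (pull-back)
  a_rot <- unclass(warp_affine(a, rot2(-pi / 4)))
  expect_lt(rel_l2(a_rot, b), 0.02)
})

test_that("spatial covariance round-trips between (l1, l2, theta) and Sigma", {
  cov <- spatial_covariance(lambda1 = 8, lambda2 = 2, theta = 1.1)
  back <- spatial_covariance(sigma_matrix = cov$sigma)
  expect_equal(back$lambda1, 8, tolerance = 1e-12)
  expect_equal(back$lambda2, 2, tolerance = 1e-12)
  expect_equal(back$theta, 1.1, tolerance = 1e-12)
  expect_error(spatial_covariance(lambda1 = -1, lambda2 = 1), "positive")
})

test_that("directional derivative kernels reduce, integrate to zero, and
           match finite differences of the affine Gaussian", {
  # isotropic reduction
  a <- directional_derivative_kernel(spatial_covariance(lambda1 = 2,
                                                        lambda2 = 2),
                                     c(1, 0), phi = 0)
  b <- gaussian_derivative_kernel(c(1, 0), 2, phi = 0)
  expect_equal(taps(a), taps(b), tolerance = 1e-12)
  # zero mean for a first-order kernel along the covariance axis
  cov <- spatial_covariance(lambda1 = 8, lambda2 = 2, theta = pi / 6)
  d <- directional_derivative_kernel(cov, c(1, 0))
  expect_lt(abs(sum(d)), 1e-6)
  # finite-difference oracle along x at theta = 0
  cov0 <- spatial_covariance(lambda1 = 8, lambda2 = 2, theta = 0)
  dx <- directional_derivative_kernel(cov0, c(1, 0), phi = 0)
  h <- 0.01
  r <- attr(dx, "support_radius")
  xs <- seq(-r[2], r[2]); ys <- seq(-r[1], r[1])
  g_plus <- visrf:::gauss_poly_grid(cov0$sigma, NULL, xs + h / 2, ys)
  g_minus <- visrf:::gauss_poly_grid(cov0$sigma, NULL, xs - h / 2, ys)
  fd <- (g_plus - g_minus) / h
  expect_lt(rel_l2(fd, taps(dx)), 0.01)
})

test_that("convolution is exact for identity kernels, preserves constants
           and is linear", {
  img <- fixture_texture(32, correlation_scale = 1, seed = 2)
  ident <- kernel2d(matrix(1, 1, 1))
  expect_equal(taps(convolve2(img, ident)), taps(img), tolerance = 1e-14)
  const <- image2d(matrix(3.7, 24, 24))
  out <- convolve2(const, gaussian_kernel(4), "mirror")
  expect_equal(max(abs(unclass(out) - 3.7)), 0, tolerance = 1e-12)
  f1 <- unclass(fixture_texture(32, 1, seed = 3))
  f2 <- unclass(fixture_texture(32, 1, seed = 4))
  k <- gaussian_derivative_kernel(c(1, 1), 2)
  lhs <- unclass(convolve2(2.5 * f1 - 1.25 * f2, k))
  rhs <- 2.5 * unclass(convolve2(f1, k)) - 1.25 * unclass(convolve2(f2, k))
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_error(convolve2(matrix(0, 4, 4), matrix(1, 31, 31)), "larger")
  # identity via image2d round trip
  expect_equal(taps(convolve2(img, ident)), taps(img), tolerance = 1e-14)
})

test_that("cascade smoothing equals direct smoothing away from borders", {
  img <- fixture_texture(96, correlation_scale = 2, seed = 11)
  rng <- diff(range(img))
  direct <- unclass(convolve2(img, gaussian_kernel(8)))
  two <- unclass(convolve2(convolve2(img, gaussian_kernel(3)),
                           gaussian_kernel(5)))
  ctr <- 30:66
  expect_lt(max(abs(direct[ctr, ctr] - two[ctr, ctr])) / rng, 1e-6)
})

test_that("smoothing satisfies the diffusion equation ds L = 1/2 lap L", {
  img <- fixture_texture(72, correlation_scale = 2, seed = 9)
  s <- 4; d <- 0.01 * s
  L1 <- unclass(convolve2(img, gaussian_kernel(s)))
  L2 <- unclass(convolve2(img, gaussian_kernel(s + d)))
  lap <- unclass(convolve2(img, log_kernel(s)))
  ctr <- 20:52
  lhs <- (L2 - L1)[ctr, ctr] / d
  rhs <- lap[ctr, ctr] / 2
  expect_lt(rel_l2(lhs, rhs), 0.01)
})

test_that("affine covariance: matched kernels commute with warps", {
  A <- diag(c(1.5, 1 / 1.5))
  img <- fixture_ring_wave(121, 10)
  imgw <- fixture_ring_wave(121, 10, warp = A)  # f'(x) = f(A x), exact
  cov1 <- diag(2) * 6
  cov2 <- solve(A) %*% cov1 %*% t(solve(A))
  L1 <- unclass(convolve2(img, affine_gaussian_kernel(cov1)))
  L2 <- unclass(convolve2(imgw, affine_gaussian_kernel(cov2)))
  # warp the view-1 response into view 2 and compare interiors
  L1w <- unclass(warp_affine(L1, A))
  ctr <- 35:85
  expect_lt(rel_l2(L2[ctr, ctr], L1w[ctr, ctr]), 0.02)
})
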