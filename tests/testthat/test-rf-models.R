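test_that("LGN kernel is centre-surround with exact zero response to
           constants", {
  k <- lgn_kernel(8)
  expect_lt(abs(sum(k)), 1e-6)
  # on-centre polarity: centre tap positive (-lap g > 0 at origin)
  expect_equal(center_tap(k), 1 / (pi * 64), tolerance = 1e-3)
  koff <- lgn_kernel(8, polarity = -1)
  expect_equal(taps(koff), -taps(k))
  const <- image2d(matrix(5, 48, 48))
  expect_lt(max(abs(convolve2(const, k))), 1e-10)
  # rotational symmetry on the grid
  m <- taps(k)
  expect_equal(m, t(m), tolerance = 1e-15)
  expect_error(lgn_kernel(8, polarity = 2), "polarity")
})

test_that("space-time separable LGN kernel composes the spatial surround
           with the temporal smoother", {
  h <- exp_cascade_kernel(c(1, 2), dt = 1, tail_mass = 1e-6)
  k <- lgn_kernel(4, temporal = h)
  expect_true(inherits(k, "st_kernel"))
  expect_true(all(attr(k, "frame_offsets") >= 0))
  expect_equal(unclass(k)[2, , ], h$taps[2] * taps(lgn_kernel(4)),
               tolerance = 1e-12)
})

test_that("DoG kernel approximates the scaled Laplacian and converges
           monotonically as the scale ratio shrinks", {
  dog <- dog_kernel(4, 4 * 1.05)
  expect_lt(abs(sum(dog)), 1e-6)
  expect_lt(log_dog_discrepancy(4, 4 * 1.05), 0.02)
  d <- vapply(c(1.5, 1.2, 1.1, 1.05),
              function(r) log_dog_discrepancy(4, 4 * r), numeric(1))
  expect_true(all(diff(d) < 0))
  expect_error(dog_kernel(4, 4), "s2 > s1")
})

test_that("V1 simple-cell kernels reduce to the expected special cases", {
  # isotropic covariance: directional derivative is the plain Gaussian
  # derivative
  a <- v1_simple_kernel(4, spatial_orders = c(1, 0), phi = 0)
  b <- gaussian_derivative_kernel(c(1, 0), 4, phi = 0)
  expect_equal(taps(a), taps(b), tolerance = 1e-12)
  # oriented odd-symmetric profile with zero tap sum
  k <- v1_simple_kernel(spatial_covariance(lambda1 = 16, lambda2 = 4),
                        spatial_orders = c(1, 0))
  expect_lt(abs(sum(k)), 1e-6)
  m <- taps(k)
  expect_equal(m, -m[, ncol(m):1], tolerance = 1e-12)
  # rotating covariance and preferred direction together rotates the kernel
  cov0 <- spatial_covariance(lambda1 = 16, lambda2 = 4, theta = 0)
  cov45 <- spatial_covariance(lambda1 = 16, lambda2 = 4, theta = pi / 4)
  k0 <- v1_simple_kernel(cov0, c(1, 0))
  k45 <- v1_simple_kernel(cov45, c(1, 0))
  r <- pmax(attr(k0, "support_radius"), attr(k45, "support_radius"))
  rot <- unclass(warp_affine(pad_kernel_to(k0, r), rot2(-pi / 4)))
  expect_lt(rel_l2(rot, pad_kernel_to(k45, r)), 0.03)
})

test_that("velocity-adapted V1 kernel tilts its centroid trajectory at the
           adapted velocity", {
  k <- v1_simple_kernel(4, spatial_orders = c(0, 0), velocity = c(0.8, 0),
                        temporal = list(temporal_variance = 2),
                        temporal_order = 2)
  raw <- unclass(k)
  fo <- attr(k, "frame_offsets")
  rx <- (dim(raw)[3] - 1) / 2
  xs <- seq(-rx, rx)
  cents <- c(); ts <- c(); wts <- c()
  for (i in seq_along(fo)) {
    sl <- raw[i, , ]
    w <- sum(abs(sl))
    if (w < 1e-3 * max(abs(raw))) next
    cents <- c(cents, sum(sweep(abs(sl), 2, xs, `*`)) / w)
    ts <- c(ts, fo[i]); wts <- c(wts, w)
  }
  slope <- stats::coef(stats::lm(cents ~ ts, weights = wts))[2]
  expect_equal(unname(slope), 0.8, tolerance = 0.05)
})

test_that("hemisphere covariance sampler realizes the foreshortening
           model", {
  covs <- hemisphere_covariances(400, lambda1 = 16, seed = 3)
  slant <- attr(covs, "slant")
  ratios <- vapply(covs, function(cv) cv$lambda2 / cv$lambda1, numeric(1))
  expect_equal(ratios, cos(slant)^2, tolerance = 1e-10)
  # uniform hemisphere: cos^2(slant) is uniform on (0, 1)
  expect_gt(stats::ks.test(ratios, "punif")$p.value, 0.01)
})

test_that("rf_gallery enumerates the parameter grid deterministically", {
  g <- rf_gallery(orientations = c(0, pi / 3, 2 * pi / 3), scales = c(8, 16))
  expect_length(g$kernels, 6)
  expect_equal(nrow(g$manifest), 6)
  expect_identical(names(g$kernels), g$manifest$name)
  g2 <- rf_gallery(orientations = c(0, pi / 3, 2 * pi / 3),
                   scales = c(8, 16))
  expect_identical(g$manifest, g2$manifest)
  empty <- rf_gallery(orientations = numeric(0), scales = numeric(0))
  expect_length(empty$kernels, 0)
})
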