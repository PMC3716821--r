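test_that("scale normalization follows the gamma power law", {
  # ramp f(x, y) = x: unnormalized first derivative is 1 at all scales,
  # normalized response is s^(1/2) at gamma = 1
  ramp <- image2d(matrix(rep(0:47, each = 48), 48, 48))
  for (s in c(2, 4, 9)) {
    r <- normalized_derivative_response(ramp, c(1, 0), s, gamma = 1)
    expect_equal(unclass(r)[24, 24], sqrt(s), tolerance = 1e-4)
  }
  # at s = 1 the normalization factor is exactly 1 for any gamma
  img <- fixture_texture(48, 2, seed = 13)
  a <- normalized_derivative_response(img, c(2, 0), 1, gamma = 0.7)
  b <- convolve2(img, gaussian_derivative_kernel(c(2, 0), 1))
  expect_equal(taps(a), taps(b), tolerance = 1e-14)
  expect_error(normalized_derivative_response(img, c(1, 0), -2), "positive")
})

test_that("normalized Laplacian and det-Hessian of a blob peak at the blob
           scale with the closed-form values", {
  t0 <- 4
  img <- fixture_blob(t0, 97)
  p <- attr(img, "center")
  # closed forms at the centre: s |lap L| = s/(pi (s+t0)^2),
  # s^2 det H = s^2/(4 pi^2 (s+t0)^4)
  for (s in c(2, 4, 8)) {
    lap <- unclass(norm_laplacian(img, s))[p[2] + 1, p[1] + 1]
    expect_equal(lap, -s / (pi * (s + t0)^2), tolerance = 1e-3)
    dh <- unclass(norm_det_hessian(img, s))[p[2] + 1, p[1] + 1]
    expect_equal(dh, s^2 / (4 * pi^2 * (s + t0)^4), tolerance = 1e-3)
  }
  const <- image2d(matrix(1, 32, 32))
  expect_lt(max(abs(norm_laplacian(const, 4))), 1e-10)
  expect_lt(max(abs(norm_det_hessian(const, 4))), 1e-10)
})

test_that("scale signatures localize blob extrema at s = t0 and report
           none on monotone signatures", {
  for (t0 in c(2, 4, 16)) {
    img <- fixture_blob(t0, 121)
    p <- attr(img, "center")
    sig <- scale_signature(img, p, "laplacian",
                           scale_grid(t0 / 8, t0 * 8, 4))
    expect_gt(nrow(sig$extrema), 0)
    expect_equal(sig$extrema$s_hat[1], t0, tolerance = 0.05 * t0)
    sigd <- scale_signature(img, p, "dethess",
                            scale_grid(t0 / 8, t0 * 8, 4))
    expect_equal(sigd$extrema$s_hat[1], t0, tolerance = 0.05 * t0)
  }
  # monotone signature: scan far below the blob scale only
  img <- fixture_blob(64, 121)
  sig <- scale_signature(img, attr(img, "center"), "laplacian",
                         scale_grid(1, 4, 3))
  expect_equal(nrow(sig$extrema), 0)
  expect_error(scale_signature(img, c(0, 5), "laplacian"), "border")
  expect_error(scale_signature(img, c(60, 60), "laplacian",
                               scales = c(4, 2, 1)), "increasing")
})

test_that("two blobs at scale ratio 4 select scales at ratio 4", {
  img4 <- fixture_blob(4, 121); img16 <- fixture_blob(16, 121)
  s4 <- scale_signature(img4, attr(img4, "center"), "laplacian",
                        scale_grid(1, 64, 4))$extrema$s_hat[1]
  s16 <- scale_signature(img16, attr(img16, "center"), "laplacian",
                         scale_grid(1, 64, 4))$extrema$s_hat[1]
  expect_equal(s16 / s4, 4, tolerance = 0.1 * 4)
})

test_that("scale selection is covariant under image rescaling and yields
           matching normalized patches", {
  res <- check_scaling_covariance()
  expect_equal(res$s_ratio, 4, tolerance = 0.1 * 4)
  expect_lt(res$patch_rel_l2, 0.05)
})

test_that("select_scale_and_normalize is the identity at matching scale
           and errors without an extremum", {
  img <- fixture_blob(4, 121)
  p <- attr(img, "center")
  sel <- select_scale_and_normalize(img, p, "laplacian",
                                    scale_grid(1, 32, 4),
                                    reference_scale = sel_ref <- 4,
                                    patch_radius = 8)
  direct <- visrf:::sample_patch(img, p, diag(2) * sqrt(sel$s_hat / 4), 8)
  expect_equal(sel$patch, direct, tolerance = 1e-12)
  expect_error(select_scale_and_normalize(fixture_blob(64, 121), p,
                                          "laplacian",
                                          scale_grid(1, 4, 3)),
               "extremum")
})
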