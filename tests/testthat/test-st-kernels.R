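test_that("zero-velocity spatio-temporal Gaussian is space-time separable", {
  stk <- gaussian_st_kernel(st_covariance(2, c(0, 0), 2))
  ksp <- unclass(gaussian_kernel(2))
  kt <- temporal_gaussian_kernel(2)
  sep <- outer(kt$taps, ksp)
  expect_lt(max(abs(unclass(stk) - sep)), 1e-10)
  # spatial marginal at fixed t equals the temporal Gaussian tap
  marg <- apply(unclass(stk), 1, sum)
  expect_equal(marg, kt$taps, tolerance = 0.01)
})

test_that("velocity shears the kernel: slices are translated Gaussians", {
  v <- 0.5
  stk <- gaussian_st_kernel(st_covariance(2, c(v, 0), 2))
  fo <- attr(stk, "frame_offsets")
  raw <- unclass(stk)
  rx <- (dim(raw)[3] - 1) / 2; ry <- (dim(raw)[2] - 1) / 2
  xs <- seq(-rx, rx)
  for (i in seq_along(fo)) {
    sl <- raw[i, , ]
    if (sum(sl) < 1e-6) next
    cx <- sum(sweep(sl, 2, xs, `*`)) / sum(sl)
    expect_equal(cx, v * fo[i], tolerance = 1e-6)
  }
})

test_that("time-causal kernels are causal bitwise and velocity tracks the
           per-frame centroid", {
  stk <- time_causal_st_kernel(st_covariance(2, c(1, 0), 1), mu = 2)
  fo <- attr(stk, "frame_offsets")
  expect_true(all(fo >= 0))   # no support before the present frame
  raw <- unclass(stk)
  rx <- (dim(raw)[3] - 1) / 2
  xs <- seq(-rx, rx)
  for (i in which(fo %in% c(0, 2, 5))) {
    sl <- raw[i, , ]
    cx <- sum(sweep(sl, 2, xs, `*`)) / sum(sl)
    expect_equal(cx, fo[i] * 1, tolerance = 0.05)
  }
  # v = 0, single stage: separable product of Gaussian and exponential
  stk0 <- time_causal_st_kernel(st_covariance(2, c(0, 0), 1), mu = 2)
  h <- exp_cascade_kernel(2, dt = 1, tail_mass = 1e-6)
  sep <- outer(h$taps, unclass(gaussian_kernel(2)))
  expect_lt(max(abs(unclass(stk0) - sep)), 1e-12)
})

test_that("derivative kernels have zero tap sum and v = 0 reduces the
           velocity-adapted temporal derivative to plain dt", {
  for (spec in list(list(so = c(1, 0), n = 0), list(so = c(0, 0), n = 1),
                    list(so = c(2, 1), n = 1))) {
    stk <- st_derivative_kernel(st_covariance(3, c(0.5, 0.25), 2),
                                spatial_orders = spec$so,
                                temporal_order = spec$n)
    expect_lt(abs(sum(stk)), 1e-6)
  }
  a <- st_derivative_kernel(st_covariance(2, c(0, 0), 2),
                            temporal_order = 1)
  b <- gaussian_st_kernel(st_covariance(2, c(0, 0), 2), temporal_order = 1)
  expect_identical(unclass(a), unclass(b))
})

test_that("velocity-adapted first temporal derivative annihilates a
           pattern translating at the adapted velocity", {
  v <- 1
  nt <- 21
  seq_m <- translating_grating(v, nt)
  seq_s <- translating_grating(0, nt)
  stk <- st_derivative_kernel(st_covariance(2, c(v, 0), 2),
                              temporal_order = 1)
  resp_m <- unclass(st_convolve(seq_m, stk))
  resp_s <- unclass(st_convolve(seq_s, stk))
  mid <- 11; ctr <- 16:32
  # moving response vanishes; the same kernel on the static pattern gives
  # the non-zero advection term v . grad L
  expect_lt(max(abs(resp_m[mid, ctr, ctr])),
            1e-3 * max(abs(resp_s[mid, ctr, ctr])))
})

test_that("Galilean covariance: the v-adapted response to a static pattern
           matches the (v+u)-adapted response to the u-moving pattern", {
  u <- 0.5
  nt <- 21
  static <- fixture_translating_sequence(c(0, 0), nt, t0 = 6, size = 48)
  moving <- fixture_translating_sequence(c(u, 0), nt, t0 = 6, size = 48)
  k_static <- gaussian_st_kernel(st_covariance(2, c(0, 0), 2))
  k_moving <- gaussian_st_kernel(st_covariance(2, c(u, 0), 2))
  r_static <- unclass(st_convolve(static, k_static))
  r_moving <- unclass(st_convolve(moving, k_moving))
  mid <- 11
  # at frame mid the moving pattern sits at offset u * (mid - 1)
  shifted <- unclass(warp_affine(r_moving[mid, , ], diag(2),
                                 offset = c(u * (mid - 1), 0),
                                 center_out = c(0, 0), center_in = c(0, 0)))
  ctr <- 13:35
  expect_lt(rel_l2(shifted[ctr, ctr], r_static[mid, , ][ctr, ctr]), 0.03)
})

test_that("st_covariance validates its inputs and builds the 3x3 matrix", {
  stc <- st_covariance(spatial_covariance(lambda1 = 4, lambda2 = 2),
                       c(0.5, -0.25), 3)
  M <- stc$matrix
  expect_equal(M[3, 3], 3)
  expect_equal(M[1, 3], 3 * 0.5)
  expect_equal(M[2, 3], 3 * -0.25)
  expect_true(isSymmetric(M))
  expect_error(st_covariance(4, c(0, 0), -1), "positive")
  expect_error(gaussian_st_kernel(st_covariance(4), temporal_order = 3),
               "order")
})
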