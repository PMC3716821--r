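test_that("spatio-temporal second moment vanishes in time for static
           sequences and in space for pure flicker", {
  static <- fixture_translating_sequence(c(0, 0), 25, t0 = 8, size = 48)
  mu <- st_second_moment(static, c(23.5, 23.5, 13), 3, 1.5)$mu
  expect_lt(max(abs(mu[, 3])), 1e-8 * max(abs(mu)))
  # flat field with temporal flicker: spatial block zero, mu_tt > 0
  flick <- image_sequence(array(sin((1:25) / 2), c(25, 16, 16)))
  muf <- st_second_moment(flick, c(8, 8, 13), 2, 1.5)$mu
  expect_lt(max(abs(muf[1:2, 1:2])), 1e-10 * muf[3, 3])
  expect_gt(muf[3, 3], 0)
  expect_error(st_second_moment(static, c(23.5, 23.5, 1), 3, 1.5),
               "interior")
})

test_that("a translating blob satisfies the advection identity
           mu_xt = -v mu_xx", {
  v <- 0.5
  seqv <- fixture_translating_sequence(c(v, 0), 25, t0 = 8, size = 56)
  p <- c(27.5 + v * 12, 27.5, 13)
  mu <- st_second_moment(seqv, p, 3, 1.5)$mu
  expect_equal(mu[1, 3], -v * mu[1, 1], tolerance = 0.03)
})

test_that("velocity estimation recovers the true velocity and degrades
           gracefully", {
  static <- fixture_translating_sequence(c(0, 0), 25, t0 = 8, size = 48)
  ve0 <- estimate_velocity(st_second_moment(static, c(23.5, 23.5, 13),
                                            3, 1.5))
  expect_equal(ve0$v, c(0, 0), tolerance = 1e-10)
  seqv <- fixture_translating_sequence(c(0.5, 0.25), 25, t0 = 8, size = 56)
  p <- c(27.5 + 0.5 * 12, 27.5 + 0.25 * 12, 13)
  ve <- estimate_velocity(st_second_moment(seqv, p, 3, 1.5))
  expect_lt(max(abs(ve$v - c(0.5, 0.25))), 0.05)
  expect_lt(ve$diag_residual, 0.02)
  # aperture problem: a grating moving along its normal has a rank-one
  # spatial block
  gr <- translating_grating(0.5, 25, size = 48, wavelength = 8)
  expect_error(estimate_velocity(st_second_moment(gr, c(23, 23, 13),
                                                  3, 1.5)),
               "aperture")
})

test_that("Galilean diagonalization zeroes the mixed entries at the
           estimated velocity and is additive under pre-warps", {
  seqv <- fixture_translating_sequence(c(0.5, 0), 25, t0 = 8, size = 56)
  p <- c(27.5 + 0.5 * 12, 27.5, 13)
  mu <- st_second_moment(seqv, p, 3, 1.5)
  ve <- estimate_velocity(mu)
  Md <- galilean_diagonalize(mu, ve$v)
  expect_lt(max(abs(Md[1:2, 3])), 1e-6 * sum(diag(Md)))
  expect_identical(galilean_diagonalize(mu, c(0, 0)), mu$mu)
  # additivity: stabilizing by -u adds u to the estimated velocity
  u <- c(0.5, 0.25)
  seq2 <- velocity_stabilize(seqv, -u, t_ref = 1)
  p2 <- c(27.5 + (0.5 + u[1]) * 12, 27.5 + u[2] * 12, 13)
  ve2 <- estimate_velocity(st_second_moment(seq2, p2, 3, 1.5))
  expect_lt(max(abs(ve2$v - (c(0.5, 0) + u))), 0.05)
})

test_that("velocity stabilization makes a translating pattern static and
           the wrong velocity leaves a larger residual", {
  v <- c(1, 0)
  seqv <- fixture_translating_sequence(v, 17, t0 = 8, size = 56)
  expect_equal(unclass(velocity_stabilize(seqv, c(0, 0))),
               unclass(seqv), ignore_attr = TRUE)
  stab <- velocity_stabilize(seqv, v, t_ref = 9)
  raw <- unclass(stab)
  rng <- diff(range(raw))
  rms <- function(arr) {
    d <- arr[-1, 10:46, 10:46] - arr[-dim(arr)[1], 10:46, 10:46]
    sqrt(mean(d^2))
  }
  expect_lt(rms(raw) / rng, 0.02)
  wrong <- unclass(velocity_stabilize(seqv, 2 * v, t_ref = 9))
  expect_gt(rms(wrong), rms(raw))
  expect_error(velocity_stabilize(seqv, c(60, 0)), "bounds")
})

test_that("velocity recovery is accurate on the full velocity grid with
           additivity and the stabilization contrast", {
  res <- check_velocity()
  expect_lt(res$max_abs_err, 0.05)
  expect_lt(res$additivity_err, 0.05)
  expect_lt(res$stabilized_rel_l2, 0.05)
  expect_gt(res$unstabilized_rel_l2, 0.15)
})
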