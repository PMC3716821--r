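# shared helpers for kernel tests

# kernel/image values with all attributes but dim stripped
taps <- function(k) {
  m <- unclass(as.matrix(k))
  attributes(m) <- list(dim = dim(m))
  m
}

# value of the central tap
center_tap <- function(k) {
  r <- attr(k, "support_radius")
  unclass(k)[r[1] + 1, r[2] + 1]
}

# zero-pad a kernel matrix to the target half-width
pad_kernel_to <- function(k, r_target) {
  m <- unclass(as.matrix(k))
  r <- c((nrow(m) - 1) / 2, (ncol(m) - 1) / 2)
  visrf:::pad_matrix(m, r_target[1] - r[1], r_target[2] - r[2], "constant")
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)

# analytic translating grating sequence: frame k shows the grating shifted
# by v * (k - 1) px along its normal, rendered exactly via the phase
translating_grating <- function(v, n_frames, size = 48, wavelength = 8) {
  frames <- array(0, c(n_frames, size, size))
  for (k in seq_len(n_frames))
    frames[k, , ] <- unclass(fixture_grating(wavelength, size,
                                             phase = -2 * pi * v *
                                               (k - 1) / wavelength))
  image_sequence(frames)
}
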