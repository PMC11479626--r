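# Shared small-scale optical models used across test files. Paper pitches
# (dx 38.5 nm, dz 87.5 nm), NA 0.8, in-medium wavelength 530/1.3 nm.

test_grid32 <- grid_geometry(32, 32, 8, dx = 38.5, dz = 87.5)
test_grid64 <- grid_geometry(64, 64, 1, dx = 38.5, dz = 87.5)

test_pupil32 <- make_pupil(0.8, 530 / 1.3, test_grid32)
test_pupil64 <- make_pupil(0.8, 530 / 1.3, test_grid64)

test_psf32 <- compute_psf3d(test_pupil32, test_grid32)
test_edf32 <- compute_edf_psf(test_psf32)
test_edf64 <- compute_edf_psf(compute_psf3d(test_pupil64, test_grid64))

# centered index of the origin pixel
ctr <- function(n) floor(n / 2) + 1L

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

fft2_tf <- function(centered) edfrim:::fft2(edfrim:::ifftshift2(centered))

# smooth separable ramp used by the topography tests
eval_ramp <- function(dims) {
  gx <- 1 + 0.5 * seq(0, 1, length.out = dims[1])
  gy <- 1 + 0.3 * seq(0, 1, length.out = dims[2])
  gz <- 1 + 0.4 * seq(0, 1, length.out = dims[3])
  200 * outer(outer(gx, gy), gz)
}
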