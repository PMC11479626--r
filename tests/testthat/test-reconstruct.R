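# Wiener filtering, variance model, optimizer, baseline, background removal.

test_that("wiener filter limits and closed-form kernel", {
  g <- test_grid64
  # identity PSF (delta): OTF = 1 everywhere, eta -> 0 recovers the input
  delta <- matrix(0, 64, 64); delta[ctr(64), ctr(64)] <- 1
  psf_id <- structure(list(values = delta, otf = fft2_tf(delta),
                           pupil = NULL, grid = g), class = "edf_psf")
  set.seed(1)
  img <- matrix(runif(64 * 64), 64)
  expect_equal(wiener_filter(img, psf_id, 1e-12), img, tolerance = 1e-8)
  # eta -> infinity kills the output
  expect_lt(max(abs(wiener_filter(img, test_edf64, 1e12))), 1e-10)
  expect_error(make_wiener(test_edf64, 0), "eta")
  # delta input returns the real-space kernel of g; its spectrum is
  # h / (h^2 + eta) for the real symmetric EDF OTF
  flt <- make_wiener(test_edf64, 1e-3)
  out <- wiener_filter(delta, flt)
  h <- Re(test_edf64$otf)
  expect_equal(Re(edfrim:::fft2(edfrim:::ifftshift2(out))), h / (h^2 + 1e-3),
               tolerance = 1e-8)
  # AM-GM bound |g| <= 1 / (2 sqrt(eta))
  expect_lte(max(Mod(flt$transfer)), 1 / (2 * sqrt(1e-3)) + 1e-12)
  # output spectrum beyond the incoherent cutoff is suppressed
  sp <- Mod(edfrim:::fft2(wiener_filter(img, flt)))
  p <- test_pupil64
  expect_lt(max(sp[p$f2 > (2 * p$cutoff * 1.02)^2]),
            1e-4 * max(sp[p$f2 <= (2 * p$cutoff)^2]))
})

test_that("empirical standard deviation uses the population convention", {
  imgs <- array(0, dim = c(4, 4, 2))
  imgs[, , 2] <- 2
  expect_equal(empirical_std(imgs), matrix(1, 4, 4)) # population: divide by N
  same <- array(3, dim = c(4, 4, 5))
  expect_equal(empirical_std(same), matrix(0, 4, 4))
  expect_error(empirical_std(array(0, dim = c(4, 4, 1))), "2 images")
})

test_that("variance model: linearity, white-speckle collapse, oracle match", {
  g <- test_grid64
  flt <- make_wiener(test_edf64, 1e-3)
  gam <- speckle_autocov_model(test_pupil64, g)
  star <- make_star_density(g, 40)
  s1 <- model_std(star, gam, flt)
  expect_equal(model_std(2.5 * star, gam, flt), 2.5 * s1, tolerance = 1e-10)
  # white speckle + point density: sigma^2 proportional to h_eff^2(r - r0)
  delta_gam <- matrix(0, 64, 64); delta_gam[ctr(64), ctr(64)] <- 1
  rho <- matrix(0, 64, 64); rho[20, 45] <- 1
  s2 <- model_std(rho, delta_gam, flt)^2
  href <- flt$effective_psf
  # h_eff^2 re-centered on the point source at (20, 45)
  shifted <- href[((seq_len(64) - 20 + ctr(64) - 1) %% 64) + 1,
                  ((seq_len(64) - 45 + ctr(64) - 1) %% 64) + 1]
  expect_lt(rel_l2(s2 / max(s2), shifted^2 / max(shifted^2)), 1e-8)
  # invalid covariance (substantially negative spectrum) is rejected
  bad <- -gam
  expect_error(model_std(star, bad, flt), "covariance")
  # Monte-Carlo oracle agreement at moderate n (acceptance re-runs at 1000)
  s_mc <- variance_oracle(star, test_pupil64, n_speckles = 400, seed = 8)
  bright <- s1 > 0.1 * max(s1)
  expect_lt(sqrt(mean((s_mc[bright] - s1[bright])^2)) /
            sqrt(mean(s1[bright]^2)), 0.08)
})

test_that("variance oracle basics: zero density, linear amplitude, 1/sqrt(n)", {
  g <- grid_geometry(32, 32, 1, dx = 38.5)
  p <- make_pupil(0.8, 530 / 1.3, g)
  zero <- matrix(0, 32, 32)
  expect_equal(max(variance_oracle(zero, p, 100, seed = 1)), 0)
  star <- make_star_density(g, 8)
  a <- variance_oracle(star, p, 200, seed = 3)
  b <- variance_oracle(2 * star, p, 200, seed = 3)
  expect_equal(b, 2 * a, tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  g <- grid_geometry(16, 16, 1, dx = 38.5)
  p <- make_pupil(0.8, 530 / 1.3, g)
  flt <- make_wiener(compute_edf_psf(compute_psf3d(p, g)), 1e-3)
  gam <- speckle_autocov_model(p, g)
  md <- edfrim:::gamma_modes(gam, 1e-6)
  H <- flt$effective_otf + 0i
  kx <- as.integer(md$kx); ky <- as.integer(md$ky)
  set.seed(4)
  rho <- matrix(runif(256), 16)
  sh <- matrix(runif(256), 16)
  obj <- function(r) {
    s <- sqrt(pmax(edfrim:::rim_sigma2_cpp(r, H, kx, ky, md$P, md$weight), 0))
    sum((sh - s)^2)
  }
  sig <- sqrt(pmax(edfrim:::rim_sigma2_cpp(rho, H, kx, ky, md$P, md$weight), 0))
  W <- (sig - sh) / pmax(sig, 1e-12)
  gr <- edfrim:::rim_grad_cpp(rho, W, H, kx, ky, md$P, md$weight)
  h <- 1e-6
  idx <- cbind(c(1, 5, 9, 16, 3, 12), c(1, 7, 16, 2, 14, 12))
  for (r in seq_len(nrow(idx))) {
    rp <- rho; rp[idx[r, 1], idx[r, 2]] <- rp[idx[r, 1], idx[r, 2]] + h
    rm <- rho; rm[idx[r, 1], idx[r, 2]] <- rm[idx[r, 1], idx[r, 2]] - h
    num <- (obj(rp) - obj(rm)) / (2 * h)
    expect_equal(gr[idx[r, 1], idx[r, 2]], num, tolerance = 1e-4)
  }
})

test_that("rim_fit: monotone objective, Tikhonov limit, nonnegativity", {
  g <- grid_geometry(32, 32, 1, dx = 38.5)
  p <- make_pupil(0.8, 530 / 1.3, g)
  flt <- make_wiener(compute_edf_psf(compute_psf3d(p, g)), 1e-3)
  gam <- speckle_autocov_model(p, g)
  star <- make_star_density(g, 8)
  sig <- model_std(star, gam, flt)
  fit <- rim_fit(sig, gam, flt, mu = 1e-5, max_iters = 40)
  expect_true(all(diff(fit$objective) <= 1e-12))
  expect_true(all(fit$rho >= 0))
  # huge mu drives the solution to zero
  fit0 <- rim_fit(sig, gam, flt, mu = 1e9, max_iters = 40)
  expect_lt(max(fit0$rho), 1e-3 * max(fit$rho))
})

test_that("deconvolved widefield baseline and gamma support matching", {
  g <- test_grid64
  star <- make_star_density(g, 40)
  imgs <- array(0, dim = c(64, 64, 3))
  clean <- edfrim:::conv2_tf(star, test_edf64$otf)
  for (k in 1:3) imgs[, , k] <- clean
  stack <- speckle_stack(imgs, modality = "edf", grid = g,
                         optics = list(na = 0.8, wavelength_nm = 530 / 1.3,
                                       kind = "disc"))
  dec <- deconvolve_widefield(stack, test_edf64)
  # identical images: same as filtering one image at the baseline eta
  expect_equal(dec, wiener_filter(clean, test_edf64, 2e-4), tolerance = 1e-10)
  # support matching masks model power where the measured spectrum is empty
  gam <- speckle_autocov_model(test_pupil64, g)
  gm <- match_gamma_support(gam, gam)
  expect_equal(gm, gam, tolerance = 1e-10)
  narrow <- matrix(0, 64, 64); narrow[ctr(64), ctr(64)] <- 1 # white: full support
  expect_equal(match_gamma_support(gam, narrow), gam, tolerance = 1e-10)
})

test_that("rolling-ball background removal preserves narrow peaks", {
  const <- matrix(5, 40, 40)
  expect_lt(max(abs(rolling_ball_background(const, 8))), 1e-10)
  img <- matrix(0, 40, 40)
  img[20, 20] <- 10 # isolated peak, much narrower than the ball
  out <- rolling_ball_background(img, 10)
  expect_equal(out[20, 20], 10, tolerance = 0.01 * 10)
  # constant offsets are absorbed into the background
  out2 <- rolling_ball_background(img + 3, 10)
  expect_equal(out2, out, tolerance = 1e-10)
})
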