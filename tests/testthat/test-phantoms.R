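# Star phantom, topographies, surface embedding and the forward model.

test_that("star density evaluates 1 + cos(n theta) with the stated geometry", {
  g <- grid_geometry(64, 64, 1, dx = 38.5)
  s <- make_star_density(g, 40)
  expect_true(all(s >= 0 & s <= 2))
  # theta = 0 ray (positive x axis from the center): density = 2
  expect_equal(s[(ctr(64) + 1):64, ctr(64)], rep(2, 64 - ctr(64)),
               tolerance = 1e-12)
  # theta = pi/40 ray: density = 0; check via direct evaluation off-grid
  x <- edfrim:::centered_coords(64, 38.5)
  th <- atan2(outer(rep(1, 64), x), outer(x, rep(1, 64)))
  expect_equal(s, 1 + cos(40 * th), tolerance = 1e-12)
  # rotation by one period maps the pattern onto itself (grid-exact at 90 deg
  # multiples; use the analytic form for the 2 pi / 40 rotation)
  expect_equal(1 + cos(40 * (th + 2 * pi / 40)), s, tolerance = 1e-12)
  expect_error(make_star_density(g, 39), "even")
})

test_that("topographies follow the stated shapes", {
  g <- grid_geometry(64, 64, 32, dx = 38.5, dz = 87.5)
  flat <- make_topography(g, "flat")
  expect_equal(max(flat) - min(flat), 0)
  cone <- make_topography(g, "cone")
  expect_equal(cone[ctr(64), ctr(64)], 32 * 87.5, tolerance = 1e-12)
  # paper grid numbers: apex = Nz dz = 128 * 87.5 = 11200 nm
  gp <- grid_paper()
  expect_equal(make_topography(gp, "cone")[ctr(512), ctr(512)], 11200)
  # height decreases with radius, base level outside Nx/2 dx
  mid <- ctr(64)
  prof <- cone[mid:64, mid]
  expect_true(all(diff(prof) <= 1e-9))
  expect_equal(cone[1, 1], 0) # corner is beyond the cone radius
  # random: i.i.d. uniform over the z range, uncorrelated neighbors
  rnd <- make_topography(grid_geometry(512, 512, 128, dx = 38.5, dz = 87.5),
                         "random", seed = 4)
  zmax <- 128 * 87.5
  se <- zmax / sqrt(12) / sqrt(length(rnd))
  expect_lt(abs(mean(rnd) - zmax / 2), 3 * se)
  lag1 <- cor(as.vector(rnd[-1, ]), as.vector(rnd[-512, ]))
  expect_lt(abs(lag1), 0.02)
  expect_error(make_topography(g, "random"), "seed")
})

test_that("surface embedding conserves the projection exactly", {
  g <- test_grid32
  star <- make_star_density(g, 8)
  for (kind in c("flat", "cone", "random")) {
    z <- make_topography(g, kind, seed = 2)
    sv <- embed_on_surface(star, z, g)
    expect_equal(rowSums(sv$density3d, dims = 2), star, tolerance = 1e-12)
    # one nonzero slice per column
    occ <- apply(sv$density3d > 0, c(1, 2), sum)
    expect_true(all(occ[star > 0] == 1))
  }
  # flat at a known slice: all mass in that slice
  zf <- matrix(3 * g$dz, g$nx, g$ny)
  sv <- embed_on_surface(star, zf, g)
  expect_equal(sv$density3d[, , 4], star)
  expect_equal(sum(sv$density3d[, , -4]), 0)
  # cone: occupied slice index non-increasing with radius
  svc <- embed_on_surface(star + 1, make_topography(g, "cone"), g)
  prof <- svc$slice_index[ctr(32):32, ctr(32)]
  expect_true(all(diff(prof) <= 0))
  expect_error(embed_on_surface(star, zf + 100 * g$dz, g), "z-range")
})

test_that("form_image matches a direct triple-loop oracle on a small grid", {
  g <- grid_geometry(16, 16, 4, dx = 38.5, dz = 87.5)
  p <- make_pupil(0.8, 530 / 1.3, g)
  psf <- compute_psf3d(p, g)
  set.seed(7)
  dens3 <- array(runif(16 * 16 * 4), dim = c(16, 16, 4))
  spk <- array(runif(16 * 16 * 4, 0.5, 1.5), dim = c(16, 16, 4))
  z_bottom <- edfrim:::grid_z_offsets(g)[1]
  z_f <- 2 * g$dz # height above bottom slice
  got <- form_image(dens3, spk, psf, z_f)
  # independent oracle: direct sum over source voxels with circular wrap
  oracle <- matrix(0, 16, 16)
  for (k in 1:4) {
    h <- edfrim:::psf_slice_at(psf, z_f - (k - 1) * g$dz)
    src <- dens3[, , k] * spk[, , k]
    for (i in 1:16) for (j in 1:16) {
      if (src[i, j] == 0) next
      di <- ((seq_len(16) - i + 8) %% 16) + 1 # displacement + center index
      dj <- ((seq_len(16) - j + 8) %% 16) + 1
      oracle <- oracle + src[i, j] * h[di, dj]
    }
  }
  expect_lt(max(abs(got - oracle)) / max(oracle), 1e-8)
  # linearity in the density
  expect_equal(form_image(2 * dens3, spk, psf, z_f), 2 * got, tolerance = 1e-12)
})

test_that("EDF image equals the z_f sum and the projected convolution", {
  g <- test_grid32
  p <- test_pupil32
  psf <- test_psf32
  edf <- test_edf32
  star <- make_star_density(g, 8)
  sv <- embed_on_surface(star, matrix(3 * g$dz, 32, 32), g)
  spk <- generate_speckle(p, g, seed = 21)
  got <- form_edf_image(sv, spk, edf)
  # sum of form_image over focal planes placed at (object slice + psf offsets)
  z_obj <- 3 * g$dz
  summed <- matrix(0, 32, 32)
  for (u in psf$z_offsets) summed <- summed + form_image(sv, spk, psf, z_obj + u)
  expect_equal(summed, got, tolerance = 1e-10)
  # uniform illumination: EDF image is rho_perp convolved with h_perp
  uni <- form_edf_image(sv, 1, edf)
  expect_equal(uni, edfrim:::conv2_tf(star, edf$otf), tolerance = 1e-12)
  # linearity in the density
  sv2 <- embed_on_surface(2 * star, matrix(3 * g$dz, 32, 32), g)
  expect_equal(form_edf_image(sv2, spk, edf), 2 * got, tolerance = 1e-10)
  # axial shift invariance: moving the flat sample by one interior slice
  # leaves the EDF image unchanged (h_perp is z-independent)
  sv_up <- embed_on_surface(star, matrix(4 * g$dz, 32, 32), g)
  expect_lt(rel_l2(form_edf_image(sv_up, 1, edf), uni), 0.01)
})

test_that("simulated acquisitions are seeded, mean-calibrated, Poisson-limited", {
  g <- grid_geometry(32, 32, 4, dx = 38.5, dz = 87.5)
  p <- make_pupil(0.8, 530 / 1.3, g)
  star <- make_star_density(g, 8)
  sv <- embed_on_surface(star, make_topography(g, "flat"), g)
  s1 <- simulate_acquisition(sv, p, n_speckles = 4, photon_budget = 500, seed = 3)
  s2 <- simulate_acquisition(sv, p, n_speckles = 4, photon_budget = 500, seed = 3)
  expect_identical(s1$images, s2$images)
  expect_equal(s1$n, 4L)
  expect_error(simulate_acquisition(sv, p, n_speckles = 4, photon_budget = -1),
               "photon_budget")
  # averaging many noiseless speckled images converges to the
  # uniform-illumination (widefield) image: <S> = 1
  uni <- embed_on_surface(matrix(1, 32, 32), make_topography(g, "flat"), g)
  stack <- simulate_acquisition(uni, p, n_speckles = 500, photon_budget = Inf,
                                seed = 11)
  m <- rowMeans(stack$images, dims = 2)
  edf <- compute_edf_psf(compute_psf3d(p, g))
  mean_img <- edfrim:::conv2_tf(uni$density2d, edf$otf) * stack$scale
  expect_lt(rel_l2(m, mean_img), 0.05)
  # with the speckle disabled, temporal variance/mean is pure Poisson: 1 +- 0.1
  su <- simulate_acquisition(uni, p, n_speckles = 250, photon_budget = 800,
                             seed = 12, illumination = "uniform")
  mm <- apply(su$images, c(1, 2), mean)
  vv <- apply(su$images, c(1, 2), var)
  bright <- mm > 0.5 * max(mm)
  expect_equal(mean(vv[bright] / mm[bright]), 1, tolerance = 0.1)
})
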