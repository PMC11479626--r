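# Background normalization, bright-point detection, RANSAC surface fitting,
# spline interpolation and mesh projection.

test_that("background fit recovers constants, ramps, and the noise scale", {
  const <- array(7, dim = c(24, 24, 8))
  bf <- estimate_background(const, fraction = 0.2, seed = 1)
  expect_equal(mean(bf$a), 7, tolerance = 0.01)
  expect_lt(bf$sigma0, 0.02)
  expect_error(estimate_background(array(0, dim = c(8, 8, 4))), "zero")
  # smooth gain ramp x multiplicative Gaussian noise (CV 0.1)
  dims <- c(40, 40, 12)
  ramp <- eval_ramp(dims)
  set.seed(2)
  vol <- ramp * (1 + 0.1 * array(rnorm(prod(dims)), dim = dims))
  bf2 <- estimate_background(vol, fraction = 0.1, seed = 3)
  expect_lt(sqrt(mean((bf2$a - ramp)^2)) / sqrt(mean(ramp^2)), 0.03)
  expect_equal(bf2$sigma0, 0.10, tolerance = 0.02)
  # two different subsample seeds agree
  bf3 <- estimate_background(vol, fraction = 0.1, seed = 99)
  expect_lt(sqrt(mean((bf2$a - bf3$a)^2)) / sqrt(mean(ramp^2)), 0.02)
})

test_that("normalized signal is standard-normal on background, large on signal", {
  dims <- c(40, 40, 12)
  ramp <- eval_ramp(dims)
  set.seed(5)
  vol <- ramp * (1 + 0.1 * array(rnorm(prod(dims)), dim = dims))
  # s = a exactly: r-hat vanishes
  bf <- estimate_background(vol, fraction = 0.1, seed = 1)
  nv0 <- normalize_volume(ramp, bf)
  # s = a_hat up to the gain-fit error: r-hat stays well below the threshold
  expect_lt(quantile(abs(nv0$values), 0.99, na.rm = TRUE), 1)
  nv <- normalize_volume(vol, bf)
  expect_lt(abs(mean(nv$values)), 0.05)
  expect_equal(sd(as.vector(nv$values)), 1, tolerance = 0.1)
  # planted bright voxels 10 sigma above background stand out
  vol2 <- vol
  vol2[10, 10, 5] <- ramp[10, 10, 5] * (1 + 10 * 0.1)
  nv2 <- normalize_volume(vol2, bf)
  expect_gt(nv2$values[10, 10, 5], 5)
})

test_that("false-alarm thresholding is calibrated", {
  expect_equal(qnorm(1 - 0.01), 2.3263, tolerance = 1e-4)
  set.seed(6)
  dims <- c(100, 100, 100) # 1e6 voxels of pure N(0, 1)
  nv <- structure(list(values = array(rnorm(prod(dims)), dim = dims),
                       z_planes = seq_len(dims[3]), dx = 1, dy = 1),
                  class = "normalized_volume")
  pts <- detect_bright_points(nv, pfa = 0.01)
  expect_equal(nrow(pts) / prod(dims), 0.01, tolerance = 0.1) # +- 0.001
  # pfa = 0.5 thresholds at the median
  pts5 <- detect_bright_points(nv, pfa = 0.499999)
  expect_equal(nrow(pts5) / prod(dims), 0.5, tolerance = 0.01)
  expect_error(detect_bright_points(nv, pfa = 0.7), "pfa")
  # empty detections are allowed
  nv$values[] <- 0
  expect_equal(nrow(detect_bright_points(nv, 0.01)), 0)
})

test_that("RANSAC recovers exact quadratics and rejects planted outliers", {
  set.seed(7)
  n <- 400
  x <- runif(n, 0, 4000); y <- runif(n, 0, 4000)
  zq <- 100 + 0.05 * x + 0.02 * y + 1e-5 * x^2 - 2e-5 * x * y + 3e-5 * y^2
  pts <- data.frame(x_nm = x, y_nm = y, z_nm = zq)
  fit <- fit_surface_ransac(pts, 2, 2, inlier_tol = 5, seed = 1)
  expect_true(all(fit$inlier)) # noiseless consensus
  # planted outliers: a cone surface (desk proportions, slope shallow enough
  # for the quadratic window model) plus 40% junk uniform over the full
  # acquisition z-range
  nc <- 1200
  xc <- runif(nc, 0, 20000); yc <- runif(nc, 0, 20000)
  zc <- 2800 * pmax(1 - sqrt((xc - 10000)^2 + (yc - 10000)^2) / 10000, 0)
  is_out <- seq_len(nc) <= 0.4 * nc
  z_all <- ifelse(is_out, runif(nc, 0, 11200), zc)
  # outliers that accidentally sit on the surface stay indistinguishable
  truly_out <- is_out & abs(z_all - zc) > 3 * 175
  ptsc <- data.frame(x_nm = xc, y_nm = yc, z_nm = z_all)
  fitc <- fit_surface_ransac(ptsc, 5, 5, inlier_tol = 175, iters = 300, seed = 2)
  surface_pts <- !is_out
  expect_gt(mean(fitc$inlier[surface_pts]), 0.95)
  expect_lt(mean(fitc$inlier[truly_out]), 0.05)
  # label order invariance under point shuffling
  perm <- sample(nc)
  fitp <- fit_surface_ransac(ptsc[perm, ], 5, 5, inlier_tol = 175,
                             iters = 300, seed = 2)
  expect_identical(fitp$inlier, fitc$inlier[perm])
})

test_that("spline interpolation reproduces planes and interpolates inliers", {
  g <- grid_geometry(32, 32, 1, dx = 100, dy = 100)
  set.seed(8)
  x <- runif(40, 0, 3100); y <- runif(40, 0, 3100)
  z <- 50 + 0.1 * x - 0.03 * y
  est <- interpolate_surface(data.frame(x_nm = x, y_nm = y, z_nm = z), g)
  gx <- (seq_len(32) - 1) * 100
  truth <- outer(50 + 0.1 * gx, -0.03 * gx, `+`)
  expect_lt(max(abs(est$z_grid - truth)), 1e-6)
  # exact interpolation at inlier positions for curved data: put the points
  # on grid nodes and read the spline back there
  ix <- sample(2:31, 30); iy <- sample(2:31, 30)
  xk <- (ix - 1) * 100; yk <- (iy - 1) * 100
  zk <- 50 + 0.1 * xk - 0.03 * yk + 1e-5 * xk^2 + 2e-5 * xk * yk
  est2 <- interpolate_surface(data.frame(x_nm = xk, y_nm = yk, z_nm = zk), g)
  expect_equal(est2$z_grid[cbind(ix, iy)], zk, tolerance = 1e-6)
  expect_error(interpolate_surface(
    data.frame(x_nm = c(0, 1, 2), y_nm = c(0, 1, 2), z_nm = 1:3), g),
    "collinear")
})

test_that("exact in-focus ring samples of the cone interpolate below d_z", {
  # the reference cone sampled where it crosses planes spaced 2 um apart:
  # each plane contributes a circle of exact (x, y, z) samples; the spline
  # through them recovers the surface to better than the axial voxel pitch
  g <- grid_geometry(128, 128, 1, dx = 154)
  radius <- (g$nx / 2) * g$dx; height <- 11200
  cx <- floor(g$nx / 2) * g$dx
  pts <- list()
  for (zp in seq(0, 10000, by = 2000)) {
    rr <- radius * (1 - zp / height)
    th <- seq(0, 2 * pi, length.out = 121)[-121]
    pts[[length(pts) + 1L]] <-
      data.frame(x_nm = cx + rr * cos(th), y_nm = cx + rr * sin(th), z_nm = zp)
  }
  # plus base-plane samples outside the cone radius
  set.seed(3)
  xb <- runif(150, 0, (g$nx - 1) * g$dx); yb <- runif(150, 0, (g$nx - 1) * g$dx)
  rb <- sqrt((xb - cx)^2 + (yb - cx)^2)
  keep <- rb > radius
  pts[[length(pts) + 1L]] <- data.frame(x_nm = xb[keep], y_nm = yb[keep], z_nm = 0)
  pts <- do.call(rbind, pts)
  est <- interpolate_surface(pts, g, lambda = 0)
  truth <- make_topography(grid_geometry(128, 128, 128, dx = 154, dz = 87.5),
                           "cone")
  err <- (est$z_grid - truth)[est$mask]
  expect_lt(sqrt(mean(err^2)), 87.5)
})

test_that("meshes conserve intensity and follow the surface", {
  img <- matrix(runif(64), 8, 8)
  zflat <- matrix(500, 8, 8)
  mesh <- project_onto_surface(img, zflat, dx = 100, dy = 100)
  expect_equal(mesh$vertices$intensity, as.vector(img)) # bitwise pass-through
  expect_equal(sum(mesh$vertices$intensity), sum(img))
  expect_true(all(mesh$vertices$z_nm == 500))
  expect_error(project_onto_surface(img, matrix(0, 4, 4)), "lateral grid")
  f <- tempfile(fileext = ".obj")
  write_obj(mesh, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "v ")), 64)
  expect_equal(sum(startsWith(lines, "f ")), 2 * 7 * 7)
})
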