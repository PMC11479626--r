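# Robust surface-topography estimation from one plane-by-plane speckled scan.
#
# Pipeline: normalize the raw volume against a smooth background gain field
# fitted on a tiny random voxel subsample (Eq.-style r-hat statistic), detect
# bright voxels by a probability-of-false-alarm threshold on the normalized
# signal, classify surface inliers with windowed quadratic RANSAC fits, fuse
# the per-window labels, and interpolate the inliers with a biharmonic
# (thin-plate) spline to obtain the height map Z_s(x, y).

#' Estimate the background gain field of a volume
#'
#' Fits a smooth separable polynomial (degree <= 2 per axis, full tensor
#' basis) to a small random fraction of the voxels by trimmed least squares;
#' the trimming discards the bright-structure voxels so the fit tracks the
#' background. Also returns the robust spread of `s / a_hat` over the
#' subsample (a trimmed, Gaussian-consistent standard deviation).
#'
#' @param volume a [simulate_volume_scan()] object or a 3D array
#' @param fraction fraction of voxels sampled (default 1/1000)
#' @param seed integer seed for the voxel subsample
#' @param degree polynomial degree per axis (<= 2 is plenty for slow gain)
#' @param trim fraction of largest residuals discarded per trimming round
#' @param sigma_sample voxel count for the scalar noise-scale estimate. The
#'   subsample `fraction` exists to make the 3D gain *fit* cheap; the 1D
#'   spread of `s / a_hat` costs nothing to evaluate on more voxels, and a
#'   larger sample keeps the false-alarm threshold calibrated to a fraction
#'   of a percent
#' @return an object of class `background_fit`: `a` (3D gain array),
#'   `sigma0`, the fitted `coefficients`, and the subsample index
#' @export
estimate_background <- function(volume, fraction = 1 / 1000, seed = 1L,
                                degree = 2L, trim = 0.2, sigma_sample = 1e5) {
  vals <- volume_values(volume)
  stopifnot(fraction > 0, fraction <= 1)
  if (!any(vals > 0)) stop("volume is identically zero; cannot fit a background")
  dims <- dim(vals)
  n <- prod(dims)
  n_s <- max(ceiling(n * fraction), 20 * (degree + 1)^3)
  set.seed(as.integer(seed))
  idx <- sample.int(n, min(n_s, n))
  s <- as.double(vals[idx])
  arr <- arrayInd(idx, dims)
  X <- poly_basis3(arr, dims, degree)

  keep <- seq_along(s)
  for (round in 1:4) {
    fit <- lm.fit(X[keep, , drop = FALSE], s[keep])
    res <- abs(s - X %*% fit$coefficients)
    n_keep <- max(ceiling(length(s) * (1 - trim)), ncol(X) + 1)
    keep <- order(res)[seq_len(n_keep)]
  }
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0

  a <- eval_poly3(beta, dims, degree)
  # spread of s / a_hat on an enlarged sample (not the trimmed-LS subset,
  # which would bias the spread down); the trimmed sd rejects the
  # bright-structure tail
  n_sig <- min(n, max(sigma_sample, length(idx)))
  idx_s <- if (n_sig >= n) seq_len(n) else sample.int(n, n_sig)
  Xs <- poly_basis3(arrayInd(idx_s, dims), dims, degree)
  ratio <- as.double(vals[idx_s]) /
    pmax(as.vector(Xs %*% beta), .Machine$double.eps)
  # center the empirical null: the gain fit carries an O(1/sqrt(n_fit))
  # global offset that would shift the whole r-hat distribution and
  # mis-calibrate the false-alarm rate
  m_hat <- trimmed_mean(ratio, 0.1)
  beta <- beta * m_hat
  a <- a * m_hat
  sigma0 <- trimmed_sd(ratio / m_hat, 0.1)
  structure(list(a = a, sigma0 = sigma0, coefficients = beta,
                 degree = degree, subsample = idx, kept = idx[keep]),
            class = "background_fit")
}

volume_values <- function(volume) {
  if (inherits(volume, "topo_volume")) volume$values
  else if (inherits(volume, "normalized_volume")) volume$values
  else { stopifnot(length(dim(volume)) == 3L); volume }
}

# tensor polynomial basis at voxel indices (rows of arr), axes scaled to [-1, 1]
poly_basis3 <- function(arr, dims, degree) {
  sc <- function(i, n) if (n > 1) 2 * (i - 1) / (n - 1) - 1 else rep(0, length(i))
  x <- sc(arr[, 1], dims[1]); y <- sc(arr[, 2], dims[2]); z <- sc(arr[, 3], dims[3])
  cols <- list()
  for (i in 0:degree) for (j in 0:degree) for (k in 0:degree)
    cols[[length(cols) + 1L]] <- x^i * y^j * z^k
  do.call(cbind, cols)
}

# evaluate the tensor polynomial over the whole grid, using separability
eval_poly3 <- function(beta, dims, degree) {
  sc <- function(n) if (n > 1) 2 * (seq_len(n) - 1) / (n - 1) - 1 else 0
  x <- sc(dims[1]); y <- sc(dims[2]); z <- sc(dims[3])
  a <- array(0, dim = dims)
  b <- 0L
  for (i in 0:degree) for (j in 0:degree) for (k in 0:degree) {
    b <- b + 1L
    if (beta[b] == 0) next
    a <- a + beta[b] * outer(outer(x^i, y^j), z^k)
  }
  a
}

trimmed_mean <- function(x, trim = 0.1) {
  q <- quantile(x, c(trim, 1 - trim), names = FALSE, type = 7)
  mean(x[x >= q[1] & x <= q[2]])
}

# Gaussian-consistent standard deviation of the central (1 - 2 trim) mass
trimmed_sd <- function(x, trim = 0.1) {
  q <- quantile(x, c(trim, 1 - trim), names = FALSE, type = 7)
  core <- x[x >= q[1] & x <= q[2]]
  z <- qnorm(1 - trim)
  corr <- sqrt(1 - 2 * z * stats::dnorm(z) / (1 - 2 * trim))
  sd(core) / corr
}

#' Normalize a volume against its background
#'
#' Computes `r_hat = (s - a) / (a * sigma0)` voxelwise; where the gain
#' estimate is not positive the result is masked (`NA`). On pure background
#' the statistic is approximately standard normal, which is what makes a
#' false-alarm threshold meaningful.
#'
#' @param volume a [simulate_volume_scan()] object or 3D array
#' @param background a [estimate_background()] fit (computed when `NULL`)
#' @param ... passed to [estimate_background()]
#' @return an object of class `normalized_volume`: `values` (r-hat),
#'   `background`, and the geometry carried over from `volume`
#' @export
normalize_volume <- function(volume, background = NULL, ...) {
  vals <- volume_values(volume)
  if (is.null(background)) background <- estimate_background(volume, ...)
  a <- background$a
  r <- (vals - a) / (a * background$sigma0)
  r[a <= 0] <- NA_real_
  structure(list(values = r, background = background,
                 z_planes = if (inherits(volume, "topo_volume")) volume$z_planes else NULL,
                 dx = if (inherits(volume, "topo_volume")) volume$dx else 1,
                 dy = if (inherits(volume, "topo_volume")) volume$dy else 1),
            class = "normalized_volume")
}

#' Detect bright points by probability of false alarm
#'
#' Thresholds the normalized volume at the upper-`pfa` quantile of the
#' standard normal (`qnorm(1 - pfa)`; 2.3263 at the default 0.01) and
#' returns the voxels above it as a point cloud in physical units.
#'
#' @param normalized a [normalize_volume()] object
#' @param pfa probability of false alarm, in (0, 0.5)
#' @return data.frame with columns `x_nm`, `y_nm`, `z_nm`, `rhat`, and the
#'   voxel indices `ix`, `iy`, `iz` (possibly zero rows)
#' @export
detect_bright_points <- function(normalized, pfa = 0.01) {
  stopifnot(inherits(normalized, "normalized_volume"), pfa > 0, pfa < 0.5)
  t0 <- qnorm(1 - pfa)
  r <- normalized$values
  sel <- which(!is.na(r) & r > t0)
  arr <- arrayInd(sel, dim(r))
  z <- if (!is.null(normalized$z_planes)) normalized$z_planes[arr[, 3]]
       else as.double(arr[, 3])
  data.frame(x_nm = (arr[, 1] - 1) * normalized$dx,
             y_nm = (arr[, 2] - 1) * normalized$dy,
             z_nm = z, rhat = r[sel],
             ix = arr[, 1], iy = arr[, 2], iz = arr[, 3])
}

#' Windowed quadratic RANSAC surface fit
#'
#' Covers the lateral extent with overlapping windows; in each window with at
#' least 6 points, RANSAC repeatedly fits `z = quadratic(x, y)` to minimal
#' 6-point samples, keeps the largest consensus within `inlier_tol`, and
#' refits by least squares on that consensus. Labels are fused across
#' overlaps strictly: a point is an inlier only if it is an inlier in every
#' fitted window that covers it. Points are canonically sorted internally, so
#' labels do not depend on input order.
#'
#' @param points data.frame from [detect_bright_points()] (needs `x_nm`,
#'   `y_nm`, `z_nm`)
#' @param n_windows_x,n_windows_y number of windows per axis (default 4)
#' @param inlier_tol inlier distance threshold in nm
#' @param iters RANSAC draws per window (300 gives > 99% success at 50%
#'   outliers for a 6-point model)
#' @param seed integer seed
#' @param overlap fractional window overlap (0.5 = half-window)
#' @param weights optional nonnegative per-point weights for the consensus
#'   refit (detection brightness; brighter points are nearer focus and carry
#'   less axial quantization error)
#' @return an object of class `surface_ransac`: `points`, logical `inlier`
#'   labels, and a data.frame of per-window quadratic `window_fits`
#' @export
fit_surface_ransac <- function(points, n_windows_x = 4L, n_windows_y = 4L,
                               inlier_tol, iters = 300L, seed = 1L,
                               overlap = 0.5, weights = NULL) {
  stopifnot(nrow(points) >= 6L, inlier_tol > 0)
  ord <- order(points$x_nm, points$y_nm, points$z_nm)
  px <- points$x_nm[ord]; py <- points$y_nm[ord]; pz <- points$z_nm[ord]
  pw <- if (!is.null(weights)) weights[ord] else NULL
  n <- length(px)
  set.seed(as.integer(seed))

  wins <- window_rects(range(px), range(py), n_windows_x, n_windows_y, overlap)
  covered <- rep(FALSE, n)
  inlier_all <- rep(TRUE, n)
  fits <- list(); fits_models <- list()
  for (w in seq_len(nrow(wins))) {
    sel <- which(px >= wins$x0[w] & px <= wins$x1[w] &
                 py >= wins$y0[w] & py <= wins$y1[w])
    if (length(sel) < 6L) next # too sparse: points fall to neighboring windows
    best <- ransac_quadratic(px[sel], py[sel], pz[sel], inlier_tol, iters,
                             w = if (!is.null(pw)) pw[sel] else NULL)
    if (is.null(best)) next
    covered[sel] <- TRUE
    inlier_all[sel] <- inlier_all[sel] & best$inlier
    fits[[length(fits) + 1L]] <-
      data.frame(window = w, x0 = wins$x0[w], x1 = wins$x1[w],
                 y0 = wins$y0[w], y1 = wins$y1[w],
                 n_points = length(sel), n_inliers = sum(best$inlier),
                 t(best$coefficients))
    fits_models[[length(fits_models) + 1L]] <-
      list(x0 = wins$x0[w], x1 = wins$x1[w], y0 = wins$y0[w], y1 = wins$y1[w],
           coefficients = best$coefficients, center = best$center,
           scale = best$scale)
  }
  inlier_sorted <- covered & inlier_all
  inlier <- logical(n)
  inlier[ord] <- inlier_sorted
  structure(list(points = points, inlier = inlier,
                 window_fits = if (length(fits)) do.call(rbind, fits)
                               else data.frame(),
                 models = fits_models, inlier_tol = inlier_tol, seed = seed),
            class = "surface_ransac")
}

#' Fused surface prediction from the window fits
#'
#' Evaluates every window's consensus quadratic at the query positions and
#' blends overlapping windows with tent (bilinear) weights centered on each
#' window. This is the fusion of the piecewise estimates: each prediction
#' averages all detections in a window, which suppresses noise and the
#' z-quantization of plane-by-plane acquisitions.
#'
#' @param fit a [fit_surface_ransac()] result
#' @param x,y query coordinates in nm
#' @return fused z predictions (nm); `NA` where no window covers a query
#' @export
predict_surface_windows <- function(fit, x, y) {
  stopifnot(inherits(fit, "surface_ransac"))
  num <- rep(0, length(x)); den <- rep(0, length(x))
  for (m in fit$models) {
    wgt <- tent_weight(x, m$x0, m$x1) * tent_weight(y, m$y0, m$y1)
    sel <- wgt > 0
    if (!any(sel)) next
    xs <- (x[sel] - m$center[1]) / m$scale
    ys <- (y[sel] - m$center[2]) / m$scale
    z <- quad_design(xs, ys) %*% m$coefficients
    num[sel] <- num[sel] + wgt[sel] * z
    den[sel] <- den[sel] + wgt[sel]
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

tent_weight <- function(x, a, b) {
  c0 <- (a + b) / 2; h <- (b - a) / 2
  pmax(1 - abs(x - c0) / h, 0)
}

window_rects <- function(xr, yr, nwx, nwy, overlap) {
  span <- function(r, nw) {
    w <- diff(r) / (1 + (nw - 1) * (1 - overlap))
    starts <- r[1] + (seq_len(nw) - 1) * (1 - overlap) * w
    cbind(starts, starts + w)
  }
  sx <- span(xr, nwx); sy <- span(yr, nwy)
  g <- expand.grid(ix = seq_len(nwx), iy = seq_len(nwy))
  data.frame(x0 = sx[g$ix, 1], x1 = sx[g$ix, 2],
             y0 = sy[g$iy, 1], y1 = sy[g$iy, 2])
}

quad_design <- function(x, y) cbind(1, x, y, x^2, x * y, y^2)

ransac_quadratic <- function(x, y, z, tol, iters, w = NULL) {
  n <- length(x)
  # condition the design by centering/scaling coordinates
  cx <- mean(range(x)); cy <- mean(range(y))
  sc <- max(diff(range(x)), diff(range(y)), 1)
  xs <- (x - cx) / sc; ys <- (y - cy) / sc
  X <- quad_design(xs, ys)
  best_count <- -1L; best_inlier <- NULL
  for (i in seq_len(iters)) {
    take <- sample.int(n, 6L)
    cf <- tryCatch(solve(X[take, ], z[take]), error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf))) next
    res <- abs(z - X %*% cf)
    cnt <- sum(res < tol)
    if (cnt > best_count) { best_count <- cnt; best_inlier <- res < tol }
  }
  if (is.null(best_inlier) || best_count < 6L) return(NULL)
  # refit on the consensus, then relabel (two rounds); the refit is weighted
  # when point weights (detection brightness) are supplied, plus a biweight
  # reweighting that tempers plane-quantized stragglers
  inl <- as.vector(best_inlier)
  wls <- function(sel, wt) {
    A <- X[sel, , drop = FALSE]
    cf <- tryCatch(solve(crossprod(A, wt * A), crossprod(A, wt * z[sel])),
                   error = function(e) NULL)
    if (is.null(cf)) { f <- lm.fit(A, z[sel]); cf <- f$coefficients }
    cf[is.na(cf)] <- 0
    cf
  }
  for (r in 1:2) {
    wt <- if (is.null(w)) rep(1, sum(inl)) else w[inl]
    cf <- wls(inl, wt)
    if (!is.null(w)) {
      for (k in 1:2) { # IRLS: Tukey biweight on residuals
        res_i <- z[inl] - X[inl, , drop = FALSE] %*% cf
        s_r <- max(1.4826 * median(abs(res_i)), tol / 50)
        wt2 <- wt * pmax(1 - (res_i / (4 * s_r))^2, 0)^2
        cf <- wls(inl, as.vector(wt2))
      }
    }
    res <- abs(z - X %*% cf)
    inl <- as.vector(res < tol)
    if (sum(inl) < 6L) return(NULL)
  }
  list(coefficients = cf, inlier = inl, center = c(cx, cy), scale = sc)
}

#' Interpolate a height map through surface inliers
#'
#' Biharmonic (thin-plate) spline interpolation of the inlier point cloud,
#' evaluated on the full lateral grid. With `lambda = 0` the spline passes
#' through the points exactly (and reproduces planes everywhere); a positive
#' `lambda` adds a smoothing ridge, which is the right choice for dense noisy
#' clouds whose z values are quantized to the acquisition planes. Clouds
#' larger than `max_knots` are fused beforehand by averaging points in
#' lateral bins. Grid nodes outside the convex hull of the knots are
#' extrapolations and are flagged in the validity mask.
#'
#' @param points data.frame with `x_nm`, `y_nm`, `z_nm` (inliers only)
#' @param grid a [grid_geometry()] describing the target lateral raster
#' @param lambda smoothing ridge (0 = exact interpolation)
#' @param max_knots maximum spline knots before bin-fusion kicks in
#' @return an object of class `surface_estimate`: `z_grid` (nx x ny, nm),
#'   logical `mask` (TRUE inside the convex hull), `knots`, `lambda`
#' @export
interpolate_surface <- function(points, grid, lambda = 0, max_knots = 1200L) {
  stopifnot(nrow(points) >= 3L)
  x <- points$x_nm; y <- points$y_nm; z <- points$z_nm
  if (nrow(points) > max_knots) {
    nb <- ceiling(sqrt(max_knots))
    bx <- cut(x, nb, labels = FALSE); by <- cut(y, nb, labels = FALSE)
    key <- interaction(bx, by, drop = TRUE)
    x <- tapply(x, key, mean); y <- tapply(y, key, mean); z <- tapply(z, key, mean)
    x <- as.double(x); y <- as.double(y); z <- as.double(z)
  }
  if (qr(cbind(1, x, y))$rank < 3L)
    stop("inliers are collinear; surface is undetermined")
  sc <- max(diff(range(x)), diff(range(y)))
  xs <- x / sc; ys <- y / sc
  k <- length(xs)
  r2 <- outer(xs, xs, `-`)^2 + outer(ys, ys, `-`)^2
  K <- tps_kernel(r2)
  P <- cbind(1, xs, ys)
  A <- rbind(cbind(K + lambda * diag(k), P),
             cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(z, 0, 0, 0)
  sol <- solve(A, rhs)
  w <- sol[seq_len(k)]; a <- sol[k + 1:3]

  gx <- (seq_len(grid$nx) - 1) * grid$dx / sc
  gy <- (seq_len(grid$ny) - 1) * grid$dy / sc
  zg <- matrix(0, grid$nx, grid$ny)
  for (j in seq_len(grid$ny)) {
    d2 <- outer(gx, xs, `-`)^2 + matrix(rep((gy[j] - ys)^2, each = grid$nx),
                                        grid$nx, k)
    zg[, j] <- tps_kernel(d2) %*% w + a[1] + a[2] * gx + a[3] * gy[j]
  }
  mask <- hull_mask(xs * sc, ys * sc, (seq_len(grid$nx) - 1) * grid$dx,
                    (seq_len(grid$ny) - 1) * grid$dy)
  structure(list(z_grid = zg, mask = mask,
                 knots = data.frame(x_nm = x, y_nm = y, z_nm = z),
                 lambda = lambda, grid = grid),
            class = "surface_estimate")
}

# biharmonic Green function U(r) = r^2 log r, with U(0) = 0
tps_kernel <- function(r2) {
  out <- 0.5 * r2 * log(pmax(r2, .Machine$double.xmin))
  out[r2 == 0] <- 0
  out
}

# TRUE for grid nodes inside the convex hull of (x, y)
hull_mask <- function(x, y, gx, gy) {
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  nx <- length(gx); ny <- length(gy)
  pts_x <- rep(gx, times = ny); pts_y <- rep(gy, each = nx)
  inside <- point_in_poly(pts_x, pts_y, hx, hy)
  matrix(inside, nx, ny)
}

point_in_poly <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xi <- vx[i] + (py - vy[i]) / (vy[j] - vy[i] + (vy[j] == vy[i]) * 1e-300) *
      (vx[j] - vx[i])
    inside <- xor(inside, cross & (px < xi))
    j <- i
  }
  inside
}

#' @export
print.surface_estimate <- function(x, ...) {
  cat(sprintf("<surface_estimate> %d x %d grid, %d knots, z in [%.0f, %.0f] nm\n",
              nrow(x$z_grid), ncol(x$z_grid), nrow(x$knots),
              min(x$z_grid), max(x$z_grid)))
  invisible(x)
}

#' End-to-end topography estimation
#'
#' Chains background normalization, false-alarm detection, windowed RANSAC
#' and spline interpolation into the standard pipeline. The inlier tolerance
#' defaults to twice the acquisition plane spacing, and the spline is run
#' with a small smoothing ridge because detected z values are quantized to
#' the acquired planes.
#'
#' @param volume a [simulate_volume_scan()] object or 3D array
#' @param pfa probability of false alarm for bright-point detection
#' @param fraction background-subsample fraction
#' @param inlier_tol RANSAC tolerance in nm (`NULL`: 2 x plane spacing)
#' @param n_windows windows per lateral axis
#' @param iters RANSAC draws per window
#' @param lambda spline smoothing ridge
#' @param max_knots spline knot budget
#' @param seed integer seed for subsampling and RANSAC
#' @param fuse replace inlier z values by the fused window-fit prediction
#'   ([predict_surface_windows()]) before interpolation; recommended whenever
#'   detections are quantized to acquisition planes
#' @return a `surface_estimate` with the detected `points` and `inlier`
#'   labels attached
#' @export
estimate_topography <- function(volume, pfa = 0.01, fraction = 1 / 1000,
                                inlier_tol = NULL, n_windows = 4L,
                                iters = 300L, lambda = 1e-2,
                                max_knots = 1200L, seed = 1L, fuse = TRUE) {
  norm <- normalize_volume(volume, fraction = fraction, seed = seed)
  pts <- detect_bright_points(norm, pfa)
  if (nrow(pts) < 6L) stop("fewer than 6 bright points detected")
  if (is.null(inlier_tol)) {
    dz <- if (!is.null(norm$z_planes) && length(norm$z_planes) > 1L)
      median(diff(sort(norm$z_planes))) else 1
    inlier_tol <- 2 * dz
  }
  w_det <- pmax(pts$rhat - qnorm(1 - pfa), 0)^2
  rs <- fit_surface_ransac(pts, n_windows, n_windows, inlier_tol,
                           iters = iters, seed = seed, weights = w_det)
  inl <- pts[rs$inlier, , drop = FALSE]
  if (fuse) {
    # plane-by-plane scans quantize each detection's z to the acquired
    # planes; the fused window-quadratic prediction averages hundreds of
    # detections and restores sub-plane accuracy before interpolation
    zf <- predict_surface_windows(rs, inl$x_nm, inl$y_nm)
    ok <- !is.na(zf)
    inl$z_nm[ok] <- zf[ok]
  }
  grid <- if (inherits(volume, "topo_volume")) volume$grid
          else grid_geometry(dim(volume_values(volume))[1],
                             dim(volume_values(volume))[2], 1L, 1, 1, 1)
  est <- interpolate_surface(inl, grid, lambda = lambda, max_knots = max_knots)
  est$points <- pts
  est$inlier <- rs$inlier
  est$ransac <- rs
  est
}

#' Drape an EDF image over an estimated surface
#'
#' Emits a vertex grid (x, y, Z_s) with the image intensity attached per
#' vertex, for 3D rendering of the projective super-resolved image on the
#' recovered topography. Intensities are passed through unchanged.
#'
#' @param edf_image nx x ny intensity image
#' @param surface a [interpolate_surface()] result (or an nx x ny height
#'   matrix in nm)
#' @param dx,dy lateral pitches in nm (taken from the surface when available)
#' @return an object of class `edf_mesh`: `vertices` data.frame
#'   (`x_nm`, `y_nm`, `z_nm`, `intensity`) and the grid dimensions
#' @export
project_onto_surface <- function(edf_image, surface, dx = NULL, dy = NULL) {
  z <- if (inherits(surface, "surface_estimate")) surface$z_grid else surface
  if (!all(dim(edf_image) == dim(z)))
    stop("image and surface must share the lateral grid")
  if (inherits(surface, "surface_estimate")) {
    dx <- surface$grid$dx; dy <- surface$grid$dy
  }
  if (is.null(dx)) dx <- 1
  if (is.null(dy)) dy <- 1
  nx <- nrow(z); ny <- ncol(z)
  vertices <- data.frame(
    x_nm = rep((seq_len(nx) - 1) * dx, times = ny),
    y_nm = rep((seq_len(ny) - 1) * dy, each = nx),
    z_nm = as.vector(z),
    intensity = as.vector(edf_image))
  structure(list(vertices = vertices, nx = nx, ny = ny),
            class = "edf_mesh")
}

#' @export
print.edf_mesh <- function(x, ...) {
  cat(sprintf("<edf_mesh> %d x %d vertices, total intensity %.4g\n",
              x$nx, x$ny, sum(x$vertices$intensity)))
  invisible(x)
}

#' Write a mesh as a Wavefront OBJ file
#'
#' Vertices carry a grayscale color (normalized intensity); faces triangulate
#' the lateral grid.
#'
#' @param mesh an [project_onto_surface()] result
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "edf_mesh"))
  v <- mesh$vertices
  g <- v$intensity / max(v$intensity, 1e-300)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.3f %.3f %.3f %.4f %.4f %.4f",
                     v$x_nm, v$y_nm, v$z_nm, g, g, g), con)
  nx <- mesh$nx; ny <- mesh$ny
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  v00 <- (j - 1) * nx + i; v10 <- v00 + 1
  v01 <- j * nx + i; v11 <- v01 + 1
  writeLines(c(sprintf("f %d %d %d", v00, v10, v11),
               sprintf("f %d %d %d", v00, v11, v01)), con)
  invisible(path)
}
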