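# Synthetic samples and the forward imaging model.
#
# The reference phantom is a star-shaped lateral density rho(r, theta) =
# 1 + cos(40 theta) whose local spatial frequency increases towards the
# center, draped over one of three topographies: flat, a right circular cone
# (radius (Nx/2) dx, height Nz dz), or i.i.d. uniform random heights.
# Heightmaps are measured in nm from the bottom slice center (value 0 places
# a column on slice 1, value (Nz-1) dz on the top slice).

#' Star-shaped lateral density
#'
#' Pixel-centered evaluation of `1 + cos(n_lobes * theta)`; values lie in
#' \[0, 2\]. The local azimuthal period at radius r is `2 pi r / n_lobes`, so
#' resolution can be read off as the innermost radius at which the spokes are
#' still resolved.
#'
#' @param grid a [grid_geometry()]
#' @param n_lobes number of cosine lobes (even positive integer; default 40)
#' @return nx x ny matrix
#' @export
make_star_density <- function(grid, n_lobes = 40L) {
  n_lobes <- as.integer(n_lobes)
  if (n_lobes <= 0L || n_lobes %% 2L != 0L)
    stop("n_lobes must be an even positive integer")
  x <- centered_coords(grid$nx, grid$dx)
  y <- centered_coords(grid$ny, grid$dy)
  theta <- atan2(outer(rep(1, grid$nx), y), outer(x, rep(1, grid$ny)))
  1 + cos(n_lobes * theta)
}

#' Topography height maps
#'
#' Heights are in nm above the bottom slice center. `flat` is a constant at
#' mid-range (`floor(nz/2) * dz`, i.e. the focus slice); `cone` is a right
#' circular cone of radius `(nx/2) dx` and height `nz * dz`, with the flat
#' base level outside that radius; `random` draws i.i.d. uniform heights over
#' the full z-range with no lateral correlation.
#'
#' @param grid a [grid_geometry()]
#' @param kind `"flat"`, `"cone"` or `"random"`
#' @param seed integer seed, required for `kind = "random"`
#' @return nx x ny matrix of heights (nm)
#' @export
make_topography <- function(grid, kind = c("flat", "cone", "random"),
                            seed = NULL) {
  kind <- match.arg(kind)
  nx <- grid$nx; ny <- grid$ny
  if (kind == "flat")
    return(matrix(floor(grid$nz / 2) * grid$dz, nx, ny))
  if (kind == "cone") {
    x <- centered_coords(nx, grid$dx)
    y <- centered_coords(ny, grid$dy)
    r <- sqrt(outer(x^2, y^2, `+`))
    radius <- (nx / 2) * grid$dx
    height <- grid$nz * grid$dz
    z <- height * pmax(1 - r / radius, 0)
    return(z)
  }
  if (is.null(seed)) stop("random topography requires a seed")
  set.seed(as.integer(seed))
  matrix(runif(nx * ny, 0, grid$nz * grid$dz), nx, ny)
}

#' Embed a projected density on a surface
#'
#' Places each lateral column's mass on the z slice nearest to the heightmap
#' value (a discrete delta in z), so the axial sum of the result reproduces
#' `density2d` exactly. Heights within half a voxel (plus a one-voxel grace
#' for boundary values such as the cone apex at exactly `nz * dz`) of the
#' grid are clamped to the nearest slice; anything further out is an error.
#'
#' @param density2d nx x ny nonnegative matrix
#' @param heightmap nx x ny heights in nm above the bottom slice center
#' @param grid a [grid_geometry()]
#' @return an object of class `sample_volume`: `density2d`, `heightmap`,
#'   `slice_index` (nx x ny integer map) and `density3d` (nx x ny x nz)
#' @export
embed_on_surface <- function(density2d, heightmap, grid) {
  stopifnot(all(dim(density2d) == c(grid$nx, grid$ny)),
            all(dim(heightmap) == c(grid$nx, grid$ny)),
            all(density2d >= 0))
  k <- as.integer(round(heightmap / grid$dz)) + 1L
  if (any(k < 0L) || any(k > grid$nz + 1L))
    stop("heightmap extends beyond the grid z-range by more than one voxel")
  k <- pmin(pmax(k, 1L), grid$nz)
  dim(k) <- dim(heightmap)
  density3d <- array(0, dim = c(grid$nx, grid$ny, grid$nz))
  idx <- cbind(as.vector(row(k)), as.vector(col(k)), as.vector(k))
  density3d[idx] <- as.vector(density2d)
  structure(list(density2d = density2d, heightmap = heightmap,
                 slice_index = k, density3d = density3d, grid = grid),
            class = "sample_volume")
}

#' @export
print.sample_volume <- function(x, ...) {
  cat(sprintf("<sample_volume> %d x %d x %d, %d occupied slices, total mass %.4g\n",
              x$grid$nx, x$grid$ny, x$grid$nz,
              length(unique(as.vector(x$slice_index))), sum(x$density2d)))
  invisible(x)
}

#' Form a single focal-plane image
#'
#' The camera image at focal position `z_f` of a (density x illumination)
#' product: each occupied slice is convolved with the PSF slice at defocus
#' `z_f - z` and the contributions are summed. Convolutions are circular.
#'
#' @param sample a [embed_on_surface()] object (or a plain 3D array)
#' @param speckle 3D illumination array matching the grid, or `1` for uniform
#' @param psf a [compute_psf3d()] object
#' @param z_f focal position in nm above the bottom slice center
#' @return nx x ny image matrix
#' @export
form_image <- function(sample, speckle, psf, z_f) {
  grid <- psf$grid
  dens3 <- if (inherits(sample, "sample_volume")) sample$density3d else sample
  stopifnot(length(dim(dens3)) == 3L)
  z_bottom <- grid_z_offsets(grid)[1]
  occ <- which(vapply(seq_len(dim(dens3)[3]),
                      function(k) any(dens3[, , k] != 0), logical(1)))
  out <- matrix(0, dim(dens3)[1], dim(dens3)[2])
  for (k in occ) {
    src <- dens3[, , k]
    if (!identical(speckle, 1)) src <- src * speckle[, , k]
    z_slice <- (k - 1L) * grid$dz            # height above bottom slice
    h <- psf_slice_at(psf, (z_f + z_bottom) - (z_slice + z_bottom))
    out <- out + conv2_circ(src, h)
  }
  out
}

#' Form an extended-depth-of-field image
#'
#' The axial integral of the focal stack collapses to a single 2D
#' convolution: every occupied slice of (density x illumination) is summed
#' and convolved with the EDF PSF `h_perp`.
#'
#' @inheritParams form_image
#' @param edf_psf a [compute_edf_psf()] object (built from `psf` when omitted)
#' @param psf optional [compute_psf3d()] (used only to build `edf_psf`)
#' @return nx x ny image matrix
#' @export
form_edf_image <- function(sample, speckle, edf_psf = NULL, psf = NULL) {
  if (is.null(edf_psf)) edf_psf <- compute_edf_psf(psf)
  dens3 <- if (inherits(sample, "sample_volume")) sample$density3d else sample
  proj <- matrix(0, dim(dens3)[1], dim(dens3)[2])
  for (k in seq_len(dim(dens3)[3])) {
    sl <- dens3[, , k]
    if (!any(sl != 0)) next
    proj <- proj + if (identical(speckle, 1)) sl else sl * speckle[, , k]
  }
  conv2_tf(proj, edf_psf$otf)
}

# Illumination seen by a surface sample: the speckle value at each column's
# occupied slice. Generating only the needed slices keeps EDF simulation
# cheap for flat and cone samples.
surface_illumination <- function(sample, pupil, envelope_sigma, seed) {
  grid <- sample$grid
  z_off <- grid_z_offsets(grid)
  occ <- sort(unique(as.vector(sample$slice_index)))
  spk <- generate_speckle(pupil, grid, envelope_sigma, seed,
                          z_offsets = z_off[occ])
  e <- matrix(0, grid$nx, grid$ny)
  for (j in seq_along(occ)) {
    sel <- sample$slice_index == occ[j]
    sl <- spk[, , j]
    e[sel] <- sl[sel]
  }
  e
}

#' Simulate a speckled acquisition
#'
#' Draws `n_speckles` independent speckle illuminations, forms noiseless EDF
#' (or fixed-plane) images of the sample, scales intensities so that the
#' brightest pixel of the mean (uniform-illumination) image receives
#' `photon_budget` expected photons, and applies Poisson noise (plus optional
#' Gaussian read noise). All randomness derives from `seed`.
#'
#' @param sample a [embed_on_surface()] object
#' @param pupil a [make_pupil()] object
#' @param n_speckles number of speckled images (>= 2)
#' @param photon_budget expected photons at the brightest pixel of the mean
#'   image (> 0); `Inf` disables photon noise
#' @param modality `"edf"` or `"plane"`
#' @param z_f focal position (nm above bottom slice) for `modality = "plane"`
#' @param seed master integer seed
#' @param envelope_sigma speckle envelope width (see [generate_speckle()])
#' @param read_noise_sd Gaussian read noise standard deviation in photons
#' @param illumination `"speckle"` (default) or `"uniform"`; the latter gives
#'   the widefield baseline (photon noise only, no illumination fluctuation)
#' @return an object of class `speckle_stack`: `images` (nx x ny x N),
#'   per-image `seeds`, the photon `scale` applied, and acquisition metadata
#' @export
simulate_acquisition <- function(sample, pupil, n_speckles = 100L,
                                 photon_budget = 1000, modality = c("edf", "plane"),
                                 z_f = NULL, seed = 1L, envelope_sigma = NULL,
                                 read_noise_sd = 0,
                                 illumination = c("speckle", "uniform")) {
  modality <- match.arg(modality)
  illumination <- match.arg(illumination)
  stopifnot(n_speckles >= 2L)
  if (!is.infinite(photon_budget) && photon_budget <= 0)
    stop("photon_budget must be positive")
  grid <- sample$grid
  psf <- compute_psf3d(pupil, grid)
  edf <- compute_edf_psf(psf)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_speckles)

  # photon scale from the mean image (unit-mean illumination)
  mean_img <- conv2_tf(sample$density2d, edf$otf)
  scale <- if (is.infinite(photon_budget)) 1 else photon_budget / max(mean_img)

  images <- array(0, dim = c(grid$nx, grid$ny, n_speckles))
  for (m in seq_len(n_speckles)) {
    if (modality == "edf") {
      e <- if (illumination == "uniform") 1
           else surface_illumination(sample, pupil, envelope_sigma, seeds[m])
      img <- conv2_tf(sample$density2d * e, edf$otf)
    } else {
      if (is.null(z_f)) stop("modality 'plane' requires z_f")
      spk <- if (illumination == "uniform") 1
             else generate_speckle(pupil, grid, envelope_sigma, seeds[m])
      img <- form_image(sample, spk, psf, z_f)
    }
    img <- pmax(img * scale, 0)
    if (!is.infinite(photon_budget)) {
      img <- matrix(rpois(length(img), img), nrow(img), ncol(img))
      if (read_noise_sd > 0)
        img <- img + matrix(rnorm(length(img), 0, read_noise_sd),
                            nrow(img), ncol(img))
    }
    images[, , m] <- img
  }
  speckle_stack(images, modality = modality, z_f = z_f,
                photon_budget = photon_budget, seeds = seeds, scale = scale,
                optics = list(na = pupil$na, wavelength_nm = pupil$wavelength,
                              kind = pupil$kind,
                              inner_fraction = pupil$annulus_inner_fraction,
                              envelope_sigma = envelope_sigma),
                grid = grid)
}

#' Speckled image stack container
#'
#' @param images nx x ny x N array (N >= 2) of nonnegative images
#' @param modality `"edf"`, `"plane"` or `"unknown"`
#' @param z_f focal position for plane stacks (nm), or `NULL`
#' @param photon_budget expected photons at the brightest mean-image pixel
#' @param seeds per-image RNG seeds (or `NULL` for experimental data)
#' @param scale photon scale factor applied to the noiseless images
#' @param optics named list of acquisition optics metadata
#' @param grid a [grid_geometry()]
#' @return an object of class `speckle_stack`
#' @export
speckle_stack <- function(images, modality = "unknown", z_f = NULL,
                          photon_budget = NA_real_, seeds = NULL, scale = 1,
                          optics = list(), grid = NULL) {
  stopifnot(length(dim(images)) == 3L, dim(images)[3] >= 2L)
  structure(list(images = images, n = dim(images)[3], modality = modality,
                 z_f = z_f, photon_budget = photon_budget, seeds = seeds,
                 scale = scale, optics = optics, grid = grid),
            class = "speckle_stack")
}

#' @export
print.speckle_stack <- function(x, ...) {
  cat(sprintf("<speckle_stack> %d images of %d x %d, modality=%s\n",
              x$n, dim(x$images)[1], dim(x$images)[2], x$modality))
  invisible(x)
}

#' Simulate a plane-by-plane volume scan under one speckle
#'
#' The topography-estimation input: the sample is imaged plane by plane (one
#' image per focal position, typically one every 2 um) under a single fixed
#' speckled illumination. A smooth multiplicative background gain field and
#' noise (Poisson, or multiplicative Gaussian of coefficient of variation
#' `gaussian_cv`) emulate real tissue acquisitions.
#'
#' @inheritParams simulate_acquisition
#' @param z_planes focal positions in nm above the bottom slice center
#' @param background_level mean background intensity (photons) added
#'   everywhere, modulated by a smooth gain ramp
#' @param noise `"poisson"`, `"gaussian"` or `"none"`
#' @param gaussian_cv coefficient of variation for `noise = "gaussian"`
#' @return an object of class `topo_volume`: `values` (nx x ny x n_planes),
#'   `z_planes`, lateral pitches, and the true `gain` field
#' @export
simulate_volume_scan <- function(sample, pupil, z_planes,
                                 photon_budget = 2000, background_level = 200,
                                 noise = c("poisson", "gaussian", "none"),
                                 gaussian_cv = 0.1, seed = 1L,
                                 envelope_sigma = NULL) {
  noise <- match.arg(noise)
  grid <- sample$grid
  psf <- compute_psf3d(pupil, grid)
  set.seed(as.integer(seed))
  speckle_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  spk <- generate_speckle(pupil, grid, envelope_sigma, speckle_seed)
  n_p <- length(z_planes)
  vals <- array(0, dim = c(grid$nx, grid$ny, n_p))
  for (j in seq_len(n_p))
    vals[, , j] <- pmax(form_image(sample, spk, psf, z_planes[j]), 0)
  vals <- vals * (photon_budget / max(vals))

  # smooth separable background gain ramp, mean ~ background_level
  gx <- 1 + 0.5 * (centered_coords(grid$nx, 1) / grid$nx)
  gy <- 1 + 0.3 * (centered_coords(grid$ny, 1) / grid$ny)
  gz <- 1 + 0.4 * (seq_len(n_p) - (n_p + 1) / 2) / max(n_p, 2)
  gain <- background_level * outer(outer(gx, gy), gz)
  s <- vals + gain
  if (noise == "poisson") {
    s <- array(rpois(length(s), s), dim = dim(s))
  } else if (noise == "gaussian") {
    s <- s * (1 + gaussian_cv * array(rnorm(length(s)), dim = dim(s)))
  }
  structure(list(values = s, z_planes = z_planes, dx = grid$dx, dy = grid$dy,
                 gain = gain, signal = vals, grid = grid,
                 noise = noise, seed = seed),
            class = "topo_volume")
}

#' @export
print.topo_volume <- function(x, ...) {
  cat(sprintf("<topo_volume> %d x %d x %d planes, z in [%g, %g] nm\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$z_planes), max(x$z_planes)))
  invisible(x)
}
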