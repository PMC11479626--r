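#' Binary pupil mask
#'
#' Builds the binary pupil of the scalar optical model on the discrete
#' transverse-frequency grid of `grid`. The support cutoff is `na/wavelength`
#' (cycles per nm); a disc gives conventional 3D speckles and PSFs, an annulus
#' gives Bessel-type (axially invariant) speckles.
#'
#' @param na numerical aperture (dimensionless, > 0)
#' @param wavelength in-medium wavelength in nm (e.g. 530/1.3 for water)
#' @param grid a [grid_geometry()]
#' @param kind `"disc"` or `"annulus"`
#' @param annulus_inner_fraction inner/outer radius ratio in (0, 1); only for
#'   `kind = "annulus"`
#' @return an object of class `pupil_mask` with the binary `amplitude` map
#'   (DC at index \[1, 1\]), the frequency axes `fx`, `fy`, and the `cutoff`
#'   frequency in cycles per nm
#' @examples
#' g <- grid_desk()
#' p <- make_pupil(0.8, 530 / 1.3, g)
#' p$cutoff # NA / lambda
#' @export
make_pupil <- function(na, wavelength, grid, kind = c("disc", "annulus"),
                       annulus_inner_fraction = 0) {
  kind <- match.arg(kind)
  stopifnot(na > 0, wavelength > 0)
  check_nyquist_cutoff(grid, na, wavelength)
  if (kind == "annulus" &&
      (annulus_inner_fraction <= 0 || annulus_inner_fraction >= 1))
    stop("annulus_inner_fraction must lie strictly in (0, 1)")
  if (kind == "disc") annulus_inner_fraction <- 0

  fx <- fftfreq(grid$nx, grid$dx)
  fy <- fftfreq(grid$ny, grid$dy)
  f2 <- outer(fx^2, fy^2, `+`)
  cutoff <- na / wavelength
  amp <- (f2 <= cutoff^2) * 1
  if (kind == "annulus")
    amp <- amp * (f2 >= (annulus_inner_fraction * cutoff)^2)

  structure(list(na = na, wavelength = wavelength, kind = kind,
                 annulus_inner_fraction = annulus_inner_fraction,
                 amplitude = amp, fx = fx, fy = fy, f2 = f2,
                 cutoff = cutoff, grid = grid),
            class = "pupil_mask")
}

# A grid that cannot even represent the pupil cutoff would alias the model.
check_nyquist_cutoff <- function(grid, na, wavelength) {
  d <- max(grid$dx, grid$dy)
  if (d >= wavelength / (2 * na))
    stop("lateral pitch ", d,
         " nm aliases the pupil cutoff; need dx < lambda/(2 NA) = ",
         signif(wavelength / (2 * na), 4), " nm")
  invisible(TRUE)
}

#' @export
print.pupil_mask <- function(x, ...) {
  cat(sprintf("<pupil_mask> %s, NA=%g, lambda=%g nm, cutoff=%.4g /nm (%d px in support)\n",
              x$kind, x$na, x$wavelength, x$cutoff, sum(x$amplitude > 0)))
  invisible(x)
}

#' Annulus inner fraction for a target axial invariance depth
#'
#' A Bessel-type speckle stays correlated along z as long as the spread of
#' axial frequencies across the annulus stays small: the correlation length
#' is about `1 / (2 (kz_inner - kz_outer))`. This helper returns the inner
#' fraction whose kz spread keeps the accumulated defocus phase below pi/2
#' over `depth_nm`, i.e. `kz_inner = kz_outer + 1/(4 depth)`.
#'
#' @param na numerical aperture
#' @param wavelength in-medium wavelength (nm)
#' @param depth_nm axial range over which the speckle should stay invariant
#' @return inner/outer radius fraction in (0, 1)
#' @export
annulus_for_depth <- function(na, wavelength, depth_nm) {
  stopifnot(depth_nm > 0)
  cutoff <- na / wavelength
  kz_out <- sqrt(1 / wavelength^2 - cutoff^2)
  kz_in <- kz_out + 1 / (4 * depth_nm)
  f_in2 <- 1 / wavelength^2 - kz_in^2
  if (f_in2 <= 0) stop("depth too small: annulus would close completely")
  min(sqrt(f_in2) / cutoff, 1 - 1e-6)
}

# Axial spatial frequency sqrt(1/lambda^2 - f_perp^2) on the pupil support;
# 0 outside (the mask is 0 there anyway). Defocus by z multiplies the pupil
# by exp(2i pi z kz) (angular-spectrum propagation).
pupil_kz <- function(pupil) {
  kz2 <- 1 / pupil$wavelength^2 - pupil$f2
  sqrt(pmax(kz2, 0))
}

# Unnormalized intensity PSF slice at defocus z (nm), centered layout.
psf_slice_raw <- function(pupil, z, kz = pupil_kz(pupil)) {
  field <- ifft2(pupil$amplitude * exp(2i * pi * z * kz))
  fftshift2(Mod(field)^2)
}

#' 3D point spread function of the scalar model
#'
#' Each axial slice is the squared modulus of the inverse transform of the
#' pupil with the angular-spectrum defocus phase. The whole volume is
#' normalized to unit sum, so the axial integral ([compute_edf_psf()]) also
#' sums to one.
#'
#' @param pupil a [make_pupil()] object
#' @param grid a [grid_geometry()]; slices are computed at its axial offsets,
#'   centered on focus
#' @return an object of class `psf3d`: `values` (nx x ny x nz, centered
#'   laterally), `z_offsets` (nm), the generating `pupil`, and `slice_scale`
#'   (the normalization factor applied to every raw slice)
#' @export
compute_psf3d <- function(pupil, grid = pupil$grid) {
  stopifnot(grid$nx == pupil$grid$nx, grid$ny == pupil$grid$ny)
  kz <- pupil_kz(pupil)
  z_off <- grid_z_offsets(grid)
  values <- array(0, dim = c(grid$nx, grid$ny, grid$nz))
  for (k in seq_len(grid$nz))
    values[, , k] <- psf_slice_raw(pupil, z_off[k], kz)
  s <- sum(values)
  structure(list(values = values / s, z_offsets = z_off,
                 pupil = pupil, grid = grid, slice_scale = 1 / s),
            class = "psf3d")
}

# One normalized PSF slice at an arbitrary defocus, on the same scale as the
# slices of `psf` (used when forming images at focal planes outside the
# precomputed offsets).
psf_slice_at <- function(psf, z) {
  k <- match(TRUE, abs(psf$z_offsets - z) < 1e-9)
  if (!is.na(k)) return(psf$values[, , k])
  psf_slice_raw(psf$pupil, z) * psf$slice_scale
}

#' Extended-depth-of-field PSF
#'
#' The axial sum of a 3D PSF, i.e. the lateral kernel of an acquisition that
#' integrates a full focal sweep into a single 2D image. Its discrete OTF is
#' cached for later filtering.
#'
#' @param psf a [compute_psf3d()] object
#' @return an object of class `edf_psf`: `values` (2D, centered, unit sum
#'   under the 3D normalization), `otf` (complex, DC at \[1, 1\]) and the
#'   originating `pupil`
#' @export
compute_edf_psf <- function(psf) {
  stopifnot(inherits(psf, "psf3d"))
  v <- psf$values
  h_perp <- if (length(dim(v)) == 3L && dim(v)[3] > 1L)
    rowSums(v, dims = 2L) else v[, , 1]
  structure(list(values = h_perp, otf = fft2(ifftshift2(h_perp)),
                 pupil = psf$pupil, grid = psf$grid),
            class = "edf_psf")
}

#' @export
print.psf3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<psf3d> %d x %d x %d, z in [%g, %g] nm\n",
              d[1], d[2], d[3], min(x$z_offsets), max(x$z_offsets)))
  invisible(x)
}

#' @export
print.edf_psf <- function(x, ...) {
  cat(sprintf("<edf_psf> %d x %d, sum=%.6f\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

# Full width at half maximum of a centered radial profile along the x axis,
# with linear interpolation between samples. Used by tests and metrics.
profile_fwhm <- function(values, d) {
  n <- nrow(values)
  c0 <- floor(n / 2) + 1L
  prof <- values[, c0]
  pk <- which.max(prof)
  half <- prof[pk] / 2
  right <- prof[pk:n]
  i <- match(TRUE, right < half)
  if (is.na(i)) return(NA_real_)
  # linear interpolation between samples i-1 and i (1-based from peak)
  x1 <- i - 2; y1 <- right[i - 1]; y2 <- right[i]
  t <- (y1 - half) / (y1 - y2)
  2 * (x1 + t) * d
}
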