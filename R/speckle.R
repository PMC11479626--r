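# Speckle synthesis and second-order statistics.
#
# A speckle volume is generated from a single random-phase draw on the pupil
# support: the complex pupil field is multiplied by a Gaussian frequency
# envelope (which sets the correlation length of the random phasor field),
# propagated to each axial offset with the angular-spectrum defocus phase, and
# squared. The pupil amplitudes are rescaled so that the expected intensity is
# exactly 1 at every voxel, which makes covariances directly comparable across
# pupils and envelopes.

# Effective (envelope-apodized) pupil amplitude, plus the normalization that
# makes E[S] = 1 for uniform random phases.
speckle_amplitude <- function(pupil, envelope_sigma = NULL) {
  if (is.null(envelope_sigma)) {
    # default: envelope FWHM equals the pupil radius
    envelope_sigma <- pupil$cutoff / (2 * sqrt(2 * log(2)))
  }
  stopifnot(envelope_sigma > 0)
  amp <- pupil$amplitude * exp(-pupil$f2 / (2 * envelope_sigma^2))
  n_px <- length(amp)
  amp * n_px / sqrt(sum(amp^2))
}

#' Generate a speckle illumination volume
#'
#' Draws i.i.d. uniform phases on the (envelope-apodized) pupil support and
#' propagates the field to each requested axial offset; the returned volume is
#' the intensity, with unit ensemble mean at every voxel. Fully developed
#' speckle from a disc pupil has unit contrast (std = mean); an annulus pupil
#' with inner fraction close to 1 yields Bessel-type speckles that are nearly
#' invariant along the optical axis.
#'
#' @param pupil a [make_pupil()] object
#' @param grid a [grid_geometry()]; default the pupil's grid
#' @param envelope_sigma Gaussian envelope width in frequency space
#'   (cycles/nm); default sets the envelope FWHM equal to the pupil radius
#' @param seed integer seed (required; the generator is deterministic given it)
#' @param z_offsets axial offsets in nm at which slices are evaluated;
#'   default the grid's centered slice offsets
#' @return nx x ny x length(z_offsets) array with attribute `z_offsets`
#' @export
generate_speckle <- function(pupil, grid = pupil$grid, envelope_sigma = NULL,
                             seed, z_offsets = grid_z_offsets(grid)) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  amp <- speckle_amplitude(pupil, envelope_sigma)
  kz <- pupil_kz(pupil)
  set.seed(as.integer(seed))
  phase <- matrix(runif(length(amp), 0, 2 * pi), nrow(amp), ncol(amp))
  base <- amp * exp(1i * phase)
  out <- array(0, dim = c(nrow(amp), ncol(amp), length(z_offsets)))
  for (k in seq_along(z_offsets)) {
    field <- ifft2(base * exp(2i * pi * z_offsets[k] * kz))
    out[, , k] <- Mod(field)^2
  }
  attr(out, "z_offsets") <- z_offsets
  out
}

#' Auto-covariance of a speckle ensemble
#'
#' Estimates the spatial auto-covariance of speckle realizations. The default
#' estimator subtracts the per-voxel ensemble mean and then averages the
#' circular (Wiener-Khinchin) spatial auto-correlation over realizations,
#' which assumes stationarity; `method = "ensemble"` instead computes, for
#' every lag, the plain ensemble covariance between the central voxel and the
#' voxel at that lag (noisy, but free of the stationarity assumption).
#'
#' @param realizations list of 2D matrices or 3D arrays, identical shapes
#' @param method `"spatial"` (default) or `"ensemble"`
#' @return an object of class `speckle_ensemble`: `autocov3d` (centered; a
#'   matrix when inputs are 2D), `autocov_slice` (the z = 0 slice, centered),
#'   `mean_intensity`, and `variance` = Gamma(0)
#' @export
estimate_autocovariance <- function(realizations,
                                    method = c("spatial", "ensemble")) {
  method <- match.arg(method)
  if (!is.list(realizations)) realizations <- list(realizations)
  if (length(realizations) < 2L && method == "ensemble")
    stop("need at least 2 realizations")
  if (length(realizations) < 1L) stop("need at least 1 realization")
  dims <- dim(realizations[[1]])
  if (is.null(dims)) stop("realizations must be matrices or 3D arrays")
  for (r in realizations)
    if (!identical(dim(r), dims)) stop("realizations must share one shape")
  is3d <- length(dims) == 3L
  m <- length(realizations)
  # the per-voxel ensemble mean needs >= 2 draws; a single realization is
  # accepted for the spatial estimator only, with its grand mean subtracted
  mu <- if (m >= 2L) Reduce(`+`, realizations) / m
        else array(mean(realizations[[1]]), dim = dims)
  n_vox <- prod(dims)

  if (method == "spatial") {
    acc <- array(0, dim = dims)
    for (r in realizations) {
      d <- r - mu
      acc <- acc + Mod(stats::fft(d))^2
    }
    gam <- Re(stats::fft(acc / (m * n_vox), inverse = TRUE)) / n_vox
  } else {
    ctr <- floor(dims / 2) + 1L
    gam <- array(0, dim = dims)
    dev <- lapply(realizations, function(r) r - mu)
    cval <- vapply(dev, function(d) {
      if (is3d) d[ctr[1], ctr[2], ctr[3]] else d[ctr[1], ctr[2]]
    }, numeric(1))
    for (i in seq_len(m)) {
      d <- dev[[i]]
      # lag Delta relative to the center voxel; wrap to fft layout afterwards
      gam <- gam + cval[i] * shift_to_center(d, ctr)
    }
    gam <- gam / m
    # already centered; convert to fft layout for uniform handling below
    gam <- uncenter(gam)
  }

  gam_c <- recenter(gam)
  slice <- if (is3d) gam_c[, , floor(dims[3] / 2) + 1L] else gam_c
  structure(list(autocov3d = gam_c, autocov_slice = slice,
                 mean_intensity = mean(mu),
                 variance = if (is3d) gam[1, 1, 1] else gam[1, 1],
                 n_realizations = m, method = method),
            class = "speckle_ensemble")
}

# fft-layout (origin at [1,1,..]) -> centered layout
recenter <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) fftshift2(x)
  else x[shift_idx(d[1], TRUE), shift_idx(d[2], TRUE), shift_idx(d[3], TRUE), drop = FALSE]
}

# centered layout -> fft layout
uncenter <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) ifftshift2(x)
  else x[shift_idx(d[1]), shift_idx(d[2]), shift_idx(d[3]), drop = FALSE]
}

# value field re-indexed so that entry at lag Delta from `ctr` lands at the
# centered position; implemented as a circular shift.
shift_to_center <- function(d, ctr) {
  dims <- dim(d)
  roll <- function(n, by) ((seq_len(n) - 1L + by) %% n) + 1L
  if (length(dims) == 2L)
    d[roll(dims[1], ctr[1] - 1L - floor(dims[1] / 2)),
      roll(dims[2], ctr[2] - 1L - floor(dims[2] / 2))]
  else
    d[roll(dims[1], ctr[1] - 1L - floor(dims[1] / 2)),
      roll(dims[2], ctr[2] - 1L - floor(dims[2] / 2)),
      roll(dims[3], ctr[3] - 1L - floor(dims[3] / 2))]
}

#' Analytic speckle auto-covariance from the pupil
#'
#' For a circular Gaussian speckle field, the intensity auto-covariance is the
#' squared modulus of the normalized field correlation, which is the Fourier
#' transform of the (envelope-apodized) pupil power. With the package's unit
#' mean-intensity normalization, Gamma(0) = 1 for fully developed speckle.
#'
#' @inheritParams generate_speckle
#' @param delta_z axial lag in nm (0 gives the focal-plane / EDF slice)
#' @return centered nx x ny matrix Gamma(delta r, delta_z)
#' @export
speckle_autocov_model <- function(pupil, grid = pupil$grid,
                                  envelope_sigma = NULL, delta_z = 0) {
  amp <- speckle_amplitude(pupil, envelope_sigma)
  pow <- amp^2
  phase <- if (delta_z != 0) exp(2i * pi * delta_z * pupil_kz(pupil)) else 1
  corr <- stats::fft(pow * phase, inverse = TRUE) / sum(pow)
  fftshift2(Mod(corr)^2)
}
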