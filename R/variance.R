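# Empirical and theoretical standard deviation of speckled EDF images.

#' Empirical standard deviation of prefiltered speckled images
#'
#' Applies an optional Tukey window and an optional Wiener prefilter to every
#' image of a stack, then takes the per-pixel population standard deviation
#' (divide by N, not N - 1).
#'
#' @param stack a [speckle_stack()] (or plain nx x ny x N array)
#' @param prefilter a [make_wiener()] filter, or `NULL` for none
#' @param window Tukey cosine fraction in \[0, 1\]; 0 disables the window.
#'   Windowing is meant for experimental-style (non-periodic) inputs.
#' @return nx x ny matrix of standard deviations
#' @export
empirical_std <- function(stack, prefilter = NULL, window = 0) {
  images <- if (inherits(stack, "speckle_stack")) stack$images else stack
  stopifnot(length(dim(images)) == 3L)
  n <- dim(images)[3]
  if (n < 2L) stop("need at least 2 images to estimate a standard deviation")
  w <- if (window > 0) tukey_window(dim(images)[1], dim(images)[2], window) else NULL
  s1 <- matrix(0, dim(images)[1], dim(images)[2])
  s2 <- s1
  for (m in seq_len(n)) {
    img <- images[, , m]
    if (!is.null(w)) img <- img * w
    if (!is.null(prefilter)) img <- wiener_filter(img, prefilter)
    s1 <- s1 + img
    s2 <- s2 + img^2
  }
  v <- s2 / n - (s1 / n)^2
  sqrt(pmax(v, 0))
}

# Spectral decomposition of the speckle auto-covariance.
#
# P(k) = DFT(Gamma)/N^2 over the discrete frequency grid; modes below
# tau * max(P) are dropped, and conjugate pairs (k, -k) are merged into one
# representative with weight 2 (self-paired modes keep weight 1). Gamma must
# be an admissible covariance: its spectrum may only dip below zero by
# numerical noise.
gamma_modes <- function(gamma_centered, tau = 1e-6) {
  nx <- nrow(gamma_centered); ny <- ncol(gamma_centered)
  P <- Re(fft2(ifftshift2(gamma_centered))) / (nx * ny)
  pmax_val <- max(P)
  if (pmax_val <= 0) stop("auto-covariance has no positive spectral mass")
  if (min(P) < -0.01 * pmax_val)
    stop("auto-covariance has a substantially negative power spectrum; ",
         "not a valid covariance")
  P[P < 0] <- 0
  keep <- which(P >= tau * pmax_val, arr.ind = TRUE)
  kx <- keep[, 1] - 1L; ky <- keep[, 2] - 1L
  # conjugate partner of (kx, ky) is ((-kx) mod nx, (-ky) mod ny)
  px <- (nx - kx) %% nx; py <- (ny - ky) %% ny
  id <- kx * ny + ky; pid <- px * ny + py
  self <- id == pid
  first <- id < pid
  sel <- self | first
  list(kx = kx[sel], ky = ky[sel],
       P = P[keep][sel],
       weight = ifelse(self[sel], 1, 2),
       n_modes_full = length(id))
}

#' Theoretical standard deviation of prefiltered EDF images
#'
#' Evaluates the canonical 2D variance model: a quadratic form in the
#' projected density with the speckle auto-covariance `Gamma` and the
#' prefiltered EDF PSF as kernels. Computed through the spectral
#' decomposition of `Gamma`: each Fourier mode of the covariance contributes
#' `P(k) |[(rho e_k) * h_eff](r)|^2`, evaluated with FFTs in compiled code.
#' The model is exactly linear in the amplitude of `density2d`.
#'
#' @param density2d nx x ny nonnegative density
#' @param gamma centered speckle auto-covariance slice (from
#'   [speckle_autocov_model()] or [estimate_autocovariance()])
#' @param effective a [make_wiener()] filter (its effective OTF is used), a
#'   real effective-OTF matrix, or an [compute_edf_psf()] object for the
#'   unfiltered model
#' @param tau spectral-mode truncation threshold relative to max P
#' @return nx x ny matrix of model standard deviations
#' @export
model_std <- function(density2d, gamma, effective, tau = 1e-6) {
  stopifnot(all(density2d >= 0))
  sqrt(pmax(model_var(density2d, gamma, effective, tau), 0))
}

model_var <- function(density2d, gamma, effective, tau = 1e-6) {
  H <- effective_otf_of(effective)
  md <- gamma_modes(gamma, tau)
  rim_sigma2_cpp(density2d, H, as.integer(md$kx), as.integer(md$ky),
                 md$P, md$weight)
}

effective_otf_of <- function(effective) {
  if (inherits(effective, "wiener_filter")) return(effective$effective_otf + 0i)
  if (inherits(effective, "edf_psf")) return(effective$otf)
  if (is.matrix(effective)) return(effective + 0i)
  stop("effective must be a wiener_filter, edf_psf, or OTF matrix")
}

#' Monte-Carlo oracle for the EDF variance
#'
#' Brute-force ground truth for [model_std()]: simulates `n_speckles`
#' noiseless EDF images of the density embedded flat at focus, prefilters
#' them, and returns the per-pixel population standard deviation. Slow but
#' model-free; used to validate the spectral variance model.
#'
#' @param density2d nx x ny nonnegative density
#' @param pupil a [make_pupil()] object
#' @param n_speckles number of speckle draws (>= 100)
#' @param seed master integer seed
#' @param eta Wiener regularization for the prefilter (`NULL` skips it)
#' @param envelope_sigma speckle envelope width (see [generate_speckle()])
#' @return nx x ny matrix of standard deviations
#' @export
variance_oracle <- function(density2d, pupil, n_speckles = 1000L, seed = 1L,
                            eta = 1e-3, envelope_sigma = NULL) {
  stopifnot(n_speckles >= 100L)
  grid <- pupil$grid
  psf <- compute_psf3d(pupil, grid)
  edf <- compute_edf_psf(psf)
  flt <- if (!is.null(eta)) make_wiener(edf, eta) else NULL
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_speckles)
  s1 <- matrix(0, grid$nx, grid$ny); s2 <- s1
  for (m in seq_len(n_speckles)) {
    spk <- generate_speckle(pupil, grid, envelope_sigma, seeds[m], z_offsets = 0)
    img <- conv2_tf(density2d * spk[, , 1], edf$otf)
    if (!is.null(flt)) img <- wiener_filter(img, flt)
    s1 <- s1 + img
    s2 <- s2 + img^2
  }
  v <- s2 / n_speckles - (s1 / n_speckles)^2
  sqrt(pmax(v, 0))
}
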