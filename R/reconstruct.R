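# Variance-matching reconstruction with Tikhonov regularization.
#
# The estimate solves
#   rho_hat = argmin_{rho >= 0}  || sigma_hat - sigma(rho) ||^2 + mu ||rho||^2
# where sigma(rho) is the theoretical standard deviation of the prefiltered
# EDF images (model_std). The optimizer is projected gradient descent with a
# Barzilai-Borwein initial step and monotone Armijo backtracking; the
# analytic gradient is assembled from the same spectral decomposition as the
# variance model and is validated against finite differences in the tests.

#' Fit a density to a measured standard-deviation map
#'
#' Low-level optimizer behind [reconstruct_rim()]; useful on its own for
#' inverse-crime studies where `sigma_hat` comes from [model_std()] rather
#' than from simulated images. `sigma_hat` is internally rescaled to unit
#' maximum (so `mu` values are transferable across photon budgets); the
#' returned density is in those normalized units.
#'
#' @param sigma_hat measured (or synthetic) standard-deviation map
#' @param gamma centered speckle auto-covariance slice
#' @param effective a [make_wiener()] filter or effective-OTF matrix
#' @param mu Tikhonov weight (>= 0)
#' @param init initial density (matrix), or `NULL` for a flat start with the
#'   amplitude matched to `sigma_hat` by least squares
#' @param nonneg project onto rho >= 0 at every step
#' @param max_iters maximum accepted iterations
#' @param tol stop when the relative objective decrease falls below this
#' @param tau spectral-mode truncation threshold (see [model_std()])
#' @param verbose print per-iteration objective values
#' @return an object of class `rim_fit`: `rho`, `objective` trace,
#'   `converged`, `iterations`, and the match `sigma` at the solution
#' @export
rim_fit <- function(sigma_hat, gamma, effective, mu = 1e-5, init = NULL,
                    nonneg = TRUE, max_iters = 200L, tol = 1e-6, tau = 1e-6,
                    verbose = FALSE) {
  stopifnot(mu >= 0, max_iters >= 1L)
  H <- effective_otf_of(effective)
  md <- gamma_modes(gamma, tau)
  kx <- as.integer(md$kx); ky <- as.integer(md$ky)
  scale <- max(sigma_hat)
  if (scale <= 0) stop("sigma_hat is identically zero")
  sh <- sigma_hat / scale
  eps <- 1e-12

  sigma_of <- function(rho)
    sqrt(pmax(rim_sigma2_cpp(rho, H, kx, ky, md$P, md$weight), 0))
  objective <- function(rho, sigma) sum((sh - sigma)^2) + mu * sum(rho^2)

  if (is.null(init)) {
    ones <- matrix(1, nrow(sh), ncol(sh))
    s1 <- sigma_of(ones)
    amp <- sum(sh * s1) / max(sum(s1^2), eps)
    rho <- ones * max(amp, eps)
  } else {
    rho <- init / max(max(init), eps)
    if (nonneg) rho[rho < 0] <- 0
    # one-parameter amplitude match (sigma is linear in the amplitude)
    s1 <- sigma_of(rho)
    amp <- sum(sh * s1) / max(sum(s1^2), eps)
    if (amp > 0) rho <- rho * amp
  }

  sigma <- sigma_of(rho)
  f <- objective(rho, sigma)
  trace <- numeric(max_iters + 1L)
  trace[1] <- f
  grad_of <- function(rho, sigma) {
    w <- (sigma - sh) / pmax(sigma, eps)
    rim_grad_cpp(rho, w, H, kx, ky, md$P, md$weight) + 2 * mu * rho
  }
  g <- grad_of(rho, sigma)
  step <- 1 / max(sqrt(sum(g^2)), eps)
  converged <- FALSE
  it <- 0L
  rho_prev <- NULL; g_prev <- NULL
  while (it < max_iters) {
    # Barzilai-Borwein step from the previous accepted pair
    if (!is.null(rho_prev)) {
      s_v <- rho - rho_prev; y_v <- g - g_prev
      sy <- sum(s_v * y_v)
      step <- if (sy > 0) sum(s_v^2) / sy else step * 2
    }
    accepted <- FALSE
    for (bt in 1:30) {
      cand <- rho - step * g
      if (nonneg) cand[cand < 0] <- 0
      sig_c <- sigma_of(cand)
      f_c <- objective(cand, sig_c)
      dd <- sum((cand - rho) * g) + sum((cand - rho)^2) / (2 * step)
      if (f_c <= f + 1e-4 * dd || f_c < f) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break } # stalled: no descent direction
    it <- it + 1L
    rho_prev <- rho; g_prev <- g
    rel <- (f - f_c) / max(abs(f), eps)
    rho <- cand; sigma <- sig_c; f <- f_c
    trace[it + 1L] <- f
    g <- grad_of(rho, sigma)
    if (verbose) cat(sprintf("iter %3d  F = %.6e  (rel %.2e)\n", it, f, rel))
    if (rel >= 0 && rel < tol) { converged <- TRUE; break }
  }
  structure(list(rho = rho, sigma = sigma, sigma_hat = sh,
                 objective = trace[seq_len(it + 1L)], iterations = it,
                 converged = converged, mu = mu, scale = scale,
                 n_modes = length(md$P)),
            class = "rim_fit")
}

#' @export
print.rim_fit <- function(x, ...) {
  cat(sprintf("<rim_fit> %d x %d, %d iters (%s), F = %.4e, %d spectral mode pairs\n",
              nrow(x$rho), ncol(x$rho), x$iterations,
              if (x$converged) "converged" else "max_iters", tail(x$objective, 1),
              x$n_modes))
  invisible(x)
}

#' Super-resolved EDF-RIM reconstruction from a speckled stack
#'
#' The full inversion: Wiener-prefilter the raw images (`eta`), estimate the
#' empirical per-pixel standard deviation, build the theoretical variance
#' model from the speckle auto-covariance and the prefiltered EDF PSF, and
#' minimize the Tikhonov-regularized variance-matching objective. The
#' initial iterate is the clipped deconvolved widefield image.
#'
#' @param stack a [speckle_stack()]
#' @param pupil the illumination/detection [make_pupil()] (rebuilt from stack
#'   metadata when `NULL`)
#' @param gamma centered speckle auto-covariance; default the analytic model
#'   from the pupil ([speckle_autocov_model()])
#' @param gamma_measured optional measured auto-covariance whose Fourier
#'   support masks the model's power spectrum before use
#' @param mu Tikhonov weight (1e-5 matches the experimental setting)
#' @param eta Wiener prefilter regularization (1e-3)
#' @param max_iters,tol,tau optimizer controls, see [rim_fit()]
#' @param window Tukey cosine fraction applied to the raw images (0.2 for
#'   experimental-style data; 0, the default, for periodic simulations)
#' @param init optional initial density
#' @return an object of class `rim_recon`: the [rim_fit()] result plus the
#'   deconvolved widefield baseline and the parameters used
#' @export
reconstruct_rim <- function(stack, pupil = NULL, gamma = NULL,
                            gamma_measured = NULL, mu = 1e-5, eta = 1e-3,
                            max_iters = 200L, tol = 1e-6, tau = 1e-6,
                            window = 0, init = NULL) {
  stopifnot(inherits(stack, "speckle_stack"))
  if (is.null(pupil)) pupil <- pupil_from_stack(stack)
  psf <- compute_psf3d(pupil, stack$grid)
  edf <- compute_edf_psf(psf)
  flt <- make_wiener(edf, eta)
  if (is.null(gamma))
    gamma <- speckle_autocov_model(pupil, stack$grid,
                                   envelope_sigma = stack$optics$envelope_sigma)
  if (!is.null(gamma_measured))
    gamma <- match_gamma_support(gamma, gamma_measured, tau)
  sigma_hat <- empirical_std(stack, flt, window)
  wf <- deconvolve_widefield(stack, edf_psf = edf, window = window)
  if (is.null(init)) init <- pmax(wf, 0)
  fit <- rim_fit(sigma_hat, gamma, flt, mu = mu, init = init,
                 max_iters = max_iters, tol = tol, tau = tau)
  structure(c(fit, list(widefield = wf, eta = eta, window = window,
                        pupil = pupil)),
            class = c("rim_recon", "rim_fit"))
}

# Rebuild the pupil recorded in a stack's acquisition metadata.
pupil_from_stack <- function(stack) {
  o <- stack$optics
  if (is.null(o$na) || is.null(o$wavelength_nm))
    stop("stack has no usable optics metadata; pass `pupil` explicitly")
  kind <- if (!is.null(o$kind) && o$kind == "annulus") "annulus" else "disc"
  make_pupil(o$na, o$wavelength_nm, stack$grid, kind,
             if (kind == "annulus") o$inner_fraction else 0)
}

#' Mask a model auto-covariance to a measured Fourier support
#'
#' Zeroes every spectral mode of the model covariance where the measured
#' covariance carries no power (below `tol` of its spectral maximum), so the
#' theoretical variance only uses frequencies the experiment actually
#' delivered.
#'
#' @param gamma_model,gamma_measured centered covariance slices
#' @param tol relative support threshold
#' @return centered covariance matrix
#' @export
match_gamma_support <- function(gamma_model, gamma_measured, tol = 1e-6) {
  Pm <- Re(fft2(ifftshift2(gamma_model)))
  Pe <- Re(fft2(ifftshift2(gamma_measured)))
  Pm[Pe < tol * max(Pe)] <- 0
  fftshift2(Re(ifft2(Pm)))
}

#' Deconvolved EDF-widefield baseline
#'
#' The mean of the raw images, Wiener-deconvolved with the EDF PSF at the
#' baseline regularization `eta = 2e-4`. This is the diffraction-limited
#' image the variance-matching reconstruction is compared against.
#'
#' @param stack a [speckle_stack()] (a single image is accepted)
#' @param edf_psf the [compute_edf_psf()] of the acquisition (rebuilt from
#'   stack metadata when `NULL`)
#' @param eta Wiener regularization (default 2e-4)
#' @param window Tukey cosine fraction applied to the mean image (0 = none)
#' @return deconvolved image matrix
#' @export
deconvolve_widefield <- function(stack, edf_psf = NULL, eta = 2e-4, window = 0) {
  images <- if (inherits(stack, "speckle_stack")) stack$images else stack
  mean_img <- if (length(dim(images)) == 3L) rowMeans(images, dims = 2L)
              else images
  if (is.null(edf_psf)) {
    pupil <- pupil_from_stack(stack)
    edf_psf <- compute_edf_psf(compute_psf3d(pupil, stack$grid))
  }
  if (window > 0)
    mean_img <- mean_img * tukey_window(nrow(mean_img), ncol(mean_img), window)
  wiener_filter(mean_img, edf_psf, eta)
}

#' Rolling-ball background removal
#'
#' Estimates a smooth background as the grayscale opening of the image with a
#' spherical-cap structuring element of the given radius and subtracts it;
#' the result is clipped at zero. Features narrower than the ball are
#' preserved, offsets and slowly varying backgrounds are removed. The radius
#' should comfortably exceed the PSF full width at half maximum.
#'
#' @param image 2D image matrix
#' @param radius ball radius in pixels
#' @return background-corrected image (same shape, >= 0)
#' @export
rolling_ball_background <- function(image, radius) {
  stopifnot(radius >= 1)
  bg <- rolling_ball_cpp(image, radius)
  pmax(image - bg, 0)
}
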