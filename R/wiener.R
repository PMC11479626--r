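# Wiener pre-filtering and the prefiltered (effective) EDF PSF.

#' Build a Wiener filter from an EDF PSF
#'
#' The transfer function is `g = conj(h) / (|h|^2 + eta)` where `h` is the
#' OTF of the extended-depth PSF. The filter amplifies attenuated in-band
#' frequencies and suppresses everything beyond the incoherent cutoff
#' `2 NA / lambda`. The effective PSF `h_perp * g` (the kernel the variance
#' model must use after prefiltering) is cached, with its transfer function
#' `|h|^2 / (|h|^2 + eta)`.
#'
#' @param edf_psf a [compute_edf_psf()] object
#' @param eta regularization scalar (> 0); 1e-3 for the RIM prefilter,
#'   2e-4 for the widefield deconvolution baseline
#' @return an object of class `wiener_filter`: `transfer` (complex, DC at
#'   \[1, 1\]), `effective_otf` (real), `effective_psf` (centered real),
#'   `eta`
#' @export
make_wiener <- function(edf_psf, eta = 1e-3) {
  stopifnot(inherits(edf_psf, "edf_psf"), eta > 0)
  h <- edf_psf$otf
  denom <- Mod(h)^2 + eta
  transfer <- Conj(h) / denom
  eff_otf <- Mod(h)^2 / denom
  structure(list(eta = eta, transfer = transfer, effective_otf = eff_otf,
                 effective_psf = fftshift2(Re(ifft2(eff_otf))),
                 edf_psf = edf_psf),
            class = "wiener_filter")
}

#' Apply a Wiener filter to an image
#'
#' @param image 2D image matrix
#' @param edf_psf a [compute_edf_psf()] object, or a prebuilt
#'   [make_wiener()] filter
#' @param eta regularization scalar (ignored when a filter object is given)
#' @return filtered image (real matrix)
#' @examples
#' # eta -> Inf drives the output to zero; eta -> 0 with a flat OTF is identity
#' @export
wiener_filter <- function(image, edf_psf, eta = 1e-3) {
  flt <- if (inherits(edf_psf, "wiener_filter")) edf_psf
         else make_wiener(edf_psf, eta)
  Re(ifft2(fft2(image) * flt$transfer))
}

#' @export
print.wiener_filter <- function(x, ...) {
  cat(sprintf("<wiener_filter> eta=%g, max|g|=%.3f\n", x$eta, max(Mod(x$transfer))))
  invisible(x)
}
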