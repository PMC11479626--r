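# FFT helpers. Convention (used everywhere in the package):
#   - frequency arrays have DC at index [1, 1] (R's fft layout);
#   - real-space kernels (PSFs, covariances) are stored "centered", i.e. the
#     origin sits at pixel (floor(n/2) + 1); ifftshift moves it to [1, 1]
#     before a transform, fftshift moves it back for display/storage.

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Discrete Fourier transform sample frequencies
#'
#' @param n number of samples
#' @param d sample pitch (nm)
#' @return numeric vector of length `n`, cycles per nm, DC first (R fft order)
#' @keywords internal
fftfreq <- function(n, d = 1) {
  k <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

# Index vector that rotates a length-n axis so the centered origin
# (floor(n/2)+1) lands on 1 (ifftshift) or the reverse (fftshift).
shift_idx <- function(n, inverse = FALSE) {
  h <- floor(n / 2)
  if (inverse) c(seq.int(n - h + 1L, n), seq_len(n - h)) # fftshift
  else c(seq.int(h + 1L, n), seq_len(h))                 # ifftshift
}

fftshift2 <- function(x) x[shift_idx(nrow(x), TRUE), shift_idx(ncol(x), TRUE), drop = FALSE]

ifftshift2 <- function(x) x[shift_idx(nrow(x)), shift_idx(ncol(x)), drop = FALSE]

# Centered pixel coordinates along one axis (origin at floor(n/2)+1), in nm.
centered_coords <- function(n, d) (seq_len(n) - 1L - floor(n / 2)) * d

#' Tukey (tapered cosine) window
#'
#' Separable 2D Tukey window with cosine fraction `r`; `r = 0` is rectangular,
#' `r = 1` is a Hann window. Used to damp the Gibbs phenomenon on
#' experimental-style images before Fourier filtering.
#'
#' @param n1,n2 window dimensions in pixels
#' @param r cosine fraction in \[0, 1\]
#' @return `n1 x n2` matrix with values in \[0, 1\]
#' @export
tukey_window <- function(n1, n2 = n1, r = 0.2) {
  stopifnot(r >= 0, r <= 1)
  w1 <- tukey_1d(n1, r)
  w2 <- tukey_1d(n2, r)
  outer(w1, w2)
}

tukey_1d <- function(n, r) {
  if (n == 1L) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  if (r > 0) {
    lo <- x < r / 2
    hi <- x >= 1 - r / 2
    w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / r - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / r - 2 / r + 1)))
  }
  w
}

# Circular 2D convolution of a real image with a centered real kernel,
# both n1 x n2. Returns a real matrix.
conv2_circ <- function(image, kernel_centered) {
  Re(ifft2(fft2(image) * fft2(ifftshift2(kernel_centered))))
}

# As above but with the kernel already transformed (DC at [1,1]).
conv2_tf <- function(image, kernel_tf) {
  Re(ifft2(fft2(image) * kernel_tf))
}
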