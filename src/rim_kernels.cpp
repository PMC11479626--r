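// Spectral kernels for the variance-matching reconstruction.
//
// The theoretical EDF variance is a quadratic form in the density rho:
//   sigma^2(r) = sum_k P(k) | [(rho . e_k) * h_eff](r) |^2
// where P(k) >= 0 is the discrete power spectrum of the speckle
// auto-covariance Gamma (divided by N^2), e_k(r) = exp(-2i pi k.r / n) and
// h_eff is the Wiener-prefiltered EDF PSF. Because Gamma is real and even,
// modes come in conjugate pairs (k, -k) with identical contributions; the R
// side passes one representative per pair with weight 2 (weight 1 for
// self-paired modes), which halves the FFT count.
//
// Gradient of the data term F = sum_r (sigma_hat - sigma)^2 with respect to
// rho(p):
//   dF/drho(p) = sum_k 2 P(k) Re{ e_k(p) d_k(p) },
//   d_k = IFFT( FFT(W . conj(c_k)) . conj(Heff) ),  W = (sigma - sigma_hat)/sigma
// with c_k = IFFT( shift(rho_hat, k) . Heff ). Both passes recompute c_k
// rather than caching K complex images.

#include <RcppArmadillo.h>
using namespace arma;

static cx_mat shifted_product(const cx_mat& rho_hat, const cx_mat& H,
                              const int kx, const int ky) {
  const int nx = rho_hat.n_rows, ny = rho_hat.n_cols;
  cx_mat out(nx, ny);
  for (int j = 0; j < ny; ++j) {
    const int jj = (j + ky) % ny;
    for (int i = 0; i < nx; ++i) {
      const int ii = (i + kx) % nx;
      out(i, j) = rho_hat(ii, jj) * H(i, j);
    }
  }
  return out;
}

// unit roots e^{-2i pi k x / n}, x = 0..n-1
static cx_vec mode_phase(const int n, const int k) {
  cx_vec v(n);
  const double w = -2.0 * datum::pi * double(k) / double(n);
  for (int i = 0; i < n; ++i)
    v(i) = cx_double(std::cos(w * i), std::sin(w * i));
  return v;
}

// [[Rcpp::export]]
arma::mat rim_sigma2_cpp(const arma::mat& rho, const arma::cx_mat& Heff,
                         const arma::ivec& kx, const arma::ivec& ky,
                         const arma::vec& P, const arma::vec& weight) {
  const cx_mat rho_hat = fft2(conv_to<cx_mat>::from(rho));
  mat sigma2(rho.n_rows, rho.n_cols, fill::zeros);
  for (uword m = 0; m < P.n_elem; ++m) {
    const cx_mat c = ifft2(shifted_product(rho_hat, Heff, kx(m), ky(m)));
    sigma2 += (weight(m) * P(m)) * square(abs(c));
  }
  return sigma2;
}

// [[Rcpp::export]]
arma::mat rim_grad_cpp(const arma::mat& rho, const arma::mat& W,
                       const arma::cx_mat& Heff,
                       const arma::ivec& kx, const arma::ivec& ky,
                       const arma::vec& P, const arma::vec& weight) {
  const int nx = rho.n_rows, ny = rho.n_cols;
  const cx_mat rho_hat = fft2(conv_to<cx_mat>::from(rho));
  const cx_mat Hc = conj(Heff);
  const cx_mat Wc = conv_to<cx_mat>::from(W);
  mat grad(nx, ny, fill::zeros);
  for (uword m = 0; m < P.n_elem; ++m) {
    const cx_mat c = ifft2(shifted_product(rho_hat, Heff, kx(m), ky(m)));
    const cx_mat d = ifft2(fft2(Wc % conj(c)) % Hc);
    const cx_vec ex = mode_phase(nx, kx(m));
    const cx_vec ey = mode_phase(ny, ky(m));
    const double a = 2.0 * weight(m) * P(m);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        grad(i, j) += a * std::real(ex(i) * ey(j) * d(i, j));
  }
  return grad;
}

// Rolling-ball background: grayscale opening with a spherical-cap
// structuring element of radius r (pixels). bg = dilate(erode(img)).
// [[Rcpp::export]]
arma::mat rolling_ball_cpp(const arma::mat& img, const double radius) {
  const int nx = img.n_rows, ny = img.n_cols;
  const int r = (int)std::floor(radius);
  const int w = 2 * r + 1;
  mat ball(w, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < w; ++i) {
      const double d2 = double((i - r) * (i - r) + (j - r) * (j - r));
      ball(i, j) = (d2 <= radius * radius)
        ? std::sqrt(radius * radius - d2) : -datum::inf;
    }
  mat er(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double mn = datum::inf;
      for (int dj = -r; dj <= r; ++dj) {
        const int jj = j + dj;
        if (jj < 0 || jj >= ny) continue;
        for (int di = -r; di <= r; ++di) {
          const int ii = i + di;
          if (ii < 0 || ii >= nx) continue;
          const double b = ball(di + r, dj + r);
          if (!std::isfinite(b)) continue;
          const double v = img(ii, jj) - b;
          if (v < mn) mn = v;
        }
      }
      er(i, j) = mn;
    }
  mat bg(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double mx = -datum::inf;
      for (int dj = -r; dj <= r; ++dj) {
        const int jj = j + dj;
        if (jj < 0 || jj >= ny) continue;
        for (int di = -r; di <= r; ++di) {
          const int ii = i + di;
          if (ii < 0 || ii >= nx) continue;
          const double b = ball(di + r, dj + r);
          if (!std::isfinite(b)) continue;
          const double v = er(ii, jj) + b;
          if (v > mx) mx = v;
        }
      }
      bg(i, j) = mx;
    }
  return bg;
}
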