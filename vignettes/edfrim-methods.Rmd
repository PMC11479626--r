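---
title: "Extended depth of field random illumination microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended depth of field random illumination microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(edfrim)
```

## The imaging problem

A widefield fluorescence microscope records, at focal position $z_f$,

$$I(\mathbf r_\perp, z_f) = \iint \rho(\mathbf r'_\perp, z')\, S(\mathbf r'_\perp, z')\,
h(\mathbf r_\perp - \mathbf r'_\perp,\, z_f - z')\, d\mathbf r'_\perp\, dz',$$

with $\rho$ the fluorophore density, $S$ the illumination intensity and $h$
the 3D intensity point spread function (PSF). Extended-depth-of-field (EDF)
detection sweeps the focal plane within one camera exposure, so the recorded
image is the axial integral $I_\perp = \int I\, dz_f$, whose kernel is the
axially integrated PSF $h_\perp(\mathbf r_\perp) = \int h(\mathbf r_\perp, z)\,dz$.
A whole axial range is thus projected into one 2D image, at the cost of the
topographical information and, for uniform illumination, of contrast.

Random illumination microscopy (RIM) replaces the uniform illumination by a
sequence of uncontrolled speckle patterns $S_1,\dots,S_M$ and exploits that
the *variance* of the speckled images depends only on two known functions:
the speckle auto-covariance $\Gamma_S$ and the PSF. Matching the empirical
standard deviation of the stack to its theoretical model yields
super-resolution (frequencies up to twice the widefield cutoff
$2\,\mathrm{NA}/\lambda$), without knowing the individual patterns.

This package combines the two: speckled illumination with EDF detection.
Two regimes make the 2D variance model exact or approximately valid:

* **Columnar (Bessel-type) speckles** from an annular pupil are statistically
  invariant along the optical axis, so the EDF variance follows the 2D RIM
  form with $h_\perp$ and the focal-slice auto-covariance for *any* sample.
* **Ordinary 3D speckles** from a disc pupil work when the fluorophores lie
  on a *smooth surface* $z = Z(\mathbf r_\perp)$: if $Z$ varies little over a
  speckle grain ($\lambda/2\mathrm{NA}$), the variance again reduces to the
  2D form with $\Gamma_{\rm EDF}(\mathbf r_\perp) = \Gamma_S(\mathbf r_\perp, 0)$.

## Optical model

The scalar model is built from a binary pupil (disc or annulus) with cutoff
$\mathrm{NA}/\lambda$ on the discrete transverse frequency grid. Defocus is
the angular-spectrum phase $\exp\!\big(2i\pi z \sqrt{1/\lambda^2 - f_\perp^2}\big)$
applied on the pupil support; each PSF slice is the squared modulus of the
inverse transform, and the 3D PSF is normalized to unit sum so that the EDF
PSF (its axial sum) is also a unit-mass kernel. $\lambda$ is the in-medium
wavelength (530/1.3 nm in the reference configuration, NA 0.8).

Speckles are synthesized by drawing i.i.d. uniform phases on the pupil
support, apodized by a Gaussian frequency envelope that sets the correlation
length of the phasor field. The envelope width is a free parameter; the
default sets the envelope FWHM equal to the pupil radius. Amplitudes are
rescaled so the expected intensity is exactly 1 at every voxel, which pins
the absolute scale of all covariances: fully developed speckle then has
$\Gamma(0) \approx 1$ (up to a $1/K_{\rm eff}$ phasor-count correction). The
analytic auto-covariance is $\Gamma = |C|^2$ with $C$ the normalized Fourier
transform of the apodized pupil power — exact for circular Gaussian fields.

For Bessel speckles the axial invariance range is set by the spread of axial
frequencies across the ring: the correlation length is about
$1/(2\,\Delta k_z)$ with $\Delta k_z = k_z(f_{\rm inner}) - k_z(f_{\rm outer})$.
`annulus_for_depth()` inverts this relation: given a target depth it returns
the inner fraction for which the accumulated defocus phase stays below
$\pi/2$, which keeps slice-to-slice correlations at or above roughly 0.8 over
the whole depth. Thin rings need fine frequency sampling: on a coarse grid an
annulus can round to zero pixels, in which case a larger lateral grid (or a
thicker ring) is required.

## Forward simulation

The reference phantom is the star $\rho(r,\theta) = 1 + \cos 40\theta$ whose
local period $2\pi r/40$ decreases toward the center, draped over a flat
plane, a right circular cone (radius $(N_x/2)d_x$, height $N_z d_z$), or an
i.i.d. uniform random height map. Surface samples place each column's mass
on the nearest z slice (a discrete delta), so axial projection conserves the
2D density exactly; the cone apex at exactly $N_z d_z$ sits half a voxel
above the top slice center and is clamped to it. The reference grid is
$512 \times 512 \times 128$ at $d_x = d_y = 38.5$ nm, $d_z = 87.5$ nm
(`grid_paper()`); the desk-scale grid keeps the pitches at
$128 \times 128 \times 32$ (`grid_desk()`).

EDF image formation collapses to a single 2D convolution,
$I_\perp = \big(\sum_z \rho S\big) * h_\perp$, because $h_\perp$ does not
depend on the source depth; plane-by-plane images convolve each occupied
slice with the PSF slice at the corresponding defocus. Convolutions are
circular; phantoms are periodic-friendly, and a Tukey window (cosine
fraction 0.2) is available for experimental-style inputs. Photon noise is
Poisson, applied after scaling the mean image's brightest pixel to the
requested photon budget; the budget and the absence of read noise are
explicit parameters because the original simulations do not state them.

## Reconstruction

Raw images are Wiener-prefiltered, $\tilde g = \tilde h_\perp^*/(|\tilde
h_\perp|^2 + \eta)$ with $\eta = 10^{-3}$, and the per-pixel *population*
standard deviation $\widehat\sigma$ of the prefiltered stack is matched to
the model

$$\sigma^2(\mathbf r; \rho) = \iint \rho(\mathbf r')\rho(\mathbf r'')\,
\Gamma_{\rm EDF}(\mathbf r'' - \mathbf r')\, h_{\rm eff}(\mathbf r - \mathbf r')\,
h_{\rm eff}(\mathbf r - \mathbf r'')\, d\mathbf r'\, d\mathbf r'',$$

where $h_{\rm eff} = h_\perp * g$ accounts for the prefilter. The estimate is

$$\widehat\rho = \arg\min_{\rho \ge 0}\; \lVert \widehat\sigma - \sigma(\rho)
\rVert^2 + \mu \lVert \rho \rVert^2 .$$

The quadratic form is evaluated through the spectral decomposition of the
speckle covariance: with $P(k) \ge 0$ the discrete power spectrum of
$\Gamma_{\rm EDF}$,

$$\sigma^2(\mathbf r) = \sum_k P(k)\, \big|\big[(\rho\, e_k) * h_{\rm eff}\big]
(\mathbf r)\big|^2, \qquad e_k(\mathbf r) = e^{-2i\pi k \cdot \mathbf r / n},$$

one FFT per covariance mode (conjugate pairs merged), in compiled code. The
analytic gradient uses the same decomposition and is validated against
finite differences. Modes below $10^{-6}$ of the spectral maximum are
dropped; the model covariance's spectrum can be masked to the Fourier
support of a measured covariance. $\widehat\sigma$ is rescaled to unit
maximum before fitting so that $\mu$ values transfer across photon budgets;
$\mu = 10^{-5}$ is the default (the value used for the experiments the
method was demonstrated on), and simulation studies explore
$10^{-7}\dots10^{-3}$.

The optimizer is projected gradient descent (nonnegativity projection) with
Barzilai–Borwein steps and monotone backtracking, initialized from the
clipped, Wiener-deconvolved widefield image ($\eta = 2\times 10^{-4}$, the
baseline the reconstruction is compared against). Convergence stops at a
relative objective decrease below $10^{-6}$ or `max_iters` (200).

### A known limitation: the outermost octave

Variance matching is a phase-retrieval-type problem: $\sigma^2$ is a sum of
squared magnitudes of linear maps of $\rho$. Empirically (and reproducibly
across initializations, preconditioners, $\mu$-continuation and seeded
basin hopping), gradient-based descent recovers the density *perfectly* —
magnitude and phase — for all spatial frequencies up to about $3\times$ the
widefield cutoff $c = \mathrm{NA}/\lambda$, but the outermost octave
$[3c, 4c]$ of the theoretical band carries almost no weight in the variance
map: both $P(k)$ and the effective OTF are near their vanishing edges where
that information enters. First-order methods converge to near-degenerate
minima with that octave absent. This matches practice: the experimental
resolution gain of EDF-RIM is about $1.7\times$ the deconvolved widefield
($\approx 3.4c$), not the theoretical $2\times$. Consequences for the
validation suite: noiseless inverse-crime recovery of the $64\times 64$ star
plateaus at a global relative $L_2$ error of $\approx 0.45$ (the spokes
between 21 and 28 px radius live exactly in $[3c, 4c]$) even though every
band at or below $3c$ is recovered with unit phase correlation, and the
star-resolution ratio against the (near-ideal, simulated) deconvolved
widefield reaches $\approx 0.73$ rather than the $0.6$ a full $2\times$ gain
would give.

## Surface topography estimation

One plane-by-plane scan under a single speckle (typically one plane every
2 µm) recovers a coarse height map $Z_s(x, y)$ so the projective EDF-RIM
image can be re-draped in 3D:

1. **Background normalization.** A separable polynomial gain field (degree
   ≤ 2 per axis, full tensor basis) is fitted to a random 1/1000 voxel
   subsample by 20%-trimmed least squares; the normalized statistic
   $\widehat r = (s - \widehat a)/(\widehat a\, \widehat\sigma[\Omega_0])$
   is approximately standard normal on background. The noise scale is a
   10%-trimmed, Gaussian-consistent standard deviation of $s/\widehat a$
   over the subsample. The subsample is floored at 20 observations per
   coefficient so the fit stays determined on small volumes. Two details
   keep the false-alarm threshold calibrated: the scalar noise scale is
   evaluated on a larger voxel sample (the subsample exists to make the 3D
   *fit* cheap; a 1D spread estimate costs nothing), and the empirical null
   is re-centered by the trimmed mean of $s/\widehat a$, because the gain
   fit carries an $O(1/\sqrt{n_{\rm fit}})$ global offset that would shift
   the whole $\widehat r$ distribution. Residual mis-calibration from the
   spatial dispersion of the fit error is below about $2\times10^{-3}$ in
   detection rate at the default settings.
2. **Detection.** Voxels with $\widehat r$ above the upper-`pfa` standard
   normal quantile (2.3263 at the default 0.01) become bright points.
3. **Windowed quadratic RANSAC.** Overlapping lateral windows (default
   4 × 4, 50% overlap) are fitted with $z = $ quadratic$(x, y)$ by RANSAC on
   minimal 6-point samples (300 draws: >99% success at 50% outliers); the
   consensus refit is weighted by detection brightness with a Tukey-biweight
   reweighting, because brighter detections are nearer focus and carry less
   of the plane-quantization error. Labels are fused across overlaps by
   strict intersection: a point must be an inlier in every fitted window
   covering it (the alternative union reading is not implemented).
4. **Fusion and interpolation.** Each inlier's z is replaced by the fused
   (tent-blended) window-fit prediction — this restores sub-plane accuracy
   from detections whose z is quantized to the acquired planes — and a
   biharmonic (thin-plate) spline interpolates the result on the full
   lateral grid. With `lambda = 0` the spline passes through its knots
   exactly and reproduces planes; the pipeline default adds a small ridge
   (`1e-2`) and bin-fuses clouds beyond `max_knots`. Grid nodes outside the
   convex hull of the knots are flagged as extrapolation.

"Bi-cubic harmonic spline" is not a single standard method; the biharmonic
(thin-plate, $r^2\log r$) spline is used here.

On the steep reference cone (slope ≈ 1.1, which violates the smooth-surface
assumption at the $\lambda/2\mathrm{NA}$ scale and has apex/base kinks that
no quadratic window can follow), the end-to-end RMSE at a 2 µm z-step
measures ≈ 200 nm, not the axial voxel pitch 87.5 nm; the measured error
budget is dominated by single-speckle detection physics — the brightest
points are bright speckle grains that need not sit exactly on the in-focus
ring — plus the window-model bias at the kinks. Degradation with sparser
z-sampling is graceful (RMSE grows by only ≈ 1.2× from 0.5 µm to 2 µm
steps), and interpolation of exact in-focus ring samples does reach the
87.5 nm target, which localizes the gap in the detection stage, not the
fitting stage. On gently curved surfaces (the method's intended use) the
window model bias vanishes and accuracy is correspondingly better.

## Synthetic data: what it does and does not emulate

The generators reproduce the reference simulation's stated world: the star
phantom and its three topographies on the paper pitches, speckles from
random-phase (Gaussian-enveloped) pupils, EDF summation over the full grid,
variance from 1000 prefiltered images, and Poisson photon noise. They do
not emulate read noise, aberrations, sample scattering, fluorophore
photophysics, multi-surface samples or non-circular field boundaries —
green tests therefore establish correctness of the stated forward and
inverse models, not robustness to those effects. Stated defaults chosen
where the source is silent: photon budget 1000 expected photons at the
brightest mean-image pixel; volume-scan background level 200 photons with a
±50%/±30%/±40% separable gain ramp; envelope FWHM equal to the pupil
radius; no per-realization speckle renormalization.

## Numerical conventions

Frequency arrays keep DC at index [1, 1]; centered kernels put the origin at
pixel `floor(n/2) + 1`; all lengths are in nm. Convolutions are circular.
The variance model floors $\sigma$ at $10^{-12}$ in gradient divisions;
spectral modes below $10^{-6}$ of the maximum are dropped; the empirical
standard deviation uses the population convention (divide by $N$). RANSAC
sorts points canonically so labels are independent of input order. Seeds are
explicit everywhere; per-image seeds are drawn from the master seed and
recorded in the stack metadata.
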