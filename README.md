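# edfrim

Extended depth of field random illumination microscopy (EDF-RIM) in R:
simulation, super-resolved reconstruction, and surface-topography estimation.

## The problem

Imaging a fluorescent structure that folds through a 3D volume — an
epithelium, a cell cortex — normally forces a choice between speed (one
extended-depth exposure that projects the whole depth into a single 2D image,
but with diffraction-limited resolution and heavy background) and resolution
(slow plane-by-plane super-resolution imaging). EDF-RIM removes the choice:
the sample is illuminated by a sequence of random speckle patterns while the
detection sweeps the focal range within each exposure. The *variance* of the
speckled EDF images depends only on two known functions — the speckle
auto-covariance Γ and the extended-depth PSF h⊥ — so matching the empirical
standard deviation of the stack to its theoretical model

ρ̂ = argmin_{ρ≥0} ‖σ̂ − σ(ρ; Γ, h⊥∗g)‖² + μ‖ρ‖²

recovers the projected fluorophore density ρ with frequencies up to twice
the widefield cutoff 2NA/λ, without knowing the individual speckles. The
package implements the whole chain for two illumination regimes: ordinary 3D
speckles (valid for samples on a smooth surface) and Bessel-type speckles
from an annular pupil (axially invariant, valid for any sample). A companion
pipeline estimates the surface height map Z_s(x, y) from one plane-by-plane
scan under a single speckle — robust background normalization, false-alarm
thresholded bright-point detection, windowed quadratic RANSAC, thin-plate
spline — so the projective super-resolved image can be re-draped in 3D.

Audience: microscopists and methods developers who want to simulate,
prototype, or analyze speckle-based super-resolution with extended depth of
field.

## Worked example

```r
library(edfrim)

grid  <- grid_desk()  # 128 x 128 x 32 voxels at dx = 38.5 nm, dz = 87.5 nm
pupil <- make_pupil(na = 0.8, wavelength = 530 / 1.3, grid)
star  <- make_star_density(grid, n_lobes = 40)           # 1 + cos(40 theta)
sample <- embed_on_surface(star, make_topography(grid, "flat"), grid)

stack <- simulate_acquisition(sample, pupil, n_speckles = 200,
                              photon_budget = 1000, modality = "edf", seed = 1)
rec <- reconstruct_rim(stack, pupil = pupil, mu = 1e-5, eta = 1e-3,
                       max_iters = 80)   # ~2.5 min on one CPU
wf  <- deconvolve_widefield(stack, eta = 2e-4)

star_resolution(rec$rho, 40, dx = 38.5)
#> <resolution_report> 40 lobes: min resolved radius 1213 nm (period 190 nm, cutoff 0.00525 /nm) at contrast >= 0.1
star_resolution(pmax(wf, 0), 40, dx = 38.5)
#> <resolution_report> 40 lobes: min resolved radius 1617 nm (period 254 nm, cutoff 0.00394 /nm) at contrast >= 0.1
```

The Siemens-star readout finds the innermost radius at which the 40 spokes
are still resolved (modulation contrast ≥ 0.1). The deconvolved widefield
baseline resolves spokes down to its diffraction cutoff (254 nm local
period ≈ λ/2NA); the variance-matching reconstruction pushes the resolved
period to 190 nm on the same data — a 1.33× gain at these 80 iterations,
approaching the method's practical ≈1.4× (radius ratio 0.73) when run to
convergence. Units are nm throughout; `rec$objective` holds the (monotone)
objective trace.

Topography from a plane-by-plane scan:

```r
tg   <- grid_geometry(96, 96, 128, dx = 154, dz = 87.5)
tp   <- make_pupil(0.8, 530 / 1.3, tg)
cone <- make_topography(tg, "cone")
vol  <- simulate_volume_scan(embed_on_surface(matrix(1, 96, 96), cone, tg),
                             tp, z_planes = seq(0, 11200, by = 2000),
                             photon_budget = 2000, seed = 1)
est  <- estimate_topography(vol, pfa = 0.01, fraction = 1/1000, seed = 1)
mesh <- project_onto_surface(matrix(1, 96, 96), est)  # drape an image in 3D
```

A command-line entry point wraps the same functions
(`inst/cli/edfrim.R`): `edfrim fixtures | simulate | reconstruct | topo |
project | evaluate`, TIFF in/out with JSON sidecar metadata.

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch at desk scale —
speckled acquisition of the star phantom, variance-matching reconstruction
against the deconvolved-widefield baseline, star-resolution readout, and
cone-topography recovery from a 2 µm-step volume scan — and writes its
(empty) target report as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The methods vignette (`vignettes/edfrim-methods.Rmd`) documents the optical
model, the variance-matching inversion and its known limitations, and every
default the simulators use.
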