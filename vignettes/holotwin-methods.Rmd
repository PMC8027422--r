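---
title: "holotwin: models and methods of the holographic digital twin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{holotwin: models and methods of the holographic digital twin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(holotwin)
```

`holotwin` is a hardware-free digital twin of an immersive micromanipulation
microscope: an instrument class that couples three-axis in-line digital
holographic microscopy (DHM) to holographic optical tweezers through a
closed software loop. Everything the optical bench does is replaced by a
physical model: a synthetic camera (the forward hologram model), a numerical
reconstruction engine, a segmentation/tracking stage, a spatial-light-
modulator (SLM) trap engine, a trap/imaging calibration, and an overdamped
Brownian dynamics simulator standing in for the sample. This vignette
records the models, their assumptions, the tunable parameters, and the
design decisions a maintainer would want explained.

## Coordinates, units, instrument geometry

Right-handed coordinates with z along the optical axis, z = 0 at the
coverslip (which is also the focal plane), gravity along -z. All lengths are
micrometres, times seconds, forces piconewtons. The imaging geometry is a
100x, NA 1.45 objective with a 512-pixel camera spanning a 56 um field of
view (pitch 56/512 = 0.109 um), and the canonical volumetric grid is
512 x 512 x 61 voxels over 56 x 56 x 20 um^3 (axial pitch 1/3 um). The
immersion medium is water (n = 1.33).

## Scalar optics

All propagation is scalar. `propagate()` implements the angular-spectrum
form of the Rayleigh--Sommerfeld diffraction integral: multiply the field's
FFT by `exp(i dz sqrt(k^2 - kx^2 - ky^2))`, zero the evanescent components,
and transform back. A Matsushima-style local-frequency limit removes the
transfer-function samples whose phase gradient exceeds the grid Nyquist
rate, which suppresses wrap-around aliasing at large propagation distances;
the reconstruction warns when more than half of the propagating band is
clipped at the requested depth. Vectorial effects at NA 1.45 are knowingly
ignored (the reconstructions the instrument performs are scalar
back-propagations), as is the finite spectral bandwidth of the LEDs.

The unit test for this kernel is a brute-force oracle: a direct double-loop
summation of the Rayleigh--Sommerfeld point-spread kernel over all source
pixels. A compact band-limited Gaussian emitter on a 4x zero-padded grid
(so the FFT's circular convolution reproduces the oracle's open aperture)
agrees with the FFT path to ~1e-9 relative error.

## Forward hologram model (the synthetic camera)

Each of the three colour channels is an independent in-line hologram: a
tilted unit-amplitude plane wave (wavelengths 0.630, 0.520, 0.460 um for
R, G, B) illuminates the scene at a common polar angle from azimuths 120
degrees apart, and each object scatters as a *thin phase object* on its own
z plane: transmission `t = exp(i (2 pi / lambda) (n_obj - n_med) tau(x, y))`
with `tau` the projected chord length through the sphere or spherocylinder.
The scattered packet `(t - 1) E_inc` is propagated to the focal plane, the
per-object contributions are summed (first Born, single scattering), and the
camera records `|E_inc + sum E_s|^2`, normalized to unit background mean.
Poisson shot noise at a configurable photon budget (default 1e4
photons/pixel) is seeded and reproducible. Mie scattering, multiple
scattering, shadowing of stacked objects, camera MTF and Bayer demosaicing
are deliberately out of model.

The illumination tilt polar angle is not a published property of this
instrument class; the package defaults to 20 degrees. We checked the twin's
point-spread function at 20-35 degrees and found the reconstructed lateral
and axial widths essentially unchanged (the axial sharpening comes from the
overlap, not from the particular tilt), so the default is not a sensitive
parameter.

Object materials default to silica (n = 1.45, 2.0 g/cm^3), polystyrene
(1.59, 1.05) and an E. coli body (1.39, 1.10); all per-object overridable.

## Reconstruction

For each channel the background-subtracted contrast `H - 1` is treated as
the demodulated estimate of the scattered field in the focal plane (with a
tilted reference `R`, `H - 1 = R* S + R S*`, both terms carrier-free). The
volume is built by propagating this contrast to every z plane with the
angular-spectrum kernel evaluated *about the channel's illumination
carrier*, `exp(i z kz(k + k0))`. The linear term of `kz` about the carrier
is exactly the geometric shear `-z tan(theta)` along the tilt azimuth, so
this one operator both refocuses the tilted beam without paraxial
astigmatism and lands a scatterer at (x, y, z) at (x, y, z) in every
channel; `compensate_tilt = FALSE` exposes the uncompensated, sheared
reconstruction for diagnostics. Voxel values are squared moduli. The twin
image and DC terms are not explicitly removed, as in standard in-line DHM;
they are handled downstream by thresholding, and the three-channel overlap
suppresses them further because each channel's artifacts shear along its
own azimuth.

The overlap operator is not uniquely defined by the instrument class (sum,
minimum and product are all defensible). The package default is the
voxelwise geometric mean of the min-max-normalized channel volumes
(equivalently a renormalized product), which suppresses the single-channel
axial elongation most aggressively; a voxelwise minimum is available via
`overlap_volumes(method = "min")`. The choice was fixed before any
benchmark was run and not revisited.

Measured on the default grid, the twin's point-like-scatterer response has
0.33 um lateral and 0.50 um axial FWHM, and the overlap centroid of a
1-um-diameter sphere localizes to ~0.02 um laterally and ~0.05 um axially.
Two caveats worth knowing. First, the *argmax* of a single channel is
axially biased for strong phase objects (a micron silica sphere acts as a
ball lens whose bright focus sits downstream of the sphere; weak phase
objects bias the other way through twin-image interference); positions
should always be read from the intensity-weighted centroid of the
segmented overlap component, which is what `segment_volume()` reports.
Second, for 2-um strong-phase silica spheres the per-plane-maximum axial
profile of the overlap is not narrower than every single channel's -- the
lensing artifacts dominate that particular measure; for micron-scale
objects the overlap sharpens the axial response as designed.

## Segmentation, shape, tracking

`segment_volume()` thresholds at a fraction of the volume maximum (default
0.3), labels connected components under 26-connectivity (so diagonal
bacteria are not split), drops components below `min_voxels` (default 20,
which suppresses residual twin-image haze while keeping 1-um spheres at the
default pitch), and summarizes each component by intensity-weighted
moments. Length and width come from the second-moment eigenvalues as
`l = 4 sqrt(lambda1)`, `b = 4 sqrt((lambda2 + lambda3)/2)`; the factor 4 is
the full-extent convention for a uniform ellipsoid, and on an ideal
spherocylinder of l = 3, b = 1 the analytic moments give 3.12 -- a ~4%
convention bias accepted as part of the estimator. The orientation is the
principal eigenvector with its sign fixed by `ez >= 0` (a bacterium's head
and tail are not distinguishable). A small per-voxel smearing term
(`pitch^2 / 12` on the moment diagonal) keeps single-plane components
non-degenerate. Because the threshold is relative to the *global* volume
maximum, scenes mixing bright compact scatterers (silica beads) with dim
extended ones (cells) may need a lower `threshold_fraction` than the
default to keep the dim objects; both parameters are exposed in the run
configuration.

Tracking is greedy nearest-neighbour with a one-frame gap tolerance and a
closest-wins tie rule (ties are logged). This is adequate for desk-scale
scenes with few objects; it is not a crowded-field tracker.

`extract_mesh()` produces the live-display isosurface. It is implemented as
marching tetrahedra -- each cell is split into six tetrahedra about the main
diagonal (a Kuhn subdivision, face-consistent across cells) and each
tetrahedron contributes one or two linearly interpolated triangles. Unlike
table-driven marching cubes this variant has no ambiguous cases, so closed
components give watertight meshes (Euler characteristic 2 for a sphere;
area of an analytic sphere reproduced to well under 3%).

## Trap engine

The SLM model is a 512 x 512 phase-only modulator under unit-amplitude
illumination at 1.064 um. The per-trap kernel is the standard prism-and-lens
phasor `exp(i [(k/f)(x u + y v) + (k z / 2 f^2)(u^2 + v^2)])`; the
effective focal length is fixed by requiring the FFT of the SLM grid to
sample the trapping volume at the imaging pitch, so the addressable field
equals the 56 um field of view. Because the kernel is paraxial, the
verification propagator (`simulate_focal_field()`) uses the matching
paraxial Fresnel kernel (`propagate(kernel = "fresnel")`); using the exact
square-root kernel here would be inconsistent with the lens term.

`gsw_optimize()` is the weighted Gerchberg--Saxton loop: seeded
random-superposition start, per-iteration trap amplitudes
`V_m = (1/N) sum_j exp(i phi_j) conj(Delta_mj)`, weight update
`w_m <- w_m <|V|>/|V_m|`, rephase. Efficiency is `sum |V_m|^2`; uniformity
is `1 - (max - min)/(max + min)`. At the standard operating point (3
iterations, 10 random traps) the mean efficiency is ~0.79-0.80 with
uniformity ~0.95. When efficiency is measured on the simulated focal field,
each trap's windowed spot power is divided by the same window's capture
fraction for that trap's ideal single-trap mask (aperture correction);
without this the finite window would discount the spot's own diffraction
tails and an ideal single trap would not score 1. Phases can be quantized
to 256 levels (`quantize_8bit = TRUE`) to mimic an 8-bit SLM.

## Calibration

The trap-space/imaging-space map is `r' = T r + r0 + alpha z^2 zhat` -- a
linear operator, an offset, and an empirical quadratic axial term absorbing
spherical aberration. The model is linear in its 13 parameters, so
`fit_calibration()` is one stacked least-squares solve with per-parameter
standard errors (`tidy()`/`glance()` follow the usual model-object
conventions). The quadratic is taken to act on the *imaging-space* z (the
defining equation does not disambiguate this; the choice is flagged here),
and the inverse map solves the scalar quadratic in z by Newton iteration.
During simulated calibration scans the sample dynamics are frozen,
mirroring a scan at maximum laser power.

## Sample dynamics

Overdamped Langevin (Euler--Maruyama) per object: drift
`(F_trap + F_gravity+buoyancy)/gamma` with Stokes drag `gamma = 6 pi eta a`
(spherocylinders use the equivalent-volume sphere radius), plus Gaussian
noise of variance `2 D dt` per axis, `D = kB T / gamma`. Traps are harmonic
with stiffness kappa (default 5 pN/um) inside a capture radius (1.5 um) and
zero outside; both values are free parameters of the simulator, as the
instrument class does not publish trap stiffness. The coverslip is a
reflective wall at `z = radius`. A 1-um silica sphere sediments at the
Stokes closed-form 2.45 um/s to better than 0.1%, and a trapped particle's
stationary position variance matches equipartition `kB T / kappa` -- note
the Euler scheme requires `kappa dt / gamma < 1` (the loop warns
otherwise), and the equipartition check is run at dt = 0.1 ms because at
dt = 1 ms the scheme's O(theta dt) variance inflation (~18% at the default
stiffness) would dominate.

Swimmers are smooth (non-tumbling): constant speed (default 20 um/s) along
the orientation, wall-induced circling at omega = 1 rad/s below 2 um
height, plus small rotational diffusion (0.1 rad^2/s) so circles are
irregular but recognizable. At 20 um/s a cell crosses the 56 um field in
2.8 s.

## The closed loop

`run_closed_loop()` executes, per frame: render -> back-propagate ->
overlap -> segment -> track, applies any pending trap commands through the
calibration model (optionally compiling real GSW masks), and advances the
dynamics by `1/(fps dt)` sub-steps (40 fps and dt = 1 ms by default). The
network layers of the original instrument are replaced by in-process calls;
`inst/message-schema.md` documents equivalent wire messages for anyone
driving real hardware. Three demos reproduce the canonical experiments:
falling bodies (glass vs plastic spheres released at z = 10 um), the
eight-bead cube under rigid rotation, and fishing for a circling bacterium.

## Problem sizes and determinism

The default instrument grid (512^2 holograms, 61 planes) is used by the
benchmark script; the test suite exercises the same code mostly at 128-256
pixel grids and 10-50 random scenes per property, sizes chosen so the whole
suite completes in minutes while keeping every estimate's statistical error
well under the asserted tolerance. Every stochastic stage (shot noise, GSW
start, dynamics) draws from a named seed stream derived from one master
seed (`derive_seeds()`), so any run is bit-reproducible.

## What the synthetic data does and does not show

The generator emulates weak-phase scattering, tilted partially-overlapping
illumination geometry, shot noise and Brownian/swimming dynamics. It does
not emulate Mie resonances, multiple scattering between close objects,
aberrations, camera artifacts, or biological variability in cell shape and
motility. Tests passing on synthetic holograms therefore validate the
numerics and the closed-loop plumbing -- not performance on real
micrographs. One concrete consequence: the instrument class reports
failing to separate *features* closer than 0.5 um laterally and ~1 um
axially. The twin's point-source response (0.33/0.50 um FWHM) is consistent
with that resolution class, but a benchmark that sweeps two 1-um-diameter
spheres measures something different -- such spheres physically
interpenetrate below 1.0 um centre separation, so the twin's lateral
two-component transition sits at exactly the contact distance (1.0 um), and
along the axis the coherent overlap of two extended blobs keeps a single
component well beyond contact at the default threshold. The discrimination
benchmark is therefore an extended-object benchmark, and its numbers should
not be read as the point-feature resolution limits.

## Known limitations

Scalar optics; first-Born forward model (no shadowing between stacked
objects); greedy tracking; no hydrodynamic wall corrections to drag
(Faxen) or trap-trap optical crosstalk; the trap engine is paraxial by
construction; HDF5 containers are not provided -- volumes and fields
travel as multi-page float TIFF with JSON sidecars, meshes as ASCII
PLY/OBJ, models as JSON, tables as CSV.
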