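# holotwin

A hardware-free digital twin of an immersive holographic micromanipulation
microscope, for microscopists and instrument builders who want to develop
and test the *computational* half of such an instrument — reconstruction,
segmentation, trap-mask optimization, calibration and the closed
imaging/trapping loop — without a single piece of optical hardware.

The instrument being twinned couples two holographic technologies:

* **Three-axis in-line digital holographic microscopy.** Three collimated
  LEDs (R, G, B) illuminate the sample from three tilted directions; each
  camera colour channel records an independent in-line hologram
  `H = |E_inc + E_scat|^2`. Each channel's contrast `H − 1` is
  back-propagated to every plane `z` with the angular-spectrum
  (Rayleigh–Sommerfeld) kernel evaluated about the illumination carrier,
  `exp(i z √(k² − |k⊥ + k₀|²))`, whose linear term applies the tilt shear
  `−z tanθ` exactly; the voxelwise geometric mean of the three intensity
  volumes (`512 × 512 × 61` voxels over `56 × 56 × 20 µm³`) sharpens the
  axial response. Segmentation by thresholding + 26-connected components
  returns, per object, position `(x, y, z)`, size and shape `(l, b)` from
  second-moment eigenvalues (`l = 4√λ₁`), and orientation `ê`.
* **Holographic optical tweezers.** An array of 3D trap positions is
  compiled into a phase-only SLM mask by a weighted Gerchberg–Saxton (GSW)
  loop over the prism-and-lens kernels
  `Δ_m = exp(i[(k/f)(x_m u + y_m v) + (k z_m/2f²)(u² + v²)])`, with
  efficiency `Σ|V_m|²` ≈ 0.8 at the standard 3-iteration operating point.
  Trap and imaging frames are tied together by the calibration
  `r′ = T r + r₀ + α z² ẑ`, fitted by least squares.

A seeded overdamped Langevin simulator (Stokes drag, gravity/buoyancy,
harmonic traps, wall-circling smooth swimmers) stands in for the sample, so
the full loop — render hologram → reconstruct → segment → track → command
traps — runs closed, deterministic and entirely in software.

## Worked example

Render a synthetic scene, reconstruct it, and read off the object features:

```r
library(holotwin)

scene <- dplyr::bind_rows(
  scene_object("sphere", 2, -3, 5, radius = 0.5, material = "silica"),
  scene_object("spherocylinder", -5, 4, 8, radius = 0.5, length = 3,
               ex = 1, ey = 1, ez = 0, material = "ecoli"))

holo <- render_hologram(scene, n = 256)
vol  <- reconstruct_volume(holo, z_planes = seq(0, 14, by = 1/3))

# the compact silica sphere focuses light more strongly than the dim
# elongated cell, so lower the global threshold for this mixed scene
segment_volume(vol, threshold_fraction = 0.15)
#>           x         y        z        l         b       ex       ey      ez voxel_count
#> 1 -4.990571  4.003053 7.971317 2.504654 1.1755783  0.70663  0.70715 0.02474         396
#> 2  2.002131 -3.002113 4.976520 2.098176 0.7435073 -0.00999 -0.00061 0.99995         306
```

The sphere is recovered at (2.00, −3.00, 4.98) — sub-voxel agreement with
the ground truth — and the bacterium's in-plane orientation
(ê ≈ (0.71, 0.71, 0)) and micron-scale length are read straight off the
moments.

Compile a trap arrangement and check it on the simulated focal field:

```r
traps <- trap_configuration(x = c(-10, 0, 10), y = c(0, 5, 0), z = c(-3, 0, 3))
mask  <- gsw_optimize(traps, iterations = 3, seed = 1)
mask$metrics$efficiency
#> [1] 0.8247646
focal_field_metrics(mask, traps)$per_trap_intensity
#> [1] 0.2744 0.2764 0.2754
```

Three nearly equal spots carrying ~82% of the light between them. The
closed-loop demos (`demo_falling_bodies()`, `demo_cube()`,
`demo_fishing()`) run the whole pipeline frame by frame and return tracked
feature tables next to the ground truth.

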