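# shared fixtures: all synthetic, generated in code

# band-limited Gaussian spot field (safe for unitarity/oracle checks)
gaussian_field <- function(n = 64, pitch = 0.2, wavelength = 0.52,
                           sigma_px = 2, medium_index = 1.33) {
  x <- grid_axis(n, pitch)
  g <- exp(-outer(x^2, x^2, `+`) / (2 * (sigma_px * pitch)^2))
  complex_field(matrix(complex(real = g), n, n), pitch, wavelength,
                medium_index)
}

# direct Rayleigh-Sommerfeld summation over source pixels: the brute-force
# diffraction-integral oracle (exact spatial kernel, finite aperture)
rs_direct_sum <- function(values, pitch, wavelength, medium_index, dz,
                          dest_idx) {
  n <- nrow(values)
  k <- 2 * pi * medium_index / wavelength
  x <- grid_axis(n, pitch)
  src <- which(Mod(values) > 0, arr.ind = TRUE)
  out <- matrix(0 + 0i, length(dest_idx), length(dest_idx))
  for (a in seq_along(dest_idx)) {
    for (b in seq_along(dest_idx)) {
      dx <- x[dest_idx[a]] - x[src[, 1]]
      dy <- x[dest_idx[b]] - x[src[, 2]]
      rho <- sqrt(dx^2 + dy^2 + dz^2)
      h <- (dz / (2 * pi)) * exp(1i * k * rho) / rho^2 * (1 / rho - 1i * k)
      out[a, b] <- sum(values[src] * h) * pitch^2
    }
  }
  out
}

# voxelized binary spherocylinder indicator on an isotropic grid
capsule_volume <- function(l = 3, b = 1, e = c(1, 0, 0), pitch = 0.1,
                           margin = 1) {
  e <- e / sqrt(sum(e^2))
  half <- (l - b) / 2
  ext <- l / 2 + margin
  ax <- seq(-ext, ext, by = pitch)
  n <- length(ax)
  arr <- array(0, c(n, n, n))
  for (k in seq_len(n)) {
    t <- outer(ax * e[1], ax * e[2], `+`) + ax[k] * e[3]
    t <- pmin(pmax(t, -half), half)
    dx <- outer(ax, rep(1, n)) - t * e[1]
    dy <- outer(rep(1, n), ax) - t * e[2]
    dzv <- ax[k] - t * e[3]
    arr[, , k] <- (dx^2 + dy^2 + dzv^2) <= (b / 2)^2
  }
  volumetric_image(arr, lateral_pitch = pitch, axial_pitch = pitch,
                   z_origin = ax[1])
}

# analytic second moments of a uniform solid spherocylinder about its axis:
# returns the length/width estimates the moment formulas should recover
capsule_moment_extents <- function(l, b) {
  R <- b / 2
  L <- l - b                      # cylinder length
  vol_cyl <- pi * R^2 * L
  vol_hem <- 2 / 3 * pi * R^3     # one hemisphere
  # axial (along e) second moment about the centroid
  i_cyl <- pi * R^2 * L^3 / 12
  i_hem <- 2 * pi * R^5 / 15 + (pi * R^4 / 4) * L + vol_hem * (L / 2)^2
  lam1 <- (i_cyl + 2 * i_hem) / (vol_cyl + 2 * vol_hem)
  # transverse second moment
  it_cyl <- pi * R^4 * L / 4
  it_hem <- 2 * pi * R^5 / 15
  lam2 <- (it_cyl + 2 * it_hem) / (vol_cyl + 2 * vol_hem)
  c(l_est = 4 * sqrt(lam1), b_est = 4 * sqrt(lam2))
}

# count segmented components for two identical spheres at a given
# centre-to-centre separation along x or z (the discrimination sweep unit)
two_sphere_components <- function(sep, axis = c("x", "z"), n = 512,
                                  diameter = 1, z0 = 5,
                                  z_planes = default_z_planes()) {
  axis <- match.arg(axis)
  r <- diameter / 2
  sc <- if (axis == "x") {
    dplyr::bind_rows(
      scene_object("sphere", -sep / 2, 0, z0, radius = r),
      scene_object("sphere", sep / 2, 0, z0, radius = r))
  } else {
    dplyr::bind_rows(
      scene_object("sphere", 0, 0, z0 - sep / 2, radius = r),
      scene_object("sphere", 0, 0, z0 + sep / 2, radius = r))
  }
  h <- suppressWarnings(render_hologram(sc, n = n))
  v <- suppressWarnings(reconstruct_volume(h, z_planes = z_planes))
  nrow(segment_volume(v))
}

# intensity-weighted centroid of the brightest segmented object
volume_centroid <- function(vol, threshold_fraction = 0.3) {
  f <- segment_volume(vol, threshold_fraction)
  f[which.max(f$peak_intensity), c("x", "y", "z")]
}
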