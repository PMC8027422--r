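#' Trap configurations
#'
#' A trap configuration is a tibble with one row per requested focal spot:
#' coordinates `x`, `y`, `z` in micrometres of trapping space and a relative
#' power weight `w` (default uniform). All traps must lie inside the
#' addressable volume, 56 x 56 x 20 um^3 by default (the imaging field of
#' view, z in [-10, 10] about the focal plane).
#'
#' @param x,y,z Trap coordinates, um.
#' @param w Relative target intensities.
#' @return A trap tibble.
#' @export
#' @examples
#' cube_traps <- trap_configuration(
#'   x = 3 * c(-1, 1, -1, 1, -1, 1, -1, 1),
#'   y = 3 * c(-1, -1, 1, 1, -1, -1, 1, 1),
#'   z = 3 * c(-1, -1, -1, -1, 1, 1, 1, 1))
trap_configuration <- function(x, y, z, w = 1) {
  stopifnot(length(x) >= 1, length(x) == length(y), length(x) == length(z))
  traps <- tibble::tibble(x = x, y = y, z = z, w = rep_len(w, length(x)))
  check_traps_in_volume(traps)
  traps
}

trap_volume <- function(fov = 56, depth = 20) {
  list(xmin = -fov / 2, xmax = fov / 2, ymin = -fov / 2, ymax = fov / 2,
       zmin = -depth / 2, zmax = depth / 2)
}

check_traps_in_volume <- function(traps, volume = trap_volume()) {
  bad <- which(traps$x < volume$xmin | traps$x > volume$xmax |
                 traps$y < volume$ymin | traps$y > volume$ymax |
                 traps$z < volume$zmin | traps$z > volume$zmax)
  if (length(bad) > 0) {
    stop("trap(s) ", paste(bad, collapse = ", "),
         " lie outside the addressable volume", call. = FALSE)
  }
  invisible(traps)
}

#' SLM geometry of the trap engine
#'
#' The phase-only spatial light modulator model: a square grid of
#' `slm_pitch`-sized pixels under unit-amplitude illumination. The effective
#' focal length is chosen so that the FFT of the SLM grid samples the
#' trapping volume at the imaging pitch (`fov / n`), making the addressable
#' lateral range equal to the imaging field of view.
#'
#' @param n SLM grid side, pixels.
#' @param wavelength Trapping laser vacuum wavelength, um (1.064 infrared).
#' @param medium_index Immersion medium index.
#' @param slm_pitch SLM pixel pitch, um.
#' @param fov Addressable lateral field, um.
#' @return A list with the grid size, pitches, in-medium wavenumber and
#'   effective focal length.
#' @export
slm_geometry <- function(n = 512, wavelength = 1.064, medium_index = 1.33,
                         slm_pitch = 10, fov = 56) {
  k <- medium_k(wavelength, medium_index)
  focal_pitch <- fov / n
  # k/f * slm_pitch * focal_pitch = 2 pi / n  =>  f
  f <- k * slm_pitch * focal_pitch * n / (2 * pi)
  list(n = n, wavelength = wavelength, medium_index = medium_index,
       slm_pitch = slm_pitch, fov = fov, focal_pitch = focal_pitch,
       k = k, focal_length = f)
}

#' Per-trap SLM phasor kernel
#'
#' The prism-and-lens phasor of one trap evaluated on the SLM pixel grid:
#' `exp(i [ (k/f)(x u + y v) + (k z / (2 f^2))(u^2 + v^2) ])` with `(u, v)`
#' the pixel coordinates, a blazed grating for the lateral displacement plus
#' a Fresnel lens for the axial one.
#'
#' @param x,y,z Trap coordinates, um.
#' @param geom SLM geometry from `slm_geometry()` (n, pitch, wavelength,
#'   effective focal length).
#' @return An n x n complex matrix of unit modulus.
#' @export
trap_kernel <- function(x, y, z, geom = slm_geometry()) {
  u <- grid_axis(geom$n, geom$slm_pitch)
  ku <- geom$k / geom$focal_length
  lin <- outer(ku * x * u, ku * y * u, `+`)
  quad <- outer(u^2, u^2, `+`) * (geom$k * z / (2 * geom$focal_length^2))
  exp(1i * (lin + quad))
}

new_phase_mask <- function(phases, geom, metrics = NULL) {
  structure(list(phases = phases, slm_shape = dim(phases),
                 trap_wavelength = geom$wavelength,
                 effective_focal_length = geom$focal_length,
                 geom = geom, metrics = metrics),
            class = "phase_mask")
}

#' @export
print.phase_mask <- function(x, ...) {
  cat(sprintf("<phase_mask> %dx%d SLM, lambda %.4g um, f_eff %.4g um\n",
              x$slm_shape[1], x$slm_shape[2], x$trap_wavelength,
              x$effective_focal_length))
  if (!is.null(x$metrics)) {
    cat(sprintf("  efficiency %.3f, uniformity %.3f over %d traps\n",
                x$metrics$efficiency, x$metrics$uniformity,
                length(x$metrics$per_trap_intensity)))
  }
  invisible(x)
}

#' Weighted Gerchberg--Saxton phase-mask optimization
#'
#' Computes a phase-only SLM mask producing focal spots at the requested
#' traps. The phase starts from a random-phase superposition of the per-trap
#' kernels (seeded); each iteration evaluates the trap amplitudes
#' `V_m = (1/N) sum_j exp(i phi_j) conj(Delta_mj)`, re-weights the traps by
#' `w_m <- w_m <|V|> / |V_m|` to equalize them, and rephases the mask as
#' `phi_j = arg sum_m w_m (V_m/|V_m|) Delta_mj`. Three iterations are the
#' operating point used throughout (efficiency of about 80% or better).
#'
#' @param traps A [trap_configuration()] tibble.
#' @param iterations Number of GSW iterations (>= 0; 0 returns the seeded
#'   random-superposition mask).
#' @param seed Integer seed for the random starting phases.
#' @param geom SLM geometry from `slm_geometry()`.
#' @param quantize_8bit Quantize the final phases to 256 SLM levels (off by
#'   default; the ideal float mask).
#'
#' @return A `phase_mask` whose `metrics` element holds `efficiency`
#'   (`sum |V_m|^2`, fraction of total power in the traps), `uniformity`
#'   (`1 - (max - min)/(max + min)` over per-trap intensities) and
#'   `per_trap_intensity`.
#' @export
#' @examples
#' tr <- trap_configuration(x = c(-5, 5), y = c(0, 0), z = c(0, 2))
#' mask <- gsw_optimize(tr, iterations = 3, seed = 1, geom = slm_geometry(64))
#' mask$metrics$efficiency
gsw_optimize <- function(traps, iterations = 3, seed = 0,
                         geom = slm_geometry(), quantize_8bit = FALSE) {
  check_traps_in_volume(traps, trap_volume(geom$fov))
  stopifnot(iterations >= 0)
  m <- nrow(traps)
  n2 <- geom$n^2
  # N x M kernel matrix
  D <- matrix(0 + 0i, n2, m)
  for (j in seq_len(m)) {
    D[, j] <- as.vector(trap_kernel(traps$x[j], traps$y[j], traps$z[j], geom))
  }
  target <- sqrt(traps$w / sum(traps$w))

  theta <- withr::with_seed(as.integer(seed),
                            stats::runif(m, 0, 2 * pi))
  field <- D %*% (target * exp(1i * theta))
  phi <- Arg(field)

  w <- target
  for (it in seq_len(iterations)) {
    V <- as.vector(crossprod(Conj(D), exp(1i * phi))) / n2
    Vmod <- Mod(V)
    if (any(Vmod < .Machine$double.eps)) {
      message("GSW: trap amplitude underflow at iteration ", it,
              "; clamped to machine epsilon")
      Vmod <- pmax(Vmod, .Machine$double.eps)
    }
    w <- w * mean(Vmod / target) * target / Vmod
    phi <- Arg(as.vector(D %*% (w * V / Vmod)))
  }

  if (quantize_8bit) phi <- round(phi %% (2 * pi) / (2 * pi) * 256) / 256 * 2 * pi
  V <- as.vector(crossprod(Conj(D), exp(1i * phi))) / n2
  per_trap <- Mod(V)^2
  metrics <- list(
    efficiency = sum(per_trap),
    uniformity = 1 - (max(per_trap) - min(per_trap)) /
      (max(per_trap) + min(per_trap)),
    per_trap_intensity = per_trap
  )
  new_phase_mask(matrix(phi %% (2 * pi), geom$n), geom, metrics)
}

#' Simulate the focal intensity field of a phase mask
#'
#' Verification oracle for optimized masks: the unit-amplitude field
#' `exp(i phi)` is Fourier-transformed to the focal plane and then propagated
#' across the requested z planes with the paraxial (Fresnel) kernel of
#' [propagate()], the propagator consistent with the lens term of
#' [trap_kernel()]. Returns the 3D intensity of the trapping light.
#'
#' @param mask A `phase_mask`.
#' @param z_planes z planes, um (relative to the focal plane).
#' @return A [volumetric_image()] on the trapping grid.
#' @export
simulate_focal_field <- function(mask, z_planes = 0) {
  geom <- mask$geom
  pupil <- exp(1i * mask$phases)
  # centred FFT: focal-plane field on the fov grid, energy-normalized
  n <- geom$n
  sgn <- matrix((-1)^(outer(seq_len(n), seq_len(n), `+`)), n)
  focal <- sgn * fft2(pupil * sgn) / n
  f0 <- complex_field(focal, pitch = geom$focal_pitch,
                      wavelength = geom$wavelength,
                      medium_index = geom$medium_index)
  vol <- array(0, c(n, n, length(z_planes)))
  for (i in seq_along(z_planes)) {
    fi <- if (z_planes[i] == 0) f0 else {
      propagate(f0, z_planes[i], kernel = "fresnel", band_limit = FALSE)
    }
    vol[, , i] <- Mod(fi$values)^2
  }
  volumetric_image(vol, lateral_pitch = geom$focal_pitch,
                   axial_pitch = if (length(z_planes) > 1) diff(z_planes)[1] else 1,
                   z_origin = z_planes[1], provenance = "trap focal field")
}

#' Measure trap-spot power fractions on a simulated focal field
#'
#' Sums the focal intensity in a small window around each commanded trap
#' position, at that trap's own z plane, and divides by the total plane
#' power: the focal-field counterpart of the kernel-space efficiency.
#'
#' @param mask A `phase_mask`.
#' @param traps The [trap_configuration()] the mask was optimized for.
#' @param window Half-width of the summation window in focal pixels.
#' @param aperture_correction Divide each trap's windowed power by the
#'   capture fraction of the same window for that trap's ideal single-trap
#'   mask, so the finite window does not discount the spot's own diffraction
#'   tails (an ideal single trap then scores efficiency 1 by construction).
#' @return A list with `efficiency`, `uniformity`, `per_trap_intensity`,
#'   `per_trap_raw` (uncorrected window fractions), and
#'   `peak_offset_voxels` (Chebyshev distance, in voxels, from each commanded
#'   position to the nearest local intensity maximum).
#' @export
focal_field_metrics <- function(mask, traps, window = 3,
                                aperture_correction = TRUE) {
  geom <- mask$geom
  per_trap <- numeric(nrow(traps))
  offset <- numeric(nrow(traps))
  capture <- rep(1, nrow(traps))
  for (j in seq_len(nrow(traps))) {
    m <- window_power(mask, traps$x[j], traps$y[j], traps$z[j], window)
    per_trap[j] <- m$fraction
    offset[j] <- m$peak_offset
    if (aperture_correction) {
      ideal <- new_phase_mask(
        Arg(trap_kernel(traps$x[j], traps$y[j], traps$z[j], geom)) %% (2 * pi),
        geom)
      capture[j] <- window_power(ideal, traps$x[j], traps$y[j], traps$z[j],
                                 window)$fraction
    }
  }
  corrected <- pmin(per_trap / capture, 1)
  list(efficiency = sum(corrected),
       uniformity = 1 - (max(corrected) - min(corrected)) /
         (max(corrected) + min(corrected)),
       per_trap_intensity = corrected,
       per_trap_raw = per_trap,
       peak_offset_voxels = offset)
}

# fraction of one focal plane's power inside a window around (x, y) at the
# trap's own z plane, plus the offset of the local peak
window_power <- function(mask, x, y, z, window) {
  geom <- mask$geom
  ax <- grid_axis(geom$n, geom$focal_pitch)
  plane <- simulate_focal_field(mask, z_planes = z)$values[, , 1]
  i0 <- which.min(abs(ax - x))
  j0 <- which.min(abs(ax - y))
  wi <- pmax(1, i0 - window):pmin(geom$n, i0 + window)
  wj <- pmax(1, j0 - window):pmin(geom$n, j0 + window)
  pk <- which(plane[wi, wj] == max(plane[wi, wj]), arr.ind = TRUE)[1, ]
  list(fraction = sum(plane[wi, wj]) / sum(plane),
       peak_offset = max(abs(c(wi[pk[1]] - i0, wj[pk[2]] - j0))))
}

#' Move, rotate or scale a trap arrangement
#'
#' Applies per-trap displacements or a rigid-body transform (rotation about
#' z by `rotate_z` degrees, isotropic `scale`, then `translate`) about the
#' arrangement's centroid, mirroring the virtual "global handle". The result
#' is validated against the addressable volume; an out-of-volume trap aborts
#' the move naming the offender.
#'
#' @param traps A [trap_configuration()] tibble.
#' @param translate Length-3 displacement, um.
#' @param rotate_z Rotation about the z axis through the handle, degrees.
#' @param scale Isotropic scale factor about the handle.
#' @param handle Centre of rotation/scaling; default the trap centroid.
#' @return The new trap tibble.
#' @export
move_traps <- function(traps, translate = c(0, 0, 0), rotate_z = 0,
                       scale = 1, handle = NULL) {
  stopifnot(length(translate) == 3, scale > 0)
  if (is.null(handle)) handle <- colMeans(traps[, c("x", "y", "z")])
  th <- rotate_z * pi / 180
  rel <- cbind(traps$x - handle[1], traps$y - handle[2], traps$z - handle[3])
  rot <- cbind(rel[, 1] * cos(th) - rel[, 2] * sin(th),
               rel[, 1] * sin(th) + rel[, 2] * cos(th),
               rel[, 3]) * scale
  out <- traps
  out$x <- rot[, 1] + handle[1] + translate[1]
  out$y <- rot[, 2] + handle[2] + translate[2]
  out$z <- rot[, 3] + handle[3] + translate[3]
  check_traps_in_volume(out)
  out
}

#' Export a phase mask as 8-bit PNG or read/write trap lists
#'
#' PNG grey levels map 0..255 to phases 0..2*pi. Trap lists are plain text,
#' one `x y z w` line per trap.
#'
#' @param mask A `phase_mask`.
#' @param traps A trap tibble.
#' @param path File path.
#' @return `read_traps()` returns a trap tibble.
#' @export
export_mask_png <- function(mask, path) {
  png::writePNG(t(mask$phases) / (2 * pi), path)
  invisible(path)
}

#' @rdname export_mask_png
#' @export
write_traps <- function(traps, path) {
  utils::write.table(traps[, c("x", "y", "z", "w")], path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname export_mask_png
#' @export
read_traps <- function(path) {
  m <- utils::read.table(path, col.names = c("x", "y", "z", "w"))
  trap_configuration(m$x, m$y, m$z, m$w)
}
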