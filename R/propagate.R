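#' Angular-spectrum (Rayleigh--Sommerfeld) free-space propagation
#'
#' Propagates a scalar field by a signed axial distance `dz` using the
#' angular-spectrum transfer function `exp(i dz sqrt(k^2 - kx^2 - ky^2))`,
#' the frequency-domain form of the Rayleigh--Sommerfeld diffraction integral.
#' Evanescent components (`kx^2 + ky^2 > k^2`) are set to zero, and a local
#' frequency (Matsushima-style) band limit suppresses wrap-around aliasing of
#' the sampled transfer function at large `|dz|`.
#'
#' The optional `carrier` shifts the transfer function in frequency,
#' `kz(kx + c1, ky + c2)`: this propagates a field whose carrier has been
#' demodulated away, exactly as if the carrier were still present. Its linear
#' term reproduces the geometric shear `-dz * tan(theta)` of a tilted beam, so
#' tilt-compensated holographic back-propagation is a single call.
#'
#' `kernel = "fresnel"` replaces the exact square root by its paraxial
#' expansion `k - |kp|^2 / (2k)` with no evanescent cut-off; this is the
#' propagator consistent with the paraxial prism-and-lens kernel used by the
#' holographic-tweezers engine.
#'
#' @param field A [complex_field()].
#' @param dz Signed axial distance in micrometres.
#' @param kernel `"exact"` (angular spectrum) or `"fresnel"` (paraxial).
#' @param carrier Length-2 numeric, transverse carrier `(kx0, ky0)` in rad/um.
#' @param band_limit Apply the anti-aliasing local-frequency limit.
#'
#' @return A new [complex_field()]; the input is not modified.
#' @export
#' @examples
#' f <- tilted_plane_wave(0, 0, 0.52, n = 64, pitch = 0.2)
#' g <- propagate(f, 5)
#' max(Mod(g$values - f$values * g$values[1, 1]))  # still a plane wave
propagate <- function(field, dz, kernel = c("exact", "fresnel"),
                      carrier = c(0, 0), band_limit = TRUE) {
  stopifnot(inherits(field, "complex_field"),
            is.numeric(dz), length(dz) == 1, is.finite(dz),
            length(carrier) == 2, all(is.finite(carrier)))
  kernel <- match.arg(kernel)
  if (dz == 0 && all(carrier == 0)) return(field)

  n <- nrow(field$values)
  tf <- transfer_function(n, field$pitch, field$wavelength, field$medium_index,
                          dz, kernel, carrier, band_limit)
  out <- field
  out$values <- ifft2(fft2(field$values) * tf)
  out
}

# Sampled transfer function exp(i dz kz) on the FFT grid, with evanescent and
# aliasing-prone components zeroed.
transfer_function <- function(n, pitch, wavelength, medium_index, dz,
                              kernel = "exact", carrier = c(0, 0),
                              band_limit = TRUE) {
  k <- medium_k(wavelength, medium_index)
  kx <- k_axis(n, pitch) + carrier[1]
  ky <- k_axis(n, pitch) + carrier[2]
  kx2 <- matrix(kx^2, n, n)
  ky2 <- matrix(ky^2, n, n, byrow = TRUE)
  kr2 <- kx2 + ky2

  if (kernel == "exact") {
    arg <- k^2 - kr2
    prop <- arg > 0
    kz <- sqrt(pmax(arg, 0))
    tf <- matrix(0 + 0i, n, n)
    tf[prop] <- exp(1i * dz * kz[prop])
  } else {
    kz <- k - kr2 / (2 * k)
    tf <- exp(1i * dz * kz)
    prop <- matrix(TRUE, n, n)
  }

  if (band_limit && dz != 0) {
    # local frequency of the sampled phase must stay below Nyquist:
    # |dz * d(kz)/d(kx)| <= n * pitch / 2 per axis.
    half_ap <- n * pitch / 2
    denom <- if (kernel == "exact") pmax(kz, .Machine$double.eps) else k
    ok <- (abs(dz) * sqrt(kx2) / denom <= half_ap) &
          (abs(dz) * sqrt(ky2) / denom <= half_ap)
    tf[!ok] <- 0 + 0i
  }
  tf
}

#' Tilted unit-amplitude plane wave
#'
#' Builds the illumination field of one LED channel: a unit-amplitude plane
#' wave whose transverse phase ramp corresponds to propagation at polar angle
#' `tilt_polar` (measured in the medium from the optical axis) towards azimuth
#' `tilt_azimuth` in the x-y plane.
#'
#' @param tilt_polar Polar tilt angle in degrees, `0 <= tilt_polar < 90`.
#' @param tilt_azimuth Azimuth in degrees (0 = +x, 90 = +y).
#' @param wavelength Vacuum wavelength, um.
#' @param n Grid side (power of two).
#' @param pitch Lateral pitch, um.
#' @param medium_index Medium refractive index.
#' @param numerical_aperture Objective NA used only to warn when the tilt lies
#'   outside the collection cone.
#'
#' @return A [complex_field()] with `|values| = 1` everywhere.
#' @export
tilted_plane_wave <- function(tilt_polar, tilt_azimuth, wavelength,
                              n = 512, pitch = 56 / 512,
                              medium_index = 1.33,
                              numerical_aperture = 1.45) {
  stopifnot(tilt_polar >= 0, tilt_polar < 90)
  k <- medium_k(wavelength, medium_index)
  if (medium_index * sin(tilt_polar * pi / 180) > numerical_aperture) {
    warning("illumination tilt of ", tilt_polar,
            " degrees lies outside the NA ", numerical_aperture,
            " acceptance cone", call. = FALSE)
  }
  kt <- tilt_carrier(tilt_polar, tilt_azimuth, wavelength, medium_index)
  x <- grid_axis(n, pitch)
  phase <- outer(kt[1] * x, kt[2] * x, `+`)
  complex_field(exp(1i * phase), pitch = pitch, wavelength = wavelength,
                medium_index = medium_index)
}

# Transverse carrier (kx0, ky0) in rad/um of a tilted beam.
tilt_carrier <- function(tilt_polar, tilt_azimuth, wavelength, medium_index) {
  k <- medium_k(wavelength, medium_index)
  s <- sin(tilt_polar * pi / 180)
  c(k * s * cos(tilt_azimuth * pi / 180),
    k * s * sin(tilt_azimuth * pi / 180))
}
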