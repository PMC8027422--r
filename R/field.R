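#' Scalar complex field on a square grid
#'
#' A `complex_field` holds one monochromatic scalar field sampled on a square
#' lateral grid, together with the physical metadata needed to propagate it:
#' the sample pitch, the vacuum wavelength and the refractive index of the
#' immersion medium. It is the common currency of the forward hologram model
#' and of the holographic reconstruction.
#'
#' @param values Square complex (or numeric) matrix of samples; the side must
#'   be a power of two so FFT-based propagation is exact and fast.
#' @param pitch Lateral sample spacing in micrometres.
#' @param wavelength Vacuum wavelength in micrometres.
#' @param medium_index Refractive index of the immersion medium (>= 1).
#'
#' @return An object of class `complex_field`.
#' @export
#' @examples
#' f <- complex_field(matrix(1 + 0i, 64, 64), pitch = 0.2, wavelength = 0.52)
#' f
complex_field <- function(values, pitch, wavelength, medium_index = 1.33) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (nrow(values) != ncol(values)) {
    stop("`values` must be square (got ", nrow(values), "x", ncol(values), ")",
         call. = FALSE)
  }
  n <- nrow(values)
  if (n < 2 || bitwAnd(n, n - 1L) != 0L) {
    stop("grid side must be a power of two, got ", n, call. = FALSE)
  }
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values)))) {
    stop("`values` contains non-finite samples", call. = FALSE)
  }
  stopifnot(is.numeric(pitch), length(pitch) == 1, pitch > 0,
            is.numeric(wavelength), length(wavelength) == 1, wavelength > 0,
            is.numeric(medium_index), length(medium_index) == 1,
            medium_index >= 1)
  storage.mode(values) <- "complex"
  structure(
    list(values = values, pitch = pitch, wavelength = wavelength,
         medium_index = medium_index),
    class = "complex_field"
  )
}

#' @export
print.complex_field <- function(x, ...) {
  n <- nrow(x$values)
  cat(sprintf(
    "<complex_field> %dx%d, pitch %.4g um (FOV %.4g um), lambda %.4g um, n_med %.3g\n",
    n, n, x$pitch, n * x$pitch, x$wavelength, x$medium_index))
  cat(sprintf("  total intensity %.6g\n", sum(Mod(x$values)^2)))
  invisible(x)
}

#' @export
dim.complex_field <- function(x) dim(x$values)

# Centered spatial coordinate axis for an n-point grid: index n/2 + 1 is x = 0,
# matching the FFT convention used throughout.
grid_axis <- function(n, pitch) (seq_len(n) - 1 - n / 2) * pitch

# Angular frequency axis (rad/um) in FFT (wrapped) order.
k_axis <- function(n, pitch) {
  2 * pi * c(seq(0, n / 2 - 1), seq(-n / 2, -1)) / (n * pitch)
}

# In-medium wavenumber (rad/um).
medium_k <- function(wavelength, medium_index) 2 * pi * medium_index / wavelength

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Microscope optical configuration
#'
#' Geometry of the imaging arm: objective magnification and numerical
#' aperture, the camera pixel pitch referred to the sample plane, and the
#' immersion-medium index. Defaults describe a 100x / NA 1.45 oil objective
#' with a 512-pixel camera spanning a 56 um field of view in water.
#'
#' @param magnification Objective magnification (dimensionless).
#' @param numerical_aperture Objective NA (dimensionless, > 0; may exceed the
#'   medium index for TIRF-class objectives).
#' @param camera_pitch_sample_plane Camera pixel pitch at the sample plane, um.
#' @param medium_index Refractive index of the sample medium.
#'
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(magnification = 100,
                           numerical_aperture = 1.45,
                           camera_pitch_sample_plane = 56 / 512,
                           medium_index = 1.33) {
  stopifnot(magnification > 0, numerical_aperture > 0,
            camera_pitch_sample_plane > 0, medium_index >= 1)
  structure(
    list(magnification = magnification,
         numerical_aperture = numerical_aperture,
         camera_pitch_sample_plane = camera_pitch_sample_plane,
         medium_index = medium_index),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf("<optical_config> %gx, NA %.3g, sample-plane pitch %.4g um, n_med %.3g\n",
              x$magnification, x$numerical_aperture,
              x$camera_pitch_sample_plane, x$medium_index))
  invisible(x)
}

#' Write / read a complex field as a two-page float TIFF
#'
#' Real and imaginary parts are stored as two 32-bit float pages, affinely
#' rescaled to [0, 1]; the scaling and the physical metadata (pitch,
#' wavelength, medium index) live in a JSON sidecar at `<path>.json`.
#'
#' @param field A [complex_field()].
#' @param path Output path.
#' @return `write_complex_field()` returns `path` invisibly;
#'   `read_complex_field()` returns a [complex_field()].
#' @export
write_complex_field <- function(field, path) {
  stopifnot(inherits(field, "complex_field"))
  write_scaled_tiff(list(Re(field$values), Im(field$values)), path,
                    list(pitch = field$pitch, wavelength = field$wavelength,
                         medium_index = field$medium_index))
  invisible(path)
}

#' @rdname write_complex_field
#' @export
read_complex_field <- function(path) {
  r <- read_scaled_tiff(path)
  complex_field(matrix(complex(real = r$pages[[1]], imaginary = r$pages[[2]]),
                       nrow = nrow(r$pages[[1]])),
                pitch = r$meta$pitch, wavelength = r$meta$wavelength,
                medium_index = r$meta$medium_index)
}

# shared scaled-TIFF plumbing: r-tiff stores floats in [0, 1], so pages are
# rescaled and the affine transform recorded in the sidecar
write_scaled_tiff <- function(pages, path, meta) {
  lo <- min(vapply(pages, min, 0))
  hi <- max(vapply(pages, max, 0))
  scale <- if (hi > lo) hi - lo else 1
  scaled <- lapply(pages, function(p) (p - lo) / scale)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, reduce = FALSE)
  meta$tiff_offset <- lo
  meta$tiff_scale <- scale
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_scaled_tiff <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) p * meta$tiff_scale + meta$tiff_offset)
  list(pages = pages, meta = meta)
}
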