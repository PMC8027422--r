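#' Three-channel tilted illumination configuration
#'
#' One entry per camera colour channel: the LED vacuum wavelength, its tilt
#' polar angle (in the medium) and azimuth, and a relative intensity. The
#' defaults are red/green/blue LEDs at 0.630, 0.520 and 0.460 um arriving at
#' a common 20-degree polar tilt from azimuths 120 degrees apart, so the
#' three back-propagated volumes shear along three distinct directions.
#'
#' @param wavelengths Vacuum wavelengths (um) for R, G, B; must be strictly
#'   decreasing.
#' @param tilt_polar Polar tilt angle(s), degrees (recycled to 3).
#' @param tilt_azimuth Azimuths, degrees; must be pairwise distinct.
#' @param intensity Relative channel intensities.
#'
#' @return A tibble with one row per channel.
#' @export
illumination_config <- function(wavelengths = c(0.630, 0.520, 0.460),
                                tilt_polar = 20,
                                tilt_azimuth = c(0, 120, 240),
                                intensity = 1) {
  stopifnot(length(wavelengths) == 3, all(diff(wavelengths) < 0),
            length(tilt_azimuth) == 3,
            !anyDuplicated(tilt_azimuth %% 360))
  tilt_polar <- rep_len(tilt_polar, 3)
  stopifnot(all(tilt_polar >= 0), all(tilt_polar < 90))
  tibble::tibble(
    name = c("R", "G", "B"),
    wavelength = wavelengths,
    tilt_polar = tilt_polar,
    tilt_azimuth = tilt_azimuth,
    intensity = rep_len(intensity, 3)
  )
}

new_hologram <- function(channels, pitch, illumination, noise_meta = NULL) {
  stopifnot(length(channels) == 3,
            all(vapply(channels, is.matrix, TRUE)))
  shp <- vapply(channels, dim, integer(2))
  if (any(shp != shp[, 1])) stop("channel shapes differ", call. = FALSE)
  structure(
    list(channels = channels, pitch = pitch, illumination = illumination,
         noise_meta = noise_meta),
    class = "hologram"
  )
}

#' @export
print.hologram <- function(x, ...) {
  n <- nrow(x$channels[[1]])
  cat(sprintf("<hologram> %dx%d x 3 channels, pitch %.4g um\n", n, n, x$pitch))
  for (i in 1:3) {
    cat(sprintf("  %s: lambda %.3g um, tilt %g deg @ %g deg, mean %.4f\n",
                x$illumination$name[i], x$illumination$wavelength[i],
                x$illumination$tilt_polar[i], x$illumination$tilt_azimuth[i],
                mean(x$channels[[i]])))
  }
  if (!is.null(x$noise_meta)) {
    cat(sprintf("  shot noise: %g photons/pixel, seed %s\n",
                x$noise_meta$photons, x$noise_meta$seed))
  }
  invisible(x)
}

# Projected optical thickness (um) of one object along z, sampled on the
# lateral grid; returns a sparse patch (index vectors + values).
object_thickness <- function(obj, axis_x, pitch) {
  n <- length(axis_x)
  half_extent <- obj$length / 2 + 2 * pitch
  ix <- which(abs(axis_x - obj$x) <= half_extent)
  iy <- which(abs(axis_x - obj$y) <= half_extent)
  if (length(ix) == 0 || length(iy) == 0) {
    return(list(ix = integer(0), iy = integer(0),
                tau = matrix(0, 0, 0)))
  }
  px <- axis_x[ix] - obj$x
  py <- axis_x[iy] - obj$y
  if (obj$kind == "sphere") {
    r2 <- obj$radius^2 - outer(px^2, py^2, `+`)
    tau <- matrix(0, length(ix), length(iy))
    pos <- r2 > 0
    tau[pos] <- 2 * sqrt(r2[pos])
  } else {
    # capsule: chord length along z where distance to the axis segment <= R.
    e <- c(obj$ex, obj$ey, obj$ez)
    h <- (obj$length - 2 * obj$radius) / 2   # cylinder half-length
    dz_step <- min(pitch / 2, obj$radius / 10)
    zs <- seq(-obj$length / 2, obj$length / 2, by = dz_step)
    gx <- rep(px, times = length(py))
    gy <- rep(py, each = length(px))
    tau_acc <- numeric(length(gx))
    r2 <- obj$radius^2
    for (zv in zs) {
      # distance^2 from (gx, gy, zv) to segment [-h e, +h e] through origin
      t <- gx * e[1] + gy * e[2] + zv * e[3]
      t <- pmin(pmax(t, -h), h)
      dx <- gx - t * e[1]; dy <- gy - t * e[2]; dzp <- zv - t * e[3]
      inside <- (dx * dx + dy * dy + dzp * dzp) <= r2
      tau_acc <- tau_acc + inside
    }
    tau <- matrix(tau_acc * dz_step, length(ix), length(iy))
  }
  list(ix = ix, iy = iy, tau = tau)
}

#' Render a synthetic three-axis RGB hologram
#'
#' The digital stand-in for the colour camera. Each object is modelled as a
#' thin phase object on its own axial plane (accumulated optical path
#' `(2 pi / lambda) * (n_obj - n_med) * thickness(x, y)`); under each
#' channel's tilted plane wave the scattered packet `(t - 1) * E_inc` is
#' propagated to the focal plane z = 0, single-scattering contributions are
#' summed over objects (first Born approximation), and the recorded channel
#' is `|E_inc + sum E_scattered|^2`, normalized so the background mean is 1.
#' Optional Poisson shot noise is applied at a stated photon budget.
#'
#' @param scene A scene tibble ([scene_object()]); may have zero rows.
#' @param illumination An [illumination_config()] tibble.
#' @param optics An [optical_config()].
#' @param n Grid side in pixels (power of two).
#' @param noise_photons Expected photons per pixel, or `NULL` for noiseless.
#' @param seed Integer seed for the shot noise (required when noisy).
#'
#' @return A `hologram` object with three non-negative channel images.
#' @export
#' @examples
#' sc <- scene_object("sphere", 0, 0, 5, radius = 1)
#' h <- render_hologram(sc, n = 128)
#' range(h$channels$R)
render_hologram <- function(scene,
                            illumination = illumination_config(),
                            optics = optical_config(),
                            n = 512,
                            noise_photons = NULL,
                            seed = NULL) {
  pitch <- optics$camera_pitch_sample_plane
  fov <- n * pitch
  validate_scene(scene, default_volume(fov = fov))
  axis_x <- grid_axis(n, pitch)
  nm <- optics$medium_index

  channels <- purrr::pmap(illumination, function(name, wavelength, tilt_polar,
                                                 tilt_azimuth, intensity) {
    if (nrow(scene) == 0) return(matrix(1, n, n))   # exact unit background
    kt <- tilt_carrier(tilt_polar, tilt_azimuth, wavelength, nm)
    kz0 <- sqrt(medium_k(wavelength, nm)^2 - sum(kt^2))
    ramp <- exp(1i * outer(kt[1] * axis_x, kt[2] * axis_x, `+`))
    scattered <- matrix(0 + 0i, n, n)
    if (nrow(scene) > 0) {
      for (i in seq_len(nrow(scene))) {
        obj <- scene[i, ]
        patch <- object_thickness(obj, axis_x, pitch)
        if (length(patch$ix) == 0) next
        phi <- (2 * pi / wavelength) *
          (obj$refractive_index - nm) * patch$tau
        packet <- matrix(0 + 0i, n, n)
        packet[patch$ix, patch$iy] <- (exp(1i * phi) - 1) *
          ramp[patch$ix, patch$iy] * exp(1i * kz0 * obj$z)
        pf <- complex_field(packet, pitch, wavelength, nm)
        scattered <- scattered + propagate(pf, -obj$z)$values
      }
    }
    img <- Mod(ramp + scattered)^2
    img / mean(img)
  })
  names(channels) <- illumination$name

  noise_meta <- NULL
  if (!is.null(noise_photons)) {
    stopifnot(noise_photons > 0)
    if (is.null(seed)) stop("give `seed` when rendering with shot noise",
                            call. = FALSE)
    channels <- withr::with_seed(as.integer(seed), {
      purrr::map2(channels, illumination$intensity, function(ch, w) {
        lam <- noise_photons * w * ch
        matrix(stats::rpois(length(lam), lam), nrow(ch)) / (noise_photons * w)
      })
    })
    names(channels) <- illumination$name
    noise_meta <- list(photons = noise_photons, seed = as.integer(seed))
  }

  new_hologram(channels, pitch, illumination, noise_meta)
}

#' Write / read a hologram as a 3-page float TIFF
#'
#' Channels are stored R, G, B as 32-bit float pages rescaled to [0, 1];
#' the scaling, pitch and illumination metadata live in a JSON sidecar at
#' `<path>.json`. [export_hologram_png()] writes an 8-bit RGB preview for
#' quick inspection.
#'
#' @param holo A `hologram`.
#' @param path Output path.
#' @return `read_hologram()` returns a `hologram`.
#' @export
write_hologram <- function(holo, path) {
  stopifnot(inherits(holo, "hologram"))
  write_scaled_tiff(unname(holo$channels), path,
                    list(pitch = holo$pitch,
                         illumination = as.list(holo$illumination),
                         noise_meta = holo$noise_meta))
  invisible(path)
}

#' @rdname write_hologram
#' @export
read_hologram <- function(path) {
  r <- read_scaled_tiff(path)
  illum <- tibble::as_tibble(r$meta$illumination)
  channels <- stats::setNames(r$pages[1:3], illum$name)
  new_hologram(channels, r$meta$pitch, illum, r$meta$noise_meta)
}

#' @rdname write_hologram
#' @export
export_hologram_png <- function(holo, path) {
  stopifnot(inherits(holo, "hologram"))
  arr <- simplify2array(holo$channels)     # n x n x 3
  lo <- min(arr); hi <- max(arr)
  arr <- if (hi > lo) (arr - lo) / (hi - lo) else arr * 0
  png::writePNG(aperm(arr, c(2, 1, 3)), path)
  invisible(path)
}
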