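#' Default run configuration
#'
#' The full set of tunable parameters of the digital twin, with the default
#' instrument geometry: 512 x 512 holograms over a 56 um field of view, 61
#' reconstruction planes over 20 um, three tilted LED channels, GSW trap
#' engine at 3 iterations and the aqueous sample environment.
#'
#' @return A nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 0L,
    optics = list(magnification = 100, numerical_aperture = 1.45,
                  camera_pitch_sample_plane = 56 / 512, medium_index = 1.33),
    illumination = list(wavelengths = c(0.630, 0.520, 0.460),
                        tilt_polar = 20, tilt_azimuth = c(0, 120, 240),
                        intensity = 1),
    recon = list(grid_n = 512L, n_planes = 61L, depth = 20, z_origin = 0,
                 overlap_method = "geomean"),
    segmentation = list(threshold_fraction = 0.3, min_voxels = 20L),
    traps = list(slm_n = 512L, wavelength = 1.064, slm_pitch = 10,
                 iterations = 3L, stiffness = 5, capture_radius = 1.5),
    dynamics = list(temperature = 295, viscosity = 8.9e-4,
                    fluid_density = 1.00, gravity = 9.81, dt = 1e-3,
                    swimmer_omega = 1, rot_diffusion = 0.1),
    noise = list(photons = 1e4)
  ), class = "run_config")
}

config_bounds <- function() {
  list(
    "optics.magnification" = c(1, 1000),
    "optics.numerical_aperture" = c(1e-3, 2),
    "optics.camera_pitch_sample_plane" = c(1e-4, 10),
    "optics.medium_index" = c(1, 2),
    "illumination.tilt_polar" = c(0, 89.999),
    "illumination.wavelengths" = c(0.2, 2),
    "recon.grid_n" = c(16, 4096),
    "recon.n_planes" = c(1, 1000),
    "recon.depth" = c(0.1, 200),
    "segmentation.threshold_fraction" = c(1e-6, 0.999999),
    "segmentation.min_voxels" = c(1, 1e6),
    "traps.iterations" = c(0, 1000),
    "traps.stiffness" = c(1e-6, 1e4),
    "traps.wavelength" = c(0.2, 2),
    "dynamics.temperature" = c(0, 1000),
    "dynamics.viscosity" = c(1e-6, 10),
    "dynamics.dt" = c(1e-9, 1e-3),
    "noise.photons" = c(1, 1e12)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejecting unknown keys (strict parsing) and
#' out-of-range values, and fills unspecified fields with the defaults of
#' [default_config()]. An empty file yields the all-defaults configuration.
#'
#' @param path Path to a YAML config file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  structure(merge_config(unclass(default_config()), user),
            class = "run_config")
}

merge_config <- function(defaults, user, prefix = "") {
  bounds <- config_bounds()
  for (key in names(user)) {
    full <- if (prefix == "") key else paste0(prefix, ".", key)
    if (!key %in% names(defaults)) {
      stop("unknown configuration key '", full, "'", call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.list(user[[key]])) {
      stop("configuration key '", full, "' must be a section", call. = FALSE)
    }
    if (is.list(defaults[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      val <- user[[key]]
      if (full %in% names(bounds)) {
        b <- bounds[[full]]
        if (any(!is.finite(val)) || any(val < b[1]) || any(val > b[2])) {
          stop("configuration key '", full, "' = ", paste(val, collapse = ", "),
               " outside allowed range [", b[1], ", ", b[2], "]",
               call. = FALSE)
        }
      }
      defaults[[key]] <- val
    }
  }
  defaults
}

#' @rdname load_config
#' @param config A `run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

#' Derive independent per-module seed streams from the run seed
#'
#' One configuration seed fans out to named streams (shot noise, GSW
#' initialization, dynamics) so that the stages are independently
#' reproducible. Streams stay below 2^31.
#'
#' @param seed Integer master seed.
#' @return Named integer vector with streams `noise`, `gsw`, `dynamics`.
#' @export
derive_seeds <- function(seed) {
  offsets <- c(noise = 101L, gsw = 211L, dynamics = 307L)
  vapply(offsets, function(o) {
    as.integer((as.numeric(seed) * 7919 + o) %% .Machine$integer.max)
  }, integer(1))
}

# Helpers to build module objects from a config
config_optics <- function(cfg) {
  do.call(optical_config, cfg$optics)
}

config_illumination <- function(cfg) {
  do.call(illumination_config, cfg$illumination)
}

config_z_planes <- function(cfg) {
  default_z_planes(cfg$recon$n_planes, cfg$recon$depth, cfg$recon$z_origin)
}
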