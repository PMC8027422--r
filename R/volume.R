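#' Volumetric intensity image
#'
#' A 3D non-negative scalar grid with physical voxel pitches. The default
#' reconstruction geometry is 512 x 512 x 61 voxels spanning 56 x 56 x 20
#' um^3: lateral pitch 56/512 um, axial pitch 1/3 um, planes ordered by
#' increasing z starting at `z_origin`.
#'
#' @param values 3D array `[x, y, z]` of non-negative intensities.
#' @param lateral_pitch Lateral voxel pitch, um.
#' @param axial_pitch Axial plane spacing, um.
#' @param z_origin z of the first plane, um.
#' @param provenance Free-text tag (`"channel:R"`, `"overlap"`, ...).
#'
#' @return An object of class `volumetric_image`.
#' @export
volumetric_image <- function(values, lateral_pitch = 56 / 512,
                             axial_pitch = 1 / 3, z_origin = 0,
                             provenance = "unknown") {
  stopifnot(is.array(values), length(dim(values)) == 3,
            lateral_pitch > 0, axial_pitch > 0)
  if (any(values < 0)) stop("volume intensities must be >= 0", call. = FALSE)
  structure(
    list(values = values, lateral_pitch = lateral_pitch,
         axial_pitch = axial_pitch, z_origin = z_origin,
         provenance = provenance),
    class = "volumetric_image"
  )
}

#' @export
print.volumetric_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<volumetric_image> %dx%dx%d voxels, %.4g x %.4g x %.4g um^3 (%s)\n",
    d[1], d[2], d[3], d[1] * x$lateral_pitch, d[2] * x$lateral_pitch,
    x$axial_pitch * (d[3] - 1) + x$axial_pitch, x$provenance))
  cat(sprintf("  z planes %.4g .. %.4g um; max intensity %.4g\n",
              x$z_origin, x$z_origin + (d[3] - 1) * x$axial_pitch,
              max(x$values)))
  invisible(x)
}

#' @export
dim.volumetric_image <- function(x) dim(x$values)

# Physical coordinate axes of a volume.
volume_axes <- function(vol) {
  d <- dim(vol$values)
  list(x = grid_axis(d[1], vol$lateral_pitch),
       y = grid_axis(d[2], vol$lateral_pitch),
       z = vol$z_origin + (seq_len(d[3]) - 1) * vol$axial_pitch)
}

# Default axial plane list: 61 planes over 20 um.
default_z_planes <- function(n_planes = 61, depth = 20, z_origin = 0) {
  seq(z_origin, z_origin + depth, length.out = n_planes)
}

#' Write / read a volume as a multi-page 32-bit float TIFF
#'
#' One page per z plane, rescaled to [0, 1]; the scaling, pitches and origin
#' live in a JSON sidecar at `<path>.json`.
#'
#' @param vol A [volumetric_image()].
#' @param path Output path.
#' @return `read_volume()` returns a [volumetric_image()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volumetric_image"))
  pages <- purrr::map(seq_len(dim(vol$values)[3]),
                      function(i) vol$values[, , i])
  write_scaled_tiff(pages, path,
                    list(lateral_pitch = vol$lateral_pitch,
                         axial_pitch = vol$axial_pitch,
                         z_origin = vol$z_origin,
                         provenance = vol$provenance))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  r <- read_scaled_tiff(path)
  arr <- array(unlist(r$pages), dim = c(dim(r$pages[[1]]), length(r$pages)))
  volumetric_image(pmax(arr, 0), r$meta$lateral_pitch, r$meta$axial_pitch,
                   r$meta$z_origin, r$meta$provenance)
}
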