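#' Optical and mechanical properties of common sample materials
#'
#' Literature refractive indices and mass densities for the materials used in
#' the synthetic scenes: silica and polystyrene microspheres and the E. coli
#' cell body. All are configurable per object; these are the defaults.
#'
#' @return A tibble with columns `material`, `refractive_index`, `density`
#'   (g/cm^3).
#' @export
material_properties <- function() {
  tibble::tribble(
    ~material,     ~refractive_index, ~density,
    "silica",      1.45,              2.00,
    "polystyrene", 1.59,              1.05,
    "ecoli",       1.39,              1.10
  )
}

#' Build a synthetic scene of scattering objects
#'
#' A scene is a tibble with one row per object: spheres (colloids) and
#' spherocylinders (bacterial cell bodies). Positions are in micrometres in
#' the imaging frame: x, y in the image plane, z along the optical axis with
#' z = 0 at the coverslip and gravity along -z.
#'
#' @param kind `"sphere"` or `"spherocylinder"`.
#' @param x,y,z Centre coordinates, um.
#' @param radius Sphere radius, or half the spherocylinder width `b/2`, um.
#' @param length End-to-end spherocylinder length `l` (>= `2 * radius`), um;
#'   for spheres it is set to the diameter.
#' @param ex,ey,ez Orientation unit vector (normalized internally; ignored
#'   for spheres, stored as (0,0,1)).
#' @param material One of [material_properties()]`$material`, or `NA` to give
#'   `refractive_index`/`density` directly.
#' @param refractive_index,density Overrides for custom materials.
#' @param behavior `"passive"` or `"smooth_swimmer"`.
#' @param speed Swimming speed, um/s (swimmers only).
#'
#' @return A one-row scene tibble; rows from repeated calls can be bound with
#'   [dplyr::bind_rows()].
#' @export
#' @examples
#' scene <- dplyr::bind_rows(
#'   scene_object("sphere", 0, 0, 5, radius = 1, material = "silica"),
#'   scene_object("spherocylinder", 5, -3, 8, radius = 0.5, length = 3,
#'                ex = 1, ey = 0, ez = 0, material = "ecoli")
#' )
scene_object <- function(kind = c("sphere", "spherocylinder"),
                         x, y, z, radius,
                         length = 2 * radius,
                         ex = 0, ey = 0, ez = 1,
                         material = "silica",
                         refractive_index = NULL, density = NULL,
                         behavior = c("passive", "smooth_swimmer"),
                         speed = 0) {
  kind <- match.arg(kind)
  behavior <- match.arg(behavior)
  stopifnot(radius > 0)
  if (kind == "sphere") {
    length <- 2 * radius
    e <- c(0, 0, 1)
  } else {
    if (length < 2 * radius) {
      stop("spherocylinder length must be >= 2 * radius", call. = FALSE)
    }
    nrm <- sqrt(ex^2 + ey^2 + ez^2)
    if (nrm < 1e-12) stop("orientation vector must be non-zero", call. = FALSE)
    e <- c(ex, ey, ez) / nrm
  }
  if (!is.null(material) && !is.na(material) && is.null(refractive_index)) {
    props <- material_properties()
    row <- props[props$material == material, ]
    if (nrow(row) == 0) {
      stop("unknown material '", material, "'; give refractive_index/density",
           call. = FALSE)
    }
    refractive_index <- row$refractive_index
    density <- row$density
  }
  stopifnot(is.numeric(refractive_index), is.numeric(density))
  tibble::tibble(
    kind = kind, x = x, y = y, z = z, radius = radius, length = length,
    ex = e[1], ey = e[2], ez = e[3],
    material = if (is.null(material)) NA_character_ else material,
    refractive_index = refractive_index, density = density,
    behavior = behavior, speed = speed
  )
}

# Volume bounds of the default imaging/trapping space, um.
default_volume <- function(fov = 56, depth = 20) {
  list(xmin = -fov / 2, xmax = fov / 2, ymin = -fov / 2, ymax = fov / 2,
       zmin = 0, zmax = depth)
}

#' Validate a scene tibble
#'
#' Checks column presence, orientation normalization, size constraints, that
#' all centres lie inside the addressable volume, and warns about overlapping
#' objects (the single-scattering forward model is then questionable).
#'
#' @param scene A scene tibble (see [scene_object()]).
#' @param volume Bounds list from `default_volume()`.
#' @return `scene` invisibly, after normalizing orientations.
#' @export
validate_scene <- function(scene, volume = default_volume()) {
  needed <- c("kind", "x", "y", "z", "radius", "length",
              "ex", "ey", "ez", "refractive_index", "density")
  missing <- setdiff(needed, names(scene))
  if (length(missing) > 0) {
    stop("scene is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(scene) == 0) return(invisible(scene))
  stopifnot(all(scene$radius > 0),
            all(scene$length >= 2 * scene$radius - 1e-12))
  nrm <- with(scene, sqrt(ex^2 + ey^2 + ez^2))
  if (any(abs(nrm - 1) > 1e-9)) {
    stop("orientation vectors must have unit norm", call. = FALSE)
  }
  inside <- scene$x >= volume$xmin & scene$x <= volume$xmax &
    scene$y >= volume$ymin & scene$y <= volume$ymax &
    scene$z >= volume$zmin & scene$z <= volume$zmax
  if (!all(inside)) {
    stop("object(s) ", paste(which(!inside), collapse = ", "),
         " lie outside the addressable volume", call. = FALSE)
  }
  if (nrow(scene) > 1) {
    ctr <- as.matrix(scene[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(ctr))
    rr <- outer(scene$length / 2, scene$length / 2, `+`)
    diag(d) <- Inf
    if (any(d < rr)) {
      warning("scene contains overlapping objects; ",
              "single-scattering rendering will be approximate",
              call. = FALSE)
    }
  }
  invisible(scene)
}

#' Read and write scene descriptions
#'
#' Scenes are stored as YAML: a list of objects, each with the fields of
#' [scene_object()].
#'
#' @param scene A scene tibble.
#' @param path File path.
#' @return `read_scene()` returns a scene tibble.
#' @export
write_scene <- function(scene, path) {
  objs <- purrr::transpose(as.list(scene))
  yaml::write_yaml(list(objects = objs), path, precision = 15)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$objects)) stop("scene file has no 'objects' list", call. = FALSE)
  scene <- purrr::map_dfr(raw$objects, tibble::as_tibble)
  # forgive serialization round-off on the unit orientations
  nrm <- with(scene, sqrt(ex^2 + ey^2 + ez^2))
  if (all(abs(nrm - 1) < 1e-6)) {
    scene$ex <- scene$ex / nrm; scene$ey <- scene$ey / nrm
    scene$ez <- scene$ez / nrm
  }
  validate_scene(scene)
  scene
}
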