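#' Two-sphere discrimination sweep
#'
#' Renders noiseless synthetic holograms of two identical spheres at a range
#' of centre-to-centre separations (laterally along x at a common height, or
#' stacked along z on the optical axis), runs the full
#' reconstruction/overlap/segmentation pipeline at the default threshold,
#' and counts the segmented components at each separation. This reproduces
#' the instrument's object-discrimination benchmark.
#'
#' @param separations Centre-to-centre separations to test, um.
#' @param axis `"x"` (lateral, both spheres at `z0`) or `"z"` (axial).
#' @param diameter Sphere diameter, um.
#' @param z0 Mid-point height above the coverslip, um.
#' @param n Hologram grid side.
#' @param z_planes Reconstruction planes.
#' @param threshold_fraction,min_voxels Segmentation parameters.
#'
#' @return A tibble with `separation` and `components`.
#' @export
discrimination_sweep <- function(separations, axis = c("x", "z"),
                                 diameter = 1, z0 = 5, n = 512,
                                 z_planes = default_z_planes(),
                                 threshold_fraction = 0.3, min_voxels = 20) {
  axis <- match.arg(axis)
  r <- diameter / 2
  comp <- purrr::map_int(separations, function(sep) {
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
    nrow(segment_volume(v, threshold_fraction, min_voxels))
  })
  tibble::tibble(separation = separations, components = comp)
}

#' Smallest separation reliably resolved as two objects
#'
#' Given a [discrimination_sweep()] table, returns the smallest separation
#' from which every larger tested separation also yields exactly two
#' components (`NA` if none does).
#'
#' @param sweep Output of [discrimination_sweep()].
#' @return A single separation in um, or `NA`.
#' @export
discrimination_limit <- function(sweep) {
  two <- sweep$components == 2
  stable <- rev(cumprod(rev(two))) > 0   # TRUE where all later seps are two
  if (!any(stable)) return(NA_real_)
  min(sweep$separation[stable])
}

#' GSW operating-point benchmark
#'
#' Optimizes phase masks for seeded random trap configurations at the
#' standard operating point (3 weighted Gerchberg--Saxton iterations) and
#' measures each mask's efficiency on the simulated focal field.
#'
#' @param n_configs Number of random configurations.
#' @param n_traps Traps per configuration.
#' @param iterations GSW iterations.
#' @param seed Base seed; configuration `i` uses `seed + i - 1`.
#' @param geom SLM geometry.
#' @param margin Keep traps this fraction inside the volume edges.
#' @return A tibble with per-configuration `seed`, `efficiency` (focal
#'   field), `kernel_efficiency` (`sum |V_m|^2`) and `uniformity`.
#' @export
gsw_operating_point <- function(n_configs = 10, n_traps = 10, iterations = 3,
                                seed = 0, geom = slm_geometry(),
                                margin = 0.9) {
  vol <- trap_volume(geom$fov)
  purrr::map_dfr(seq_len(n_configs), function(i) {
    s <- seed + i - 1
    tr <- withr::with_seed(s, trap_configuration(
      stats::runif(n_traps, vol$xmin * margin, vol$xmax * margin),
      stats::runif(n_traps, vol$ymin * margin, vol$ymax * margin),
      stats::runif(n_traps, vol$zmin * margin, vol$zmax * margin)))
    mask <- gsw_optimize(tr, iterations = iterations, seed = s, geom = geom)
    fm <- focal_field_metrics(mask, tr)
    tibble::tibble(seed = s, efficiency = fm$efficiency,
                   kernel_efficiency = mask$metrics$efficiency,
                   uniformity = fm$uniformity)
  })
}
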