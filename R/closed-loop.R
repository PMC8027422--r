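#' Run the closed imaging--trapping loop
#'
#' Reproduces the instrument's data flow entirely in software. At every
#' frame: the ground-truth scene is rendered into an RGB hologram, the
#' hologram is back-propagated and overlapped into a volumetric image, the
#' volume is segmented into features and the features are linked into
#' tracks; pending trap commands are mapped through the calibration model
#' and (optionally) compiled into GSW phase masks; finally the dynamics
#' simulator advances the scene to the next frame under the active traps.
#'
#' @param scene Initial scene tibble.
#' @param script Tibble of timed trap commands with columns `time` (s) and
#'   `traps` (list column of trap tibbles, or `NULL` entries to switch traps
#'   off), time-sorted; `NULL` for no commands.
#' @param frames Number of frames to run.
#' @param fps Imaging frame rate, 1/s (40 by default).
#' @param n Hologram grid side.
#' @param z_planes Reconstruction planes, um.
#' @param calibration Optional `calibration_model` applied to commanded trap
#'   positions; `NULL` uses them as-is.
#' @param stiffness,capture_radius Trap parameters, see [trap_field()].
#' @param dt Dynamics sub-step, s.
#' @param env A [sample_environment()].
#' @param compute_masks Also run [gsw_optimize()] for each new command (off
#'   by default: mask computation does not influence the simulated motion,
#'   which uses ideal harmonic traps).
#' @param seed Integer seed driving the dynamics noise stream.
#' @param threshold_fraction,min_voxels Segmentation parameters.
#' @param max_link_distance Tracking link distance, um.
#' @param ... Extra arguments to [step_scene()].
#'
#' @return A list: `frames` (tibble of tracked features per frame),
#'   `truth` (tibble of ground-truth object states per frame), `masks`
#'   (list of phase masks, if computed), `commands` (the script as applied).
#' @export
run_closed_loop <- function(scene, script = NULL, frames = 10, fps = 40,
                            n = 256, z_planes = default_z_planes(),
                            calibration = NULL,
                            stiffness = 5, capture_radius = 1.5,
                            dt = 1e-3, env = sample_environment(),
                            compute_masks = FALSE, seed = 1,
                            threshold_fraction = 0.3, min_voxels = 20,
                            max_link_distance = 2, ...) {
  if (!is.null(script)) {
    stopifnot(all(c("time", "traps") %in% names(script)))
    if (is.unsorted(script$time)) {
      stop("script commands must be time-sorted", call. = FALSE)
    }
  }
  # overdamped Euler-Maruyama is stable only for kappa dt / gamma < 1;
  # check against the smallest drag in the scene
  if (nrow(scene) > 0) {
    gam_min <- min(stokes_drag(scene, env))
    if (stiffness * dt / gam_min > 1) {
      warning("stiffness * dt / gamma = ",
              signif(stiffness * dt / gam_min, 3),
              " > 1: reduce dt for a stable trapped-particle update",
              call. = FALSE)
    }
  }
  substeps <- max(1L, round(1 / (fps * dt)))
  feat_log <- list()
  truth_log <- list()
  masks <- list()
  active <- NULL
  next_cmd <- 1L

  withr::with_seed(as.integer(seed), {
    for (fr in seq_len(frames)) {
      t_now <- (fr - 1) / fps
      while (!is.null(script) && next_cmd <= nrow(script) &&
             script$time[next_cmd] <= t_now + 1e-12) {
        cmd <- script$traps[[next_cmd]]
        if (is.null(cmd)) {
          active <- NULL
        } else {
          cmd_t <- if (!is.null(calibration)) {
            dplyr::bind_cols(apply_calibration(calibration, cmd),
                             w = cmd$w %||% rep(1, nrow(cmd)))
          } else cmd
          active <- trap_field(cmd_t, stiffness, capture_radius)
          if (compute_masks) {
            masks[[length(masks) + 1]] <- gsw_optimize(
              trap_configuration(cmd_t$x, cmd_t$y, cmd_t$z - 10, cmd_t$w),
              iterations = 3, seed = seed + length(masks))
          }
        }
        next_cmd <- next_cmd + 1L
      }

      stage <- "render"
      feats <- tryCatch({
        holo <- render_hologram(scene, n = n)
        stage <- "reconstruct"
        vol <- suppressWarnings(reconstruct_volume(holo, z_planes = z_planes))
        stage <- "segment"
        segment_volume(vol, threshold_fraction, min_voxels)
      }, error = function(e) {
        stop("closed loop failed at frame ", fr, ", stage '", stage,
             "': ", conditionMessage(e), call. = FALSE)
      })
      feat_log[[fr]] <- dplyr::mutate(feats, frame = fr, time = t_now)
      truth_log[[fr]] <- dplyr::mutate(scene, frame = fr, time = t_now)

      scene <- advance_scene(scene, substeps, traps = active, dt = dt,
                             env = env, ...)
    }
  })

  feats_all <- dplyr::bind_rows(feat_log)
  tracked <- if (nrow(feats_all) > 0) {
    link_tracks(feats_all, max_link_distance, frame_interval = 1 / fps)
  } else feats_all
  list(frames = tracked, truth = dplyr::bind_rows(truth_log),
       masks = masks, commands = script)
}

#' Demonstration runs of the closed loop
#'
#' `demo_falling_bodies()`: a silica and a polystyrene sphere (radius 1 um)
#' are held at z = 10 um, released, and tracked while they sediment; the
#' denser silica sphere falls measurably faster. `demo_cube()`: eight 2-um
#' silica spheres held on the vertices of a cube follow a rigid rotation of
#' the trap arrangement. `demo_fishing()`: a smooth-swimming bacterium
#' circling near the coverslip is trapped, dragged and released, resuming
#' its initial speed.
#'
#' @param seed Integer seed.
#' @param x_offset Lateral half-separation of the two spheres, um.
#' @param frames Number of imaging frames.
#' @param n Hologram grid side (smaller grids run faster at reduced lateral
#'   sampling).
#' @param ... Passed to [run_closed_loop()].
#' @return The [run_closed_loop()] log.
#' @export
demo_falling_bodies <- function(seed = 1, frames = 24, n = 256,
                                x_offset = 6, ...) {
  scene <- dplyr::bind_rows(
    scene_object("sphere", -x_offset, 0, 10, radius = 1,
                 material = "silica"),
    scene_object("sphere", x_offset, 0, 10, radius = 1,
                 material = "polystyrene"))
  run_closed_loop(scene, script = NULL, frames = frames, fps = 4, n = n,
                  seed = seed, ...)
}

#' @rdname demo_falling_bodies
#' @param rotate_deg Total cube rotation about z, degrees.
#' @param threshold_fraction,min_voxels Segmentation settings; the cube
#'   scene is bright and crowded, so a higher threshold and size filter
#'   separate vertically stacked beads and reject interference ghosts.
#' @export
demo_cube <- function(seed = 1, frames = 6, n = 256, rotate_deg = 45,
                      threshold_fraction = 0.5, min_voxels = 60, ...) {
  half <- 3
  base <- trap_configuration(
    x = half * c(-1, 1, -1, 1, -1, 1, -1, 1),
    y = half * c(-1, -1, 1, 1, -1, -1, 1, 1),
    z = half * c(-1, -1, -1, -1, 1, 1, 1, 1) + 0)
  base$z <- base$z + 10   # imaging space: cube centred at z = 10
  scene <- purrr::pmap_dfr(base, function(x, y, z, w) {
    scene_object("sphere", x, y, z, radius = 1, material = "silica")
  })
  angles <- seq(0, rotate_deg, length.out = frames)
  script <- tibble::tibble(
    time = (seq_len(frames) - 1) / 40,
    traps = purrr::map(angles, function(a) {
      out <- base
      th <- a * pi / 180
      rel <- cbind(base$x, base$y)
      out$x <- rel[, 1] * cos(th) - rel[, 2] * sin(th)
      out$y <- rel[, 1] * sin(th) + rel[, 2] * cos(th)
      out
    }))
  run_closed_loop(scene, script = script, frames = frames, fps = 40, n = n,
                  stiffness = 50, dt = 1e-4, seed = seed,
                  threshold_fraction = threshold_fraction,
                  min_voxels = min_voxels, ...)
}

#' @rdname demo_falling_bodies
#' @export
demo_fishing <- function(seed = 1, frames = 30, n = 256, ...) {
  scene <- scene_object("spherocylinder", -10, 0, 1.2, radius = 0.5,
                        length = 3, ex = 1, ey = 0, ez = 0,
                        material = "ecoli", behavior = "smooth_swimmer",
                        speed = 20)
  # traps are commanded in imaging space here (no calibration model)
  script <- tibble::tibble(
    time = c(10, 20) / 40,
    traps = list(trap_configuration(0, 5, 1.2), NULL))
  run_closed_loop(scene, script = script, frames = frames, fps = 40, n = n,
                  stiffness = 20, dt = 2e-4, seed = seed, ...)
}
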