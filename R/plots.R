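#' Plot methods for the twin's objects
#'
#' `autoplot()` methods render holograms (one facet per colour channel),
#' volumetric images (maximum-intensity projections along z and y), phase
#' masks, and tracked features (x-y paths coloured by speed) as ggplot2
#' figures.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-holotwin
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

mat_to_df <- function(m, pitch, what) {
  ax <- grid_axis(nrow(m), pitch)
  tibble::tibble(
    x = rep(ax, times = ncol(m)),
    y = rep(grid_axis(ncol(m), pitch), each = nrow(m)),
    value = as.vector(m),
    what = what
  )
}

#' @rdname autoplot-holotwin
#' @method autoplot hologram
#' @export
autoplot.hologram <- function(object, ...) {
  df <- purrr::imap_dfr(object$channels,
                        ~mat_to_df(.x, object$pitch, .y))
  df$what <- factor(df$what, levels = names(object$channels))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~what) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "I / I0") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = "RGB in-line hologram")
}

#' @rdname autoplot-holotwin
#' @method autoplot volumetric_image
#' @export
autoplot.volumetric_image <- function(object, ...) {
  ax <- volume_axes(object)
  mip_z <- apply(object$values, c(1, 2), max)
  mip_y <- apply(object$values, c(1, 3), max)
  df <- dplyr::bind_rows(
    tibble::tibble(h = rep(ax$x, length(ax$y)),
                   v = rep(ax$y, each = length(ax$x)),
                   value = as.vector(mip_z), what = "x-y (top view)"),
    tibble::tibble(h = rep(ax$x, length(ax$z)),
                   v = rep(ax$z, each = length(ax$x)),
                   value = as.vector(mip_y), what = "x-z (side view)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$h, .data$v, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~what, scales = "free") +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::labs(x = "(um)", y = "(um)",
                  title = paste("volume maximum-intensity projections -",
                                object$provenance))
}

#' @rdname autoplot-holotwin
#' @method autoplot phase_mask
#' @export
autoplot.phase_mask <- function(object, ...) {
  df <- mat_to_df(object$phases, object$geom$slm_pitch, "phase")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = grDevices::gray.colors(64),
                                  name = "phase (rad)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u (um)", y = "v (um)", title = "SLM phase mask")
}

#' Plot tracked trajectories
#'
#' @param tracks Output of [link_tracks()].
#' @return A ggplot object: x-y paths coloured by instantaneous speed.
#' @export
plot_tracks <- function(tracks) {
  ggplot2::ggplot(tracks,
                  ggplot2::aes(.data$x, .data$y, group = .data$track,
                               colour = .data$speed)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_viridis_c(name = "speed (um/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", title = "object trajectories")
}

#' Replay a closed-loop run as PNG frame montages
#'
#' Writes one PNG per frame showing the tracked features (and, faintly, the
#' ground truth) in the x-y plane, so a recorded run can be replayed and
#' inspected without rerunning the pipeline.
#'
#' @param log A [run_closed_loop()] log.
#' @param dir Output directory (created if needed).
#' @param width,height Image size in pixels.
#' @return The directory, invisibly.
#' @export
export_frame_montage <- function(log, dir, width = 480, height = 480) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  frames <- sort(unique(log$frames$frame))
  rng_x <- range(log$truth$x); rng_y <- range(log$truth$y)
  for (fr in frames) {
    p <- ggplot2::ggplot() +
      ggplot2::geom_point(
        data = dplyr::filter(log$truth, .data$frame == fr),
        ggplot2::aes(.data$x, .data$y), colour = "grey70", size = 3) +
      ggplot2::geom_point(
        data = dplyr::filter(log$frames, .data$frame == fr),
        ggplot2::aes(.data$x, .data$y,
                     colour = factor(.data$track)), size = 1.6) +
      ggplot2::coord_equal(xlim = rng_x + c(-2, 2), ylim = rng_y + c(-2, 2)) +
      ggplot2::labs(x = "x (um)", y = "y (um)",
                    title = sprintf("frame %d", fr), colour = "track")
    grDevices::png(file.path(dir, sprintf("frame_%04d.png", fr)),
                   width = width, height = height)
    print(p)
    grDevices::dev.off()
  }
  invisible(dir)
}
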