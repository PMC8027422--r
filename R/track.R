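#' Link per-frame features into trajectories
#'
#' Greedy nearest-neighbour linking of segmented features across time-ordered
#' frames, with a one-frame gap tolerance: a track that finds no match in the
#' next frame stays open for one more frame before it is closed. When two
#' open tracks compete for the same feature within `max_link_distance`, the
#' closer one wins and the tie is logged as a message. Instantaneous speed is
#' the displacement between consecutive observations divided by their time
#' separation.
#'
#' @param features A tibble of features carrying a `frame` column (integer,
#'   time-ordered) plus `x`, `y`, `z` and any other per-object columns, e.g.
#'   rows of [segment_volume()] outputs bound together.
#' @param max_link_distance Maximum displacement (um) allowed between
#'   consecutive observations of one object.
#' @param frame_interval Time between frames, seconds (default 1/40 s, the
#'   40 fps imaging cadence).
#'
#' @return The input tibble with `track`, `speed` (um/s; `NA` on each track's
#'   first observation) columns, ordered by track then frame.
#' @export
#' @examples
#' fr <- tibble::tibble(frame = 1:5, x = 0.5 * (0:4), y = 0, z = 5)
#' link_tracks(fr, max_link_distance = 1)
link_tracks <- function(features, max_link_distance,
                        frame_interval = 1 / 40) {
  stopifnot(all(c("frame", "x", "y", "z") %in% names(features)),
            max_link_distance > 0, frame_interval > 0)
  if (nrow(features) == 0) {
    return(dplyr::mutate(features, track = integer(), speed = numeric()))
  }
  features <- dplyr::arrange(features, .data$frame)
  frames <- sort(unique(features$frame))
  features$track <- NA_integer_
  features$.row <- seq_len(nrow(features))

  # open tracks: id, last position, last frame
  open <- tibble::tibble(track = integer(), x = numeric(), y = numeric(),
                         z = numeric(), frame = integer())
  next_id <- 1L
  for (fr in frames) {
    cur <- features[features$frame == fr, ]
    open <- open[fr - open$frame <= 2L, ]   # 1-frame gap tolerance
    taken_feat <- rep(FALSE, nrow(cur))
    if (nrow(open) > 0 && nrow(cur) > 0) {
      dmat <- outer(open$x, cur$x, `-`)^2 + outer(open$y, cur$y, `-`)^2 +
        outer(open$z, cur$z, `-`)^2
      dmat <- sqrt(dmat)
      cand <- which(dmat <= max_link_distance, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        cand <- cand[order(dmat[cand]), , drop = FALSE]
        used_track <- rep(FALSE, nrow(open))
        for (r in seq_len(nrow(cand))) {
          i <- cand[r, 1]; j <- cand[r, 2]
          if (used_track[i] || taken_feat[j]) {
            if (!used_track[i] && taken_feat[j]) {
              message("link tie at frame ", fr,
                      ": two tracks within range of one feature; ",
                      "kept the closer link")
            }
            next
          }
          used_track[i] <- TRUE
          taken_feat[j] <- TRUE
          features$track[cur$.row[j]] <- open$track[i]
          open[i, c("x", "y", "z")] <- cur[j, c("x", "y", "z")]
          open$frame[i] <- fr
        }
      }
    }
    if (any(!taken_feat)) {
      fresh <- cur[!taken_feat, ]
      ids <- next_id + seq_len(nrow(fresh)) - 1L
      next_id <- next_id + nrow(fresh)
      features$track[fresh$.row] <- ids
      open <- dplyr::bind_rows(open, tibble::tibble(
        track = ids, x = fresh$x, y = fresh$y, z = fresh$z,
        frame = fr))
    }
  }

  features |>
    dplyr::select(-".row") |>
    dplyr::arrange(.data$track, .data$frame) |>
    dplyr::group_by(.data$track) |>
    dplyr::mutate(speed = sqrt((.data$x - dplyr::lag(.data$x))^2 +
                                 (.data$y - dplyr::lag(.data$y))^2 +
                                 (.data$z - dplyr::lag(.data$z))^2) /
                    ((.data$frame - dplyr::lag(.data$frame)) *
                       frame_interval)) |>
    dplyr::ungroup()
}
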