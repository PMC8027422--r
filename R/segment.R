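#' Segment a volumetric image into object features
#'
#' Thresholds the volume at a fraction of its maximum, labels connected
#' components under 26-connectivity, discards components smaller than
#' `min_voxels`, and summarizes each component by its intensity-weighted
#' moments: the centroid gives the position, the principal eigenvector of the
#' second-moment matrix gives the orientation, and the eigenvalues give the
#' length `l = 4 sqrt(lambda1)` and width `b = 4 sqrt((lambda2 + lambda3)/2)`
#' (the factor 4 being the full extent of a uniform ellipsoid along an
#' eigenaxis). The orientation sign is fixed by `ez >= 0` (the head/tail of a
#' bacterium is not observable); components touching the lateral boundary are
#' flagged.
#'
#' @param volume A [volumetric_image()], normalized or not (the threshold is
#'   relative to its maximum).
#' @param threshold_fraction Fraction of the volume maximum, in (0, 1).
#' @param min_voxels Minimum component size in voxels.
#'
#' @return A tibble with one row per object: `id`, `x`, `y`, `z` (um), `l`,
#'   `b` (um), `ex`, `ey`, `ez`, `voxel_count`, `peak_intensity`,
#'   `on_boundary`. Zero rows for an empty volume.
#' @export
#' @examples
#' v <- volumetric_image(array(0, c(32, 32, 8)))
#' segment_volume(v)  # empty tibble
segment_volume <- function(volume, threshold_fraction = 0.3, min_voxels = 20) {
  stopifnot(inherits(volume, "volumetric_image"),
            threshold_fraction > 0, threshold_fraction < 1,
            min_voxels >= 1)
  arr <- volume$values
  vmax <- max(arr)
  empty <- tibble::tibble(
    id = integer(), x = numeric(), y = numeric(), z = numeric(),
    l = numeric(), b = numeric(), ex = numeric(), ey = numeric(),
    ez = numeric(), voxel_count = integer(), peak_intensity = numeric(),
    on_boundary = logical())
  if (vmax <= 0) return(empty)

  idx <- which(arr >= threshold_fraction * vmax)
  if (length(idx) == 0) return(empty)
  d <- dim(arr)
  coords <- arrayInd(idx, d)
  labels <- label_components_26(coords, d)

  ax <- volume_axes(volume)
  pitches <- c(volume$lateral_pitch, volume$lateral_pitch, volume$axial_pitch)
  feats <- purrr::map_dfr(split(seq_along(idx), labels), function(rows) {
    if (length(rows) < min_voxels) return(NULL)
    cc <- coords[rows, , drop = FALSE]
    w <- arr[idx[rows]]
    pos <- cbind(ax$x[cc[, 1]], ax$y[cc[, 2]], ax$z[cc[, 3]])
    ctr <- colSums(pos * w) / sum(w)
    dc <- sweep(pos, 2, ctr)
    M <- crossprod(dc * sqrt(w / sum(w)))
    # smear each voxel by its own extent so single-plane components stay
    # non-degenerate
    M <- M + diag(pitches^2 / 12)
    eg <- eigen(M, symmetric = TRUE)
    e1 <- eg$vectors[, 1]
    if (e1[3] < 0 || (e1[3] == 0 && e1[1] < 0)) e1 <- -e1
    tibble::tibble(
      x = ctr[1], y = ctr[2], z = ctr[3],
      l = 4 * sqrt(max(eg$values[1], 0)),
      b = 4 * sqrt(max((eg$values[2] + eg$values[3]) / 2, 0)),
      ex = e1[1], ey = e1[2], ez = e1[3],
      voxel_count = length(rows),
      peak_intensity = max(w),
      on_boundary = any(cc[, 1] %in% c(1L, d[1])) ||
        any(cc[, 2] %in% c(1L, d[2]))
    )
  })
  if (nrow(feats) == 0) return(empty)
  feats <- dplyr::arrange(feats, dplyr::desc(.data$voxel_count))
  dplyr::mutate(feats, id = dplyr::row_number(), .before = 1)
}

# Label a sparse voxel set under 26-connectivity. `coords` is an m x 3 index
# matrix, `d` the array dimensions. Returns an integer label per row.
# Union-find over the neighbour graph found by hashing linear indices.
label_components_26 <- function(coords, d) {
  m <- nrow(coords)
  lin <- (as.numeric(coords[, 3]) - 1) * d[1] * d[2] +
    (as.numeric(coords[, 2]) - 1) * d[1] + as.numeric(coords[, 1])
  ord <- order(lin)
  lin_sorted <- lin[ord]

  parent <- seq_len(m)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }

  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  # only half of the offsets are needed: each pair is seen from one side
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
                 (offs$dz == 0 & offs$dy == 0 & offs$dx > 0), ]

  for (r in seq_len(nrow(offs))) {
    dx <- offs$dx[r]; dy <- offs$dy[r]; dz <- offs$dz[r]
    nx <- coords[, 1] + dx; ny <- coords[, 2] + dy; nz <- coords[, 3] + dz
    valid <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
    nlin <- (as.numeric(nz) - 1) * d[1] * d[2] + (as.numeric(ny) - 1) * d[1] +
      as.numeric(nx)
    hit <- findInterval(nlin, lin_sorted)
    ok <- valid & hit > 0 & lin_sorted[pmax(hit, 1)] == nlin
    src <- which(ok)
    dst <- ord[hit[ok]]
    for (j in seq_along(src)) {
      a <- find(src[j]); b <- find(dst[j])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  match(roots, unique(roots))
}

#' Export features or tracks as CSV
#'
#' @param features A features or tracks tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
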