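z_test_planes <- seq(0, 14, by = 1 / 3)

test_that("a blank hologram reconstructs to an all-zero volume", {
  blank <- matrix(1, 64, 64)
  # a 64-px tile cannot alias-safely reach z = 10 um, so this also checks
  # the depth-range warning
  expect_warning(
    v <- backpropagate_channel(blank, 0.63, 20, 0, pitch = 56 / 512,
                               z_planes = c(0, 5, 10)),
    "anti-aliasing")
  expect_true(all(v$values == 0))
})

test_that("a single sphere reconstructs at its true position", {
  true_pos <- c(2, -3, 5)
  sc <- scene_object("sphere", true_pos[1], true_pos[2], true_pos[3],
                     radius = 0.5)
  h <- suppressWarnings(render_hologram(sc, n = 256))
  vols <- suppressWarnings(reconstruct_channels(h, z_planes = z_test_planes))
  ax <- volume_axes(vols$R)
  for (v in vols) {
    w <- which(v$values == max(v$values), arr.ind = TRUE)[1, ]
    got <- c(ax$x[w[1]], ax$y[w[2]], ax$z[w[3]])
    # per-channel argmax: lateral within a few voxels (residual shear from
    # the phase-object axial focus bias), axial within 2 voxels
    expect_lt(max(abs(got[1:2] - true_pos[1:2])), 0.35)
    expect_lt(abs(got[3] - true_pos[3]), 0.67 + 1e-9)
  }
  ov <- overlap_volumes(vols)
  ctr <- volume_centroid(ov)
  # overlap centroid: sub-voxel laterally, < 2 voxels axially
  expect_lt(abs(ctr$x - true_pos[1]), 56 / 512)
  expect_lt(abs(ctr$y - true_pos[2]), 56 / 512)
  expect_lt(abs(ctr$z - true_pos[3]), 2 / 3)
})

test_that("without tilt compensation the image is sheared by z tan(theta)", {
  z <- 8
  sc <- scene_object("sphere", 0, 0, z, radius = 0.5)
  h <- suppressWarnings(render_hologram(sc, n = 256))
  v <- suppressWarnings(
    backpropagate_channel(h$channels$R, 0.630, 20, 0, pitch = h$pitch,
                          z_planes = z_test_planes, compensate_tilt = FALSE))
  ax <- volume_axes(v)
  w <- which(v$values == max(v$values), arr.ind = TRUE)[1, ]
  # the R channel (azimuth 0) peak walks off along x by about z tan(20 deg)
  expect_equal(abs(ax$x[w[1]]), z * tan(20 * pi / 180), tolerance = 0.25)
  expect_lt(abs(ax$y[w[2]]), 0.35)
})

test_that("overlap normalizes, preserves identical inputs, checks grids", {
  arr <- array(runif(16 * 16 * 5), c(16, 16, 5))
  v <- volumetric_image(arr, 0.1, 0.5, 0)
  ov <- overlap_volumes(list(v, v, v))
  expect_equal(max(ov$values), 1)
  expect_true(all(ov$values >= 0))
  # three identical volumes: overlap proportional to each input
  nrm <- (arr - min(arr)) / (max(arr) - min(arr))
  expect_equal(ov$values, nrm / max(nrm), tolerance = 1e-12)

  v2 <- volumetric_image(arr[, , 1:4], 0.1, 0.5, 0)
  expect_error(overlap_volumes(list(v, v, v2)), "grid")
  v3 <- volumetric_image(arr, 0.2, 0.5, 0)
  expect_error(overlap_volumes(list(v, v, v3)), "grid")

  ovm <- overlap_volumes(list(v, v, v), method = "min")
  expect_equal(max(ovm$values), 1)
})

test_that("channel overlap sharpens the axial response", {
  sc <- scene_object("sphere", 0, 0, 8, radius = 0.5)
  h <- suppressWarnings(render_hologram(sc, n = 256))
  # fine axial sampling so the FWHM comparison is not grid-quantized
  vols <- suppressWarnings(
    reconstruct_channels(h, z_planes = seq(4, 12, by = 1 / 6)))
  ov <- overlap_volumes(vols)
  fwhm_z <- function(v) {
    prof <- apply(v$values, 3, max)
    sum(prof >= 0.5 * max(prof)) * v$axial_pitch
  }
  for (v in vols) expect_lt(fwhm_z(ov), fwhm_z(v))
})

test_that("random single-sphere scenes localize to sub-voxel accuracy", {
  lat_err <- ax_err <- numeric(0)
  withr::with_seed(11, {
    for (i in 1:10) {
      pos <- c(runif(2, -8, 8), runif(1, 3, 11))
      sc <- scene_object("sphere", pos[1], pos[2], pos[3], radius = 0.5)
      h <- suppressWarnings(render_hologram(sc, n = 256))
      ov <- suppressWarnings(
        reconstruct_volume(h, z_planes = z_test_planes))
      ctr <- volume_centroid(ov)
      lat_err <- c(lat_err, sqrt((ctr$x - pos[1])^2 + (ctr$y - pos[2])^2))
      ax_err <- c(ax_err, abs(ctr$z - pos[3]))
    }
  })
  expect_lt(median(lat_err), 56 / 512)    # < 1 lateral voxel
  expect_lt(median(ax_err), 2 / 3)        # < 2 axial voxels
})

test_that("volumes round-trip through multi-page TIFF", {
  arr <- array(runif(8 * 8 * 3), c(8, 8, 3))
  v <- volumetric_image(arr, 0.1, 0.5, 1, provenance = "overlap:geomean")
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_lt(max(abs(v2$values - v$values)), 1e-6)
  expect_equal(v2$z_origin, 1)
  expect_equal(v2$provenance, "overlap:geomean")
})
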