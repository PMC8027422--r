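geom64 <- slm_geometry(64)
geom128 <- slm_geometry(128)
geom256 <- slm_geometry(256)

circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

test_that("the trap kernel reduces to grating and lens limits", {
  k0 <- trap_kernel(0, 0, 0, geom64)
  expect_lt(max(Mod(k0 - k0[1, 1])), 1e-12)            # on-axis: constant

  kx <- trap_kernel(5, 0, 0, geom64)                   # blazed grating
  expect_lt(max(abs(Mod(kx) - 1)), 1e-12)
  ramp <- Arg(kx[2:64, 1] / kx[1:63, 1])
  expect_lt(diff(range(ramp)), 1e-9)                   # pure linear ramp in u
  expect_lt(max(abs(Arg(kx[1, 2:64] / kx[1, 1:63]))), 1e-12)

  kz <- trap_kernel(0, 0, 4, geom64)                   # Fresnel lens
  u <- grid_axis(64, geom64$slm_pitch)
  want <- geom64$k * 4 / (2 * geom64$focal_length^2) * outer(u^2, u^2, `+`)
  expect_lt(max(circ_diff(Arg(kz), want %% (2 * pi))), 1e-9)
})

test_that("a single trap is solved exactly by its own kernel phase", {
  tr <- trap_configuration(6, -3, 2)
  mask <- gsw_optimize(tr, iterations = 3, seed = 5, geom = geom128)
  expect_gt(mask$metrics$efficiency, 0.99)
  want <- Arg(trap_kernel(6, -3, 2, geom128))
  d <- circ_diff(mask$phases, want %% (2 * pi))
  # equal up to one global phase constant
  offs <- Arg(mean(exp(1i * (mask$phases - want))))
  expect_lt(max(circ_diff(mask$phases, (want + offs) %% (2 * pi))), 1e-6)
})

test_that("focal spots land where commanded", {
  # blazed grating: peak at (x, 0, 0) within one focal voxel
  tr <- trap_configuration(8, 0, 0)
  mask <- gsw_optimize(tr, iterations = 0, seed = 1, geom = geom256)
  ff <- simulate_focal_field(mask, z_planes = 0)
  ax <- grid_axis(geom256$n, geom256$focal_pitch)
  w <- which(ff$values[, , 1] == max(ff$values), arr.ind = TRUE)[1, ]
  expect_lt(abs(ax[w[1]] - 8), geom256$focal_pitch)
  expect_lt(abs(ax[w[2]]), geom256$focal_pitch)

  # axial trap: intensity maximum at the commanded z plane
  trz <- trap_configuration(0, 0, 5)
  maskz <- gsw_optimize(trz, iterations = 0, seed = 1, geom = geom256)
  zp <- seq(-8, 8, by = 0.5)
  ffz <- simulate_focal_field(maskz, z_planes = zp)
  pk <- apply(ffz$values, 3, max)
  expect_equal(zp[which.max(pk)], 5, tolerance = 0.5 + 1e-9)
})

test_that("three collinear traps reach workable uniformity at 3 iterations", {
  tr <- trap_configuration(c(-8, 0, 8), c(0, 0, 0), c(0, 0, 0))
  mask <- gsw_optimize(tr, iterations = 3, seed = 2, geom = geom256)
  fm <- focal_field_metrics(mask, tr)
  expect_equal(length(fm$per_trap_intensity), 3)
  expect_gt(fm$uniformity, 0.6)
  expect_true(all(fm$peak_offset_voxels <= 1))
})

test_that("GSW efficiency is non-decreasing in expectation with iterations", {
  iters <- c(0, 1, 3, 5)
  eff <- matrix(NA_real_, 10, length(iters))
  unif3 <- unif0 <- numeric(10)
  for (s in 1:10) {
    tr <- withr::with_seed(100 + s, trap_configuration(
      stats::runif(10, -25, 25), stats::runif(10, -25, 25),
      stats::runif(10, -9, 9)))
    for (j in seq_along(iters)) {
      m <- gsw_optimize(tr, iterations = iters[j], seed = s, geom = geom128)
      eff[s, j] <- m$metrics$efficiency
      if (iters[j] == 0) unif0[s] <- m$metrics$uniformity
      if (iters[j] == 3) unif3[s] <- m$metrics$uniformity
    }
  }
  means <- colMeans(eff)
  expect_true(all(diff(means) > -1e-3))
  # weighting beats the raw random superposition for at least 9 of 10 seeds
  expect_gte(sum(unif3 > unif0), 9)
})

test_that("trap arrangements move rigidly and stay in the volume", {
  cube <- trap_configuration(
    x = 3 * c(-1, 1, -1, 1, -1, 1, -1, 1),
    y = 3 * c(-1, -1, 1, 1, -1, -1, 1, 1),
    z = 3 * c(-1, -1, -1, -1, 1, 1, 1, 1))
  expect_equal(move_traps(cube), cube)

  shifted <- move_traps(cube, translate = c(1, 2, 3))
  expect_equal(shifted$x, cube$x + 1)
  expect_equal(shifted$y, cube$y + 2)
  expect_equal(shifted$z, cube$z + 3)

  rot <- move_traps(cube, rotate_z = 90)
  key <- function(df) sort(apply(round(df[, c("x", "y", "z")], 9), 1,
                                 paste, collapse = ","))
  expect_equal(key(rot), key(cube))       # 90 deg z-rotation maps cube to itself

  expect_error(move_traps(cube, translate = c(30, 0, 0)), "outside")
  expect_error(trap_configuration(0, 0, 30), "outside")
})

test_that("masks export to PNG and trap lists round-trip as text", {
  tr <- trap_configuration(c(1, -4), c(2, 3), c(0, 5), w = c(1, 2))
  mask <- gsw_optimize(tr, iterations = 1, seed = 1, geom = geom64)
  png_path <- withr::local_tempfile(fileext = ".png")
  export_mask_png(mask, png_path)
  img <- png::readPNG(png_path)
  expect_equal(dim(img), c(64, 64))
  expect_lt(max(abs(t(img) * 2 * pi - mask$phases)), 2 * pi / 255)

  txt <- withr::local_tempfile(fileext = ".txt")
  write_traps(tr, txt)
  back <- read_traps(txt)
  expect_equal(as.data.frame(back), as.data.frame(tr))
})
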