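test_that("an empty scene renders a pure unit background", {
  h <- render_hologram(scene_object("sphere", 0, 0, 5, radius = 1)[0, ],
                       n = 64)
  for (ch in h$channels) expect_true(all(ch == 1))
})

test_that("noiseless holograms are normalized to unit mean background", {
  sc <- scene_object("sphere", 1, -2, 5, radius = 0.5)
  h <- suppressWarnings(render_hologram(sc, n = 128))
  for (ch in h$channels) {
    expect_lt(abs(mean(ch) - 1), 1e-6)
    expect_true(all(ch >= 0))
  }
})

test_that("fringe pattern is sheared by z tan(theta) along each tilt azimuth", {
  z <- 8
  sc <- scene_object("sphere", 0, 0, z, radius = 0.5)
  h <- suppressWarnings(render_hologram(sc, n = 256))
  ax <- grid_axis(256, h$pitch)
  shear <- z * tan(20 * pi / 180)
  for (i in 1:3) {
    c2 <- (h$channels[[i]] - 1)^2
    cx <- sum(outer(ax, rep(1, 256)) * c2) / sum(c2)
    cy <- sum(outer(rep(1, 256), ax) * c2) / sum(c2)
    az <- h$illumination$tilt_azimuth[i] * pi / 180
    # centroid sits opposite the tilt azimuth, |offset| ~ z tan(theta)
    expect_equal(sqrt(cx^2 + cy^2), shear, tolerance = 0.15)
    along <- cx * cos(az) + cy * sin(az)
    across <- -cx * sin(az) + cy * cos(az)
    expect_lt(along, -0.8 * shear)
    expect_lt(abs(across), 0.3)
  }
})

test_that("shot noise is reproducible from the seed", {
  sc <- scene_object("sphere", 0, 0, 5, radius = 0.5)
  h1 <- suppressWarnings(render_hologram(sc, n = 64, noise_photons = 1e4,
                                         seed = 42))
  h2 <- suppressWarnings(render_hologram(sc, n = 64, noise_photons = 1e4,
                                         seed = 42))
  h3 <- suppressWarnings(render_hologram(sc, n = 64, noise_photons = 1e4,
                                         seed = 43))
  expect_identical(h1$channels, h2$channels)
  expect_false(identical(h1$channels, h3$channels))
  expect_error(render_hologram(sc, n = 64, noise_photons = 1e4), "seed")
})

test_that("contrast is linear over well-separated weak scatterers", {
  s1 <- scene_object("sphere", -4, 0, 5, radius = 0.4, material = NULL,
                     refractive_index = 1.36, density = 1.1)
  s2 <- scene_object("sphere", 4, 1, 7, radius = 0.4, material = NULL,
                     refractive_index = 1.36, density = 1.1)
  h1 <- suppressWarnings(render_hologram(s1, n = 128))
  h2 <- suppressWarnings(render_hologram(s2, n = 128))
  h12 <- suppressWarnings(render_hologram(dplyr::bind_rows(s1, s2), n = 128))
  for (nm in c("R", "G", "B")) {
    sum_c <- (h1$channels[[nm]] - 1) + (h2$channels[[nm]] - 1)
    joint <- h12$channels[[nm]] - 1
    rel_rms <- sqrt(mean((joint - sum_c)^2)) / sqrt(mean(joint^2))
    expect_lt(rel_rms, 0.01)
  }
})

test_that("scene validation flags overlap and out-of-volume objects", {
  touching <- dplyr::bind_rows(
    scene_object("sphere", 0, 0, 5, radius = 1),
    scene_object("sphere", 0.5, 0, 5, radius = 1))
  expect_warning(validate_scene(touching), "overlap")
  outside <- scene_object("sphere", 40, 0, 5, radius = 1)
  expect_error(render_hologram(outside, n = 128), "outside")
  expect_error(scene_object("spherocylinder", 0, 0, 5, radius = 1,
                            length = 1), "length")
})

test_that("illumination configuration enforces channel ordering", {
  expect_error(illumination_config(wavelengths = c(0.46, 0.52, 0.63)))
  expect_error(illumination_config(tilt_azimuth = c(0, 0, 120)))
  ic <- illumination_config()
  expect_equal(ic$wavelength, c(0.630, 0.520, 0.460))
})

test_that("holograms round-trip through TIFF and scenes through YAML", {
  sc <- scene_object("sphere", 2, 1, 6, radius = 0.8)
  h <- suppressWarnings(render_hologram(sc, n = 64))
  path <- withr::local_tempfile(fileext = ".tif")
  write_hologram(h, path)
  h2 <- read_hologram(path)
  expect_equal(h2$pitch, h$pitch)
  expect_lt(max(abs(h2$channels$G - h$channels$G)), 1e-6)
  expect_equal(h2$illumination$wavelength, h$illumination$wavelength)

  png_path <- withr::local_tempfile(fileext = ".png")
  export_hologram_png(h, png_path)
  expect_true(file.exists(png_path))

  sc2 <- dplyr::bind_rows(
    sc, scene_object("spherocylinder", -3, 2, 4, radius = 0.5, length = 3,
                     ex = 1, ey = 1, ez = 0.5, material = "ecoli",
                     behavior = "smooth_swimmer", speed = 20))
  ypath <- withr::local_tempfile(fileext = ".yaml")
  write_scene(sc2, ypath)
  back <- read_scene(ypath)
  expect_equal(as.data.frame(back), as.data.frame(sc2), tolerance = 1e-12)
})
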