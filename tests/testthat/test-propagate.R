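test_that("propagation by zero distance is the identity", {
  f <- gaussian_field(32)
  g <- propagate(f, 0)
  expect_identical(g$values, f$values)
})

test_that("propagation conserves total intensity on the propagating band", {
  f <- gaussian_field(64)
  # restrict the spectrum to the band that survives the largest |dz| used,
  # then propagation is unitary there
  tf <- holotwin:::transfer_function(64, f$pitch, f$wavelength,
                                     f$medium_index, 10)
  f$values <- holotwin:::ifft2(holotwin:::fft2(f$values) * (Mod(tf) > 0))
  for (dz in c(-7.5, -1, 0.5, 3, 10)) {
    g <- propagate(f, dz)
    expect_lt(abs(sum(Mod(g$values)^2) / sum(Mod(f$values)^2) - 1), 1e-9)
  }
})

test_that("propagation is invertible and composes over distances", {
  withr::with_seed(7, {
    for (rep in 1:3) {
      # random band-limited field: smooth envelope times random phase ripple
      f <- gaussian_field(64, sigma_px = 2 + rep)
      f$values <- f$values * exp(0.3i * matrix(rnorm(64^2), 64))
      # keep the spectrum inside the band-limit mask of the largest |dz| used
      tf <- holotwin:::transfer_function(64, f$pitch, f$wavelength,
                                         f$medium_index, 6)
      f$values <- holotwin:::ifft2(holotwin:::fft2(f$values) * (Mod(tf) > 0))
      a <- runif(1, -3, 3); b <- runif(1, -3, 3)

      round_trip <- propagate(propagate(f, a), -a)
      expect_lt(max(Mod(round_trip$values - f$values)), 1e-9)

      two_step <- propagate(propagate(f, a), b)
      one_step <- propagate(f, a + b)
      expect_lt(max(Mod(two_step$values - one_step$values)), 1e-9)
    }
  })
})

test_that("FFT propagation matches the direct Rayleigh-Sommerfeld summation", {
  # compact band-limited emitter; FFT run on a 4x padded grid so the
  # circular convolution reproduces the oracle's open aperture
  n <- 32; pad <- 4; pitch <- 0.2; wl <- 0.52; dz <- 5
  f <- gaussian_field(n, pitch = pitch, wavelength = wl)
  np <- n * pad
  big <- matrix(0 + 0i, np, np)
  i0 <- np / 2 - n / 2
  big[i0 + (1:n), i0 + (1:n)] <- f$values
  res <- propagate(complex_field(big, pitch, wl, f$medium_index), dz)
  got <- res$values[i0 + (1:n), i0 + (1:n)]

  dest <- (n / 4 + 1):(3 * n / 4)   # central quarter
  want <- rs_direct_sum(f$values, pitch, wl, f$medium_index, dz, dest)
  rel <- max(Mod(got[dest, dest] - want)) / max(Mod(want))
  expect_lt(rel, 1e-6)
})

test_that("invalid fields are rejected", {
  expect_error(complex_field(matrix(0i, 8, 4), 0.1, 0.5), "square")
  expect_error(complex_field(matrix(0i, 24, 24), 0.1, 0.5), "power of two")
  bad <- matrix(complex(real = c(NaN, rep(0, 15))), 4)
  expect_error(complex_field(bad, 0.1, 0.5), "non-finite")
})

test_that("tilted plane waves carry the analytic phase ramp", {
  wl <- 0.63; nm <- 1.33
  f <- tilted_plane_wave(20, 0, wl, n = 64, pitch = 0.1, medium_index = nm)
  expect_true(all(abs(Mod(f$values) - 1) < 1e-12))
  # phase gradient along +x equals k n sin(20 deg) = (2 pi nm / wl) sin(20)
  dphi <- Arg(f$values[2:64, 1] / f$values[1:63, 1]) / 0.1
  expect_true(all(abs(dphi - 2 * pi * nm / wl * sin(20 * pi / 180)) < 1e-9))
  # no gradient along y at azimuth 0
  expect_true(all(abs(Arg(f$values[1, 2:64] / f$values[1, 1:63])) < 1e-12))

  flat <- tilted_plane_wave(0, 0, wl, n = 32, pitch = 0.1)
  expect_lt(max(Mod(flat$values - flat$values[1, 1])), 1e-12)

  a <- tilted_plane_wave(15, 40, wl, n = 32, pitch = 0.1)
  b <- tilted_plane_wave(15, 220, wl, n = 32, pitch = 0.1)
  expect_lt(max(Mod(b$values - Conj(a$values))), 1e-9)
})

test_that("tilts outside the objective acceptance cone warn but proceed", {
  # with a water-dipping NA below the medium index, steep tilts fall outside
  expect_warning(tilted_plane_wave(75, 0, 0.52, n = 32, pitch = 0.1,
                                   numerical_aperture = 1.2),
                 "acceptance")
  expect_silent(tilted_plane_wave(20, 0, 0.52, n = 32, pitch = 0.1))
})

test_that("complex fields round-trip through float TIFF", {
  f <- gaussian_field(32)
  f$values <- f$values * exp(1i * 0.7)
  path <- withr::local_tempfile(fileext = ".tif")
  write_complex_field(f, path)
  g <- read_complex_field(path)
  expect_equal(g$pitch, f$pitch)
  expect_equal(g$wavelength, f$wavelength)
  expect_lt(max(Mod(g$values - f$values)), 1e-6)
})
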