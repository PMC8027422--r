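test_that("zero temperature, zero force leaves a neutral particle still", {
  env <- sample_environment(temperature = 0, fluid_density = 1.05)
  sc <- scene_object("sphere", 1, 2, 5, radius = 1, material = "polystyrene")
  out <- advance_scene(sc, 100, dt = 1e-3, env = env)
  expect_equal(c(out$x, out$y, out$z), c(1, 2, 5), tolerance = 1e-12)
})

test_that("sedimentation speed matches the Stokes closed form to 0.1%", {
  env <- sample_environment(temperature = 0, viscosity = 8.9e-4,
                            fluid_density = 1.00)
  a <- 1
  sc <- scene_object("sphere", 0, 0, 15, radius = a, material = NULL,
                     refractive_index = 1.45, density = 2.00)
  steps <- 1000; dt <- 1e-3
  out <- advance_scene(sc, steps, dt = dt, env = env)
  v_sim <- (15 - out$z) / (steps * dt)
  # v = 2 drho g a^2 / (9 eta), converted to um/s
  drho_si <- (2.00 - 1.00) * 1e3
  v_stokes <- 2 * drho_si * 9.81 * (a * 1e-6)^2 / (9 * 8.9e-4) * 1e6
  expect_equal(v_stokes, 2.45, tolerance = 0.002)  # about 2.45 um/s
  expect_lt(abs(v_sim - v_stokes) / v_stokes, 1e-3)
})

test_that("free diffusion reproduces the Einstein relation within 5%", {
  env <- sample_environment(fluid_density = 1.05)   # neutral buoyancy
  n <- 800
  sc <- do.call(dplyr::bind_rows, purrr::map(seq_len(n), function(i) {
    scene_object("sphere", 0, 0, 100, radius = 1, material = "polystyrene")
  }))
  sc$z <- rep(100, n)   # far from the wall
  vol <- list(xmin = -1e6, xmax = 1e6, ymin = -1e6, ymax = 1e6,
              zmin = 0, zmax = 1e6)
  steps <- 120; dt <- 1e-3
  out <- withr::with_seed(9, advance_scene(sc, steps, dt = dt, env = env,
                                           volume = vol))
  msd <- mean((out$x - sc$x)^2 + (out$y - sc$y)^2 + (out$z - sc$z)^2)
  gam <- 6 * pi * 8.9e-4 * 1
  D <- 1.380649e-5 * 295 / gam
  expect_equal(msd / (steps * dt), 6 * D, tolerance = 0.05)
  # ensemble mean displacement consistent with zero
  se <- sqrt(2 * D * steps * dt / n)
  expect_lt(abs(mean(out$x - sc$x)), 3 * se)
  expect_lt(abs(mean(out$y - sc$y)), 3 * se)
})

test_that("a trapped particle obeys equipartition within 10%", {
  env <- sample_environment(fluid_density = 1.05)
  kappa <- 5
  n <- 100
  sc <- do.call(dplyr::bind_rows, purrr::map(seq_len(n), function(i) {
    scene_object("sphere", 0, 0, 10, radius = 1, material = "polystyrene")
  }))
  tf <- trap_field(tibble::tibble(x = 0, y = 0, z = 10, w = 1),
                   stiffness = kappa, capture_radius = 1.5)
  dt <- 1e-4
  xs <- ys <- NULL
  withr::with_seed(13, {
    sc <- advance_scene(sc, 500, traps = tf, dt = dt, env = env)  # relax
    for (b in 1:20) {
      sc <- advance_scene(sc, 100, traps = tf, dt = dt, env = env)
      xs <- c(xs, sc$x); ys <- c(ys, sc$y)
    }
  })
  var_want <- 1.380649e-5 * 295 / kappa
  expect_equal(mean(c(var(xs), var(ys))), var_want, tolerance = 0.10)
})

test_that("the coverslip wall is impenetrable", {
  env <- sample_environment(temperature = 310)
  sc <- scene_object("sphere", 0, 0, 1.2, radius = 1, material = "silica")
  withr::with_seed(4, {
    for (i in 1:200) {
      sc <- step_scene(sc, dt = 1e-3, env = env)
      expect_gte(sc$z, sc$radius)
    }
  })
})

test_that("swimmers circle near the wall and go straight above it", {
  env <- sample_environment(temperature = 0)
  mk <- function(z) scene_object("spherocylinder", 0, -10, z, radius = 0.5,
                                 length = 3, ex = 1, ey = 0, ez = 0,
                                 material = "ecoli",
                                 behavior = "smooth_swimmer", speed = 10)
  # near the wall: heading precesses at omega = 1 rad/s about z
  low <- advance_scene(mk(1), 1000, dt = 1e-3, env = env, omega = 1,
                       rot_diffusion = 0)
  expect_equal(atan2(low$ey, low$ex), 1, tolerance = 1e-3)
  # far from the wall: straight run at constant speed
  high <- advance_scene(mk(10), 1000, dt = 1e-3, env = env, omega = 1,
                        rot_diffusion = 0)
  expect_equal(high$ex, 1, tolerance = 1e-12)
  expect_equal(high$x, 0 + 10 * 1, tolerance = 1e-9)
})

test_that("the virtual pointer picks the nearest intersected object", {
  feats <- tibble::tibble(
    x = c(0, 0, 5), y = c(0, 0, 0), z = c(5, 12, 5),
    l = c(2, 2, 3), b = c(2, 2, 1),
    ex = c(0, 0, 1), ey = c(0, 0, 0), ez = c(1, 1, 0))
  # ray down the z axis from above: hits both axis spheres, near one first
  hit <- pointer_pick(c(0, 0, 20), c(0, 0, -1), feats)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$z, 12)
  expect_equal(hit$hit_distance, 20 - 12 - 1, tolerance = 1e-6)
  # brute-force check of the ordering
  expect_lt(hit$hit_distance, 20 - 5 - 1)

  # miss
  miss <- pointer_pick(c(30, 30, 20), c(0, 0, -1), feats)
  expect_equal(nrow(miss), 0)

  # capsule hit from the side
  hit2 <- pointer_pick(c(5, 10, 5), c(0, -1, 0), feats)
  expect_equal(hit2$x, 5)
  expect_equal(hit2$hit_distance, 10 - 0.5, tolerance = 1e-6)
})

test_that("objects leaving the lateral field of view are removed with a log", {
  env <- sample_environment(temperature = 0)
  sc <- scene_object("spherocylinder", 27.5, 0, 5, radius = 0.5, length = 3,
                     ex = 1, ey = 0, ez = 0, material = "ecoli",
                     behavior = "smooth_swimmer", speed = 20)
  expect_message(
    out <- advance_scene(sc, 100, dt = 1e-3, env = env, rot_diffusion = 0),
    "removed")
  expect_equal(nrow(out), 0)
})
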