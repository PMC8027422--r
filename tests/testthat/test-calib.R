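grid_pairs <- function(T = diag(3), r0 = c(0, 0, 0), alpha = 0,
                       nx = 3, nz = 3, span = 20, zmax = 16,
                       noise_sd = 0) {
  g <- expand.grid(x = seq(-span / 2, span / 2, length.out = nx),
                   y = seq(-span / 2, span / 2, length.out = nx),
                   z = seq(0, zmax, length.out = nz))
  r <- as.matrix(g)
  rp <- r %*% t(T) + matrix(r0, nrow(r), 3, byrow = TRUE)
  rp[, 3] <- rp[, 3] + alpha * r[, 3]^2
  if (noise_sd > 0) rp <- rp + rnorm(length(rp), 0, noise_sd)
  tibble::tibble(x = r[, 1], y = r[, 2], z = r[, 3],
                 xp = rp[, 1], yp = rp[, 2], zp = rp[, 3])
}

test_that("noiseless identity pairs are recovered exactly", {
  fit <- fit_calibration(grid_pairs())
  expect_lt(max(abs(fit$T - diag(3))), 1e-9)
  expect_lt(max(abs(fit$r0)), 1e-9)
  expect_lt(abs(fit$alpha), 1e-12)
  expect_lt(max(fit$residual_rms), 1e-9)
})

test_that("all 13 parameters are recovered within 3 standard errors", {
  withr::with_seed(21, {
    T_true <- diag(3) + matrix(runif(9, -0.1, 0.1), 3)
    r0_true <- c(1.5, -2, 0.7)
    alpha_true <- 0.01
    pairs <- grid_pairs(T_true, r0_true, alpha_true, nx = 5, nz = 5,
                        span = 40, zmax = 16, noise_sd = 0.01)
    fit <- fit_calibration(pairs)
    td <- tidy(fit)
    truth <- c(t(T_true), r0_true, alpha_true)
    zscore <- abs(td$estimate - truth) / td$std.error
    expect_true(all(zscore < 3))
    g <- glance(fit)
    expect_equal(g$n, 125)
    expect_lt(g$rms_z, 0.05)
  })
})

test_that("a pure z^2 displacement isolates alpha with T_zz = 1", {
  pairs <- grid_pairs(alpha = 0.02, nx = 3, nz = 7)
  fit <- fit_calibration(pairs)
  expect_equal(fit$alpha, 0.02, tolerance = 1e-9)
  expect_equal(fit$T[3, 3], 1, tolerance = 1e-9)
})

test_that("the fit is equivariant under translations of the imaging frame", {
  withr::with_seed(5, {
    T_true <- diag(3) + matrix(runif(9, -0.05, 0.05), 3)
    pairs <- grid_pairs(T_true, r0 = c(0.5, 1, -1))
    fit0 <- fit_calibration(pairs)
    d <- c(3, -2, 1)
    shifted <- dplyr::mutate(pairs, x = x + d[1], y = y + d[2], z = z + d[3])
    fit1 <- fit_calibration(shifted)
    expect_equal(fit1$r0, fit0$r0 - as.vector(T_true %*% d),
                 tolerance = 1e-8)
  })
})

test_that("degenerate calibration scans are rejected by axis name", {
  flat <- grid_pairs()
  flat$z <- 5; flat$zp <- 5
  expect_error(fit_calibration(flat), "z")
  expect_error(fit_calibration(grid_pairs()[1:10, ]), "13")
  two_z <- grid_pairs(nz = 2)
  expect_error(fit_calibration(two_z), "3 distinct z")
})

test_that("apply and invert are consistent to 1e-6 um", {
  model <- fit_calibration(grid_pairs(
    T = diag(3) * c(1.05, 0.95, 1.02), r0 = c(1, 2, 3), alpha = 0.01))
  pts <- tibble::tibble(x = c(0, 5, -7), y = c(0, -3, 4), z = c(10, 2, 8))
  fwd <- apply_calibration(model, pts)
  expect_equal(fwd$z[1], 1.02 * 10 + 3 + 0.01 * 100, tolerance = 1e-9)
  back <- invert_calibration(model, fwd)
  expect_lt(max(abs(as.matrix(back) - as.matrix(pts))), 1e-6)
})

test_that("identity model is the identity map", {
  model <- fit_calibration(grid_pairs())
  pts <- tibble::tibble(x = 1:3, y = 4:6, z = 7:9)
  expect_equal(unname(as.matrix(apply_calibration(model, pts))),
               unname(as.matrix(pts)), tolerance = 1e-9)
})

test_that("calibration models round-trip through JSON", {
  model <- fit_calibration(grid_pairs(T = diag(3) * 1.01, r0 = c(1, 0, -2),
                                      alpha = 0.005))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(model, path)
  m2 <- read_calibration(path)
  expect_equal(m2$T, model$T, tolerance = 1e-12)
  expect_equal(m2$r0, model$r0, tolerance = 1e-12)
  expect_equal(m2$alpha, model$alpha, tolerance = 1e-12)
})
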