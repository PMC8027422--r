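#' Fit the trap-space / imaging-space calibration transform
#'
#' The mapping between a position `r = (x, y, z)` measured in imaging space
#' and the trap coordinate `r'` that holds an object there is modelled as
#' `r' = T r + r0 + alpha z^2 zhat`: a 3x3 linear operator `T`, an offset
#' `r0` between the two origins, and an empirical quadratic axial correction
#' `alpha` absorbing spherical aberration. The model is linear in all 13
#' parameters, so the fit is ordinary least squares on the stacked
#' coordinates. The quadratic term uses the imaging-space z.
#'
#' @param pairs A tibble/data frame of matched positions with imaging-space
#'   columns `x`, `y`, `z` and trap-space columns `xp`, `yp`, `zp` (one row
#'   per grid point of the calibration scan). At least 13 pairs spanning all
#'   three axes and at least 3 distinct z values are required.
#'
#' @return A `calibration_model`: list with `T` (3x3), `r0`, `alpha`,
#'   `residual_rms` (per axis, um), `n` and `condition_number`.
#' @export
#' @examples
#' grid <- expand.grid(x = c(-10, 0, 10), y = c(-10, 0, 10), z = c(2, 6, 10))
#' pairs <- tibble::as_tibble(grid) |>
#'   dplyr::mutate(xp = 1.02 * x, yp = y, zp = z + 0.01 * z^2)
#' fit_calibration(pairs)
fit_calibration <- function(pairs) {
  need <- c("x", "y", "z", "xp", "yp", "zp")
  stopifnot(all(need %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 13) stop("need at least 13 calibration pairs (13 unknowns), got ",
                   n, call. = FALSE)
  r <- as.matrix(pairs[, c("x", "y", "z")])
  rp <- as.matrix(pairs[, c("xp", "yp", "zp")])
  spans <- apply(r, 2, function(v) diff(range(v)))
  if (any(spans <= 0)) {
    stop("calibration grid is degenerate along ",
         paste(c("x", "y", "z")[spans <= 0], collapse = ", "),
         "; scan must span all three axes", call. = FALSE)
  }
  if (length(unique(r[, 3])) < 3) {
    stop("need at least 3 distinct z values to separate alpha from T_zz",
         call. = FALSE)
  }

  # stacked design: unknowns (T11,T12,T13, T21..., T31..., r0 (3), alpha)
  zero <- matrix(0, n, 3)
  one <- rep(1, n)
  X <- rbind(
    cbind(r, zero, zero, one, 0 * one, 0 * one, 0 * one),
    cbind(zero, r, zero, 0 * one, one, 0 * one, 0 * one),
    cbind(zero, zero, r, 0 * one, 0 * one, one, r[, 3]^2)
  )
  yv <- c(rp[, 1], rp[, 2], rp[, 3])
  qrx <- qr(X)
  if (qrx$rank < 13) {
    stop("rank-deficient calibration design (rank ", qrx$rank,
         " of 13); enlarge the scan grid", call. = FALSE)
  }
  beta <- unname(qr.coef(qrx, yv))
  res <- matrix(yv - X %*% beta, ncol = 3)
  Tm <- matrix(beta[1:9], 3, byrow = TRUE)
  sv <- svd(Tm)$d
  cond <- sv[1] / sv[3]
  if (!is.finite(cond) || cond > 1e6) {
    stop("fitted transform T is numerically singular (condition number ",
         format(cond), ")", call. = FALSE)
  }

  # standard errors from the stacked OLS
  sigma2 <- sum(res^2) / max(1, 3 * n - 13)
  XtXinv <- chol2inv(qr.R(qrx))
  se <- sqrt(sigma2 * diag(XtXinv))

  structure(
    list(T = Tm, r0 = beta[10:12], alpha = beta[13],
         residual_rms = sqrt(colMeans(res^2)),
         se = list(T = matrix(se[1:9], 3, byrow = TRUE),
                   r0 = se[10:12], alpha = se[13]),
         n = n, condition_number = cond),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> r' = T r + r0 + alpha z^2 zhat\n")
  cat("T =\n"); print(signif(x$T, 6))
  cat("r0 =", signif(x$r0, 6), " alpha =", signif(x$alpha, 6), "um^-1\n")
  cat("residual RMS (x, y, z):", signif(x$residual_rms, 3), "um over",
      x$n, "pairs\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration model
#'
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @return `tidy()` gives one row per parameter with `estimate` and
#'   `std.error`; `glance()` gives a one-row model summary.
#' @method tidy calibration_model
#' @export
tidy.calibration_model <- function(x, ...) {
  terms <- c(outer(1:3, 1:3, function(i, j) sprintf("T[%d,%d]", i, j)),
             c("r0_x", "r0_y", "r0_z"), "alpha")
  est <- c(t(x$T), x$r0, x$alpha)
  se <- c(t(x$se$T), x$se$r0, x$se$alpha)
  tibble::tibble(term = terms, estimate = est, std.error = se)
}

#' @rdname tidy.calibration_model
#' @method glance calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    rms_x = x$residual_rms[1], rms_y = x$residual_rms[2],
    rms_z = x$residual_rms[3],
    alpha = x$alpha, condition_number = x$condition_number
  )
}

#' Apply or invert a calibration model
#'
#' `apply_calibration()` maps imaging-space points to trapping space,
#' `r' = T r + r0 + alpha z^2 zhat`, exactly. `invert_calibration()` maps
#' trap coordinates back to imaging space; since the model is nonlinear only
#' through the scalar `alpha z^2` term, the inverse solves one scalar
#' equation in z by Newton iteration and back-substitutes.
#'
#' @param model A `calibration_model`.
#' @param points Tibble/data frame with columns `x`, `y`, `z`.
#' @param tol Newton convergence tolerance on z, um.
#' @return A tibble with transformed `x`, `y`, `z`.
#' @export
apply_calibration <- function(model, points) {
  r <- as.matrix(points[, c("x", "y", "z")])
  rp <- r %*% t(model$T) +
    matrix(model$r0, nrow(r), 3, byrow = TRUE)
  rp[, 3] <- rp[, 3] + model$alpha * r[, 3]^2
  tibble::tibble(x = rp[, 1], y = rp[, 2], z = rp[, 3])
}

#' @rdname apply_calibration
#' @export
invert_calibration <- function(model, points, tol = 1e-9) {
  rp <- as.matrix(points[, c("x", "y", "z")])
  Tinv <- solve(model$T)
  u <- sweep(rp, 2, model$r0) %*% t(Tinv)   # = r + alpha z^2 Tinv zhat
  wz <- Tinv[, 3]
  out <- matrix(NA_real_, nrow(rp), 3)
  for (i in seq_len(nrow(rp))) {
    zeta <- u[i, 3]
    for (it in 1:50) {
      f <- zeta + model$alpha * zeta^2 * wz[3] - u[i, 3]
      fp <- 1 + 2 * model$alpha * zeta * wz[3]
      step <- f / fp
      zeta <- zeta - step
      if (abs(step) < tol) break
    }
    out[i, ] <- u[i, ] - model$alpha * zeta^2 * wz
  }
  tibble::tibble(x = out[, 1], y = out[, 2], z = out[, 3])
}

#' Save / load a calibration model as JSON
#'
#' @param model A `calibration_model`.
#' @param path File path.
#' @return `read_calibration()` returns a `calibration_model`.
#' @export
write_calibration <- function(model, path) {
  jsonlite::write_json(
    list(T = as.vector(t(model$T)), r0 = model$r0, alpha = model$alpha,
         residual_rms = model$residual_rms, n = model$n,
         condition_number = model$condition_number),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::fromJSON(path)
  structure(
    list(T = matrix(j$T, 3, byrow = TRUE), r0 = j$r0, alpha = j$alpha,
         residual_rms = j$residual_rms, se = NULL, n = j$n,
         condition_number = j$condition_number),
    class = "calibration_model"
  )
}
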