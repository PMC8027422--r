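#' Sample environment
#'
#' Physical environment of the simulated sample chamber: absolute
#' temperature, dynamic viscosity, fluid density, gravitational acceleration
#' and a reflective wall (the coverslip) at z = 0. Internally forces are in
#' pN, lengths in um and times in s, so the viscosity converts as
#' 1 Pa s = 1 pN s / um^2.
#'
#' @param temperature Kelvin.
#' @param viscosity Pa s (water at room temperature by default).
#' @param fluid_density g/cm^3.
#' @param gravity m/s^2.
#' @return A list of class `sample_environment`.
#' @export
sample_environment <- function(temperature = 295, viscosity = 8.9e-4,
                               fluid_density = 1.00, gravity = 9.81) {
  stopifnot(temperature >= 0, viscosity > 0, fluid_density > 0)
  structure(list(temperature = temperature, viscosity = viscosity,
                 fluid_density = fluid_density, gravity = gravity),
            class = "sample_environment")
}

# Boltzmann constant: 1.380649e-23 J/K = 1.380649e-5 pN um / K
.kB <- 1.380649e-5

# Stokes drag gamma = 6 pi eta a in pN s / um; spherocylinders use the
# equivalent-volume sphere radius.
stokes_drag <- function(objects, env) {
  a <- ifelse(objects$kind == "sphere", objects$radius,
              equivalent_radius(objects$radius, objects$length))
  6 * pi * env$viscosity * a
}

equivalent_radius <- function(radius, length) {
  cyl <- pmax(length - 2 * radius, 0)
  vol <- pi * radius^2 * cyl + 4 / 3 * pi * radius^3
  (3 * vol / (4 * pi))^(1 / 3)
}

# gravity + buoyancy force along -z in pN; density contrast in g/cm^3
gravity_force <- function(objects, env) {
  a <- objects$radius
  cyl <- pmax(objects$length - 2 * a, 0)
  vol <- ifelse(objects$kind == "sphere", 4 / 3 * pi * a^3,
                pi * a^2 * cyl + 4 / 3 * pi * a^3)   # um^3
  drho <- objects$density - env$fluid_density        # g/cm^3 = 1e3 kg/m^3
  # F [N] = vol[1e-18 m^3] * drho[1e3 kg/m^3] * g  ->  pN = 1e12 N
  -vol * drho * env$gravity * 1e-3                   # pN, along -z
}

#' Optical trap field acting on the sample
#'
#' Harmonic traps: an object within `capture_radius` of a trap feels the
#' restoring force `-kappa (r - r_trap)`; outside it feels nothing.
#'
#' @param traps A [trap_configuration()] tibble (imaging-space coordinates),
#'   or `NULL` for no traps.
#' @param stiffness Trap stiffness kappa, pN/um.
#' @param capture_radius Capture range, um.
#' @return A list of class `trap_field`.
#' @export
trap_field <- function(traps = NULL, stiffness = 5, capture_radius = 1.5) {
  stopifnot(stiffness > 0, capture_radius > 0)
  structure(list(traps = traps, stiffness = stiffness,
                 capture_radius = capture_radius),
            class = "trap_field")
}

#' Advance the scene by one overdamped Langevin step
#'
#' Euler--Maruyama update of every object: drift `(F_trap + F_gravity)/gamma`
#' with Stokes drag `gamma = 6 pi eta a`, plus a Gaussian displacement of
#' variance `2 D dt` per axis with `D = kB T / gamma`. Smooth swimmers
#' additionally advance at their constant speed along their orientation;
#' below 2 um from the wall the orientation rotates about z at `omega`
#' (wall-induced circular swimming), and rotational diffusion adds angular
#' noise. The wall at z = 0 is reflective: objects cannot penetrate below
#' `z = radius`.
#'
#' @param scene A scene tibble ([scene_object()]).
#' @param traps A [trap_field()] or `NULL`.
#' @param dt Time step, s (<= 1e-3 for stability at default stiffness).
#' @param env A [sample_environment()].
#' @param omega Wall-circling angular speed of swimmers, rad/s.
#' @param rot_diffusion Swimmer rotational diffusivity, rad^2/s.
#' @param wall_circle_height Height below which swimmers circle, um.
#' @param volume Addressable volume bounds; objects leaving it are removed
#'   with a message.
#'
#' @return The advanced scene tibble (attribute `time` incremented by `dt`).
#' @export
step_scene <- function(scene, traps = NULL, dt = 1e-3,
                       env = sample_environment(),
                       omega = 1, rot_diffusion = 0.1,
                       wall_circle_height = 2,
                       volume = default_volume()) {
  stopifnot(dt > 0, dt <= 1e-3 + 1e-12)
  if (nrow(scene) == 0) return(scene)
  gam <- stokes_drag(scene, env)
  D <- .kB * env$temperature / gam

  force <- cbind(0, 0, gravity_force(scene, env))
  if (!is.null(traps) && inherits(traps, "trap_field") &&
      !is.null(traps$traps) && nrow(traps$traps) > 0) {
    tp <- as.matrix(traps$traps[, c("x", "y", "z")])
    pos <- as.matrix(scene[, c("x", "y", "z")])
    for (i in seq_len(nrow(scene))) {
      dvec <- sweep(tp, 2, pos[i, ])
      dd <- sqrt(rowSums(dvec^2))
      jmin <- which.min(dd)
      if (dd[jmin] <= traps$capture_radius) {
        force[i, ] <- force[i, ] + traps$stiffness * dvec[jmin, ]
      }
    }
  }

  drift <- force / gam * dt                      # um
  noise <- matrix(stats::rnorm(3 * nrow(scene)), ncol = 3) *
    sqrt(2 * D * dt)

  swim <- scene$behavior == "smooth_swimmer" & scene$speed > 0
  swim_step <- matrix(0, nrow(scene), 3)
  if (any(swim)) {
    e <- as.matrix(scene[, c("ex", "ey", "ez")])
    swim_step[swim, ] <- e[swim, ] * scene$speed[swim] * dt
    # wall-induced circling + rotational diffusion
    for (i in which(swim)) {
      ei <- e[i, ]
      if (scene$z[i] < wall_circle_height) {
        th <- omega * dt
        ei <- c(ei[1] * cos(th) - ei[2] * sin(th),
                ei[1] * sin(th) + ei[2] * cos(th), ei[3])
      }
      if (rot_diffusion > 0) {
        dth <- stats::rnorm(2, 0, sqrt(2 * rot_diffusion * dt))
        # rotate about two axes orthogonal to e
        b1 <- normalize_ortho(ei)
        b2 <- cross3(ei, b1)
        ei <- ei + dth[1] * b1 + dth[2] * b2
        ei <- ei / sqrt(sum(ei^2))
      }
      scene$ex[i] <- ei[1]; scene$ey[i] <- ei[2]; scene$ez[i] <- ei[3]
    }
  }

  scene$x <- scene$x + drift[, 1] + noise[, 1] + swim_step[, 1]
  scene$y <- scene$y + drift[, 2] + noise[, 2] + swim_step[, 2]
  scene$z <- scene$z + drift[, 3] + noise[, 3] + swim_step[, 3]

  # reflective wall at the coverslip
  below <- scene$z < scene$radius
  scene$z[below] <- 2 * scene$radius[below] - scene$z[below]

  # objects drifting out of the lateral volume are removed
  gone <- scene$x < volume$xmin | scene$x > volume$xmax |
    scene$y < volume$ymin | scene$y > volume$ymax | scene$z > volume$zmax
  if (any(gone)) {
    message("removed ", sum(gone), " object(s) leaving the volume")
    scene <- scene[!gone, ]
  }
  attr(scene, "time") <- (attr(scene, "time") %||% 0) + dt
  scene
}

normalize_ortho <- function(e) {
  ref <- if (abs(e[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- cross3(e, ref)
  v / sqrt(sum(v^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Run several dynamics sub-steps
#'
#' Convenience wrapper advancing the scene by `n` steps of `dt` (the imaging
#' cadence of 40 fps with the default `dt = 1` ms corresponds to `n = 25`
#' sub-steps per frame).
#'
#' @inheritParams step_scene
#' @param n Number of sub-steps.
#' @param ... Passed to [step_scene()].
#' @return The advanced scene tibble.
#' @export
advance_scene <- function(scene, n, traps = NULL, dt = 1e-3, ...) {
  for (i in seq_len(n)) scene <- step_scene(scene, traps = traps, dt = dt, ...)
  scene
}

#' Pick the scene object hit by a virtual pointer ray
#'
#' Returns the feature whose surface is first intersected by the ray
#' (objects modelled as spheres or spherocylinders of their fitted
#' dimensions), or zero rows if the ray misses everything.
#'
#' @param origin Length-3 ray origin, um (imaging space).
#' @param direction Length-3 direction (normalized internally).
#' @param features A features tibble with `x`, `y`, `z`, `l`, `b` columns
#'   (and orientation `ex`, `ey`, `ez` for elongated objects) or a scene
#'   tibble with `radius`/`length`.
#' @return One row of `features` with a `hit_distance` column, or the empty
#'   tibble if nothing is hit.
#' @export
pointer_pick <- function(origin, direction, features) {
  stopifnot(length(origin) == 3, length(direction) == 3)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be non-zero", call. = FALSE)
  dirn <- direction / nrm
  if (nrow(features) == 0) return(dplyr::mutate(features, hit_distance = numeric()))

  radius <- if ("b" %in% names(features)) features$b / 2 else features$radius
  len <- if ("l" %in% names(features)) features$l else features$length

  hit <- rep(Inf, nrow(features))
  for (i in seq_len(nrow(features))) {
    ctr <- c(features$x[i], features$y[i], features$z[i])
    half <- max(len[i] / 2 - radius[i], 0)
    e <- if (all(c("ex", "ey", "ez") %in% names(features))) {
      c(features$ex[i], features$ey[i], features$ez[i])
    } else c(0, 0, 1)
    if (half < 1e-9) {
      hit[i] <- ray_sphere(origin, dirn, ctr, radius[i])
    } else {
      hit[i] <- ray_capsule(origin, dirn, ctr, e, half, radius[i])
    }
  }
  ok <- is.finite(hit)
  if (!any(ok)) return(dplyr::mutate(features[0, ], hit_distance = numeric()))
  sel <- which.min(hit)
  dplyr::mutate(features[sel, ], hit_distance = hit[sel])
}

# smallest positive ray parameter hitting a sphere, Inf if none
ray_sphere <- function(o, d, c0, r) {
  oc <- o - c0
  b <- sum(oc * d)
  disc <- b^2 - (sum(oc^2) - r^2)
  if (disc < 0) return(Inf)
  t1 <- -b - sqrt(disc)
  t2 <- -b + sqrt(disc)
  if (t1 > 0) t1 else if (t2 > 0) t2 else Inf
}

# capsule intersection by minimizing distance from ray to the axis segment
ray_capsule <- function(o, d, c0, e, half, r) {
  # distance from ray point o + t d to segment c0 +/- half e, minimized over t
  dist_t <- function(t) {
    p <- o + t * d
    s <- sum((p - c0) * e)
    s <- min(max(s, -half), half)
    q <- c0 + s * e
    sqrt(sum((p - q)^2))
  }
  # bracket the closest approach of ray to the capsule centre
  t0 <- sum((c0 - o) * d)
  lo <- max(0, t0 - half - 4 * r)
  hi <- t0 + half + 4 * r
  if (hi <= 0) return(Inf)
  opt <- stats::optimize(dist_t, c(lo, hi))
  if (opt$objective > r) return(Inf)
  # walk back to the entry point where distance == r
  f <- function(t) dist_t(t) - r
  if (f(lo) <= 0) return(if (lo > 0) lo else Inf)
  stats::uniroot(f, c(lo, opt$minimum), tol = 1e-9)$root
}
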