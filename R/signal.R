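#' Signal field parameters
#'
#' The regeneration-inducing signal is a continuous density field
#' discretized by a cloud of equal-mass particles (a smoothed-particle,
#' diffusion-velocity scheme). At the posterior front a Dirichlet source
#' holds the density at `rho0` inside a strip one cell diameter deep; the
#' fixed anterior wall absorbs the signal (density zero).
#'
#' Configuration accepts the units the biology is quoted in — `D` in
#' um^2/s and `k` in 1/day — and converts to the internal hours/um system.
#'
#' @param D Diffusion coefficient (um^2 per second).
#' @param k Degradation rate (per day); the signal half-life is `ln 2 / k`.
#' @param rho0 Dirichlet source density at the front (signal units/um^2).
#' @param rhos_min Recruitment threshold density (same units as `rho0`).
#' @param particle_mass Mass of one signalling particle (signal units); the
#'   number of source particles is `NS = round(2 R W rho0 / particle_mass)`,
#'   which reduces to the unit-mass source count `2 R W rho0` at mass 1.
#' @param h Kernel support radius (um); defaults to four cell radii.
#' @param rho_star Regularization density preventing a singular velocity at
#'   vanishing density; defaults to `rho0 / 100`.
#' @param R Cell radius (um), setting the source strip depth `2R` and the
#'   per-step displacement bound.
#' @param cfl Constant `C <= 1/2` in the diffusive step-size bound.
#' @param degrade_in_source If `FALSE` (default) particles inside the
#'   source strip are exempt from degradation (they are re-imposed by the
#'   Dirichlet refill anyway).
#' @return An object of class `signal_params` with internal-unit fields
#'   `D_h` (um^2/h) and `k_h` (1/h).
#' @export
signal_params <- function(D = 1, k = 1, rho0 = 40, rhos_min = 3,
                          particle_mass = 400, R = 7, h = 4 * R,
                          rho_star = rho0 / 100, cfl = 0.5,
                          degrade_in_source = FALSE) {
  stopifnot(D >= 0, k >= 0, rho0 > 0, rhos_min > 0, particle_mass > 0,
            h > 0, rho_star > 0, cfl > 0, cfl <= 0.5)
  structure(list(D = D, k = k, D_h = D * 3600, k_h = k / 24,
                 rho0 = rho0, rhos_min = rhos_min,
                 particle_mass = particle_mass, h = h,
                 rho_star = rho_star, R = R, cfl = cfl,
                 degrade_in_source = degrade_in_source),
            class = "signal_params")
}

#' Poly6 smoothing kernel and its gradient
#'
#' Two-dimensional Poly6 kernel
#' \eqn{W(q,h) = \frac{4}{\pi h^8}(h^2-\|q\|^2)^3} on \eqn{\|q\| \le h}
#' (zero outside), with gradient
#' \eqn{\nabla W = -\frac{24}{\pi h^8}(h^2-\|q\|^2)^2 q}. The kernel
#' integrates to one over the plane.
#'
#' @param q Displacement vectors: a two-column matrix or length-2 vector.
#' @param h Support radius (um).
#' @return `poly6()`: numeric weights; `poly6_grad()`: a two-column matrix.
#' @export
poly6 <- function(q, h) {
  q <- matrix(as.numeric(q), ncol = 2)
  r2 <- rowSums(q^2)
  ifelse(r2 <= h^2, 4 / (pi * h^8) * (h^2 - r2)^3, 0)
}

#' @rdname poly6
#' @export
poly6_grad <- function(q, h) {
  q <- matrix(as.numeric(q), ncol = 2)
  r2 <- rowSums(q^2)
  fac <- ifelse(r2 <= h^2, -24 / (pi * h^8) * (h^2 - r2)^2, 0)
  q * fac
}

#' SPH density, gradient and neighbour count at query points
#'
#' Kernel-summation estimate \eqn{\rho(p) = \sum_i m W(p - Z_i, h)} over
#' the signalling particles, with y-displacements taken by minimal image on
#' the periodic strip; the gradient uses \eqn{\nabla W} analogously. The
#' neighbour count is the number of particles strictly within distance `h`.
#'
#' @param points Tibble or matrix of query positions with columns/cols
#'   `x`, `y` (um).
#' @param particles Tibble with columns `x`, `y`: the signalling particles.
#' @param sp A [signal_params()].
#' @param geom A [domain_geometry()].
#' @return A tibble with columns `rho`, `grad_x`, `grad_y`, `n_neighbours`.
#' @export
sph_density <- function(points, particles, sp, geom) {
  pts <- as.data.frame(points)
  res <- sph_eval_cpp(particles$x, particles$y, pts$x, pts$y,
                      sp$particle_mass, sp$h, geom$ymin, geom$width)
  tibble::tibble(rho = res$rho, grad_x = res$gx, grad_y = res$gy,
                 n_neighbours = res$count)
}

#' Diffusion step: move particles along the diffusion velocity
#'
#' Every particle moves by
#' \eqn{-\Delta t\, D\, \nabla\rho_j / (\rho_j + \rho^*)}; the particle
#' count is conserved, y is re-wrapped, and each displacement is asserted
#' to stay within the bound of one cell diameter implied by the step-size
#' rule.
#'
#' @param particles Particle tibble (`x`, `y`).
#' @param dt Time step (hours), satisfying [choose_timestep()].
#' @param sp A [signal_params()].
#' @param geom A [domain_geometry()].
#' @return Updated particle tibble.
#' @export
diffusion_step <- function(particles, dt, sp, geom) {
  if (nrow(particles) == 0) return(particles)
  out <- diffuse_xy(particles$x, particles$y, dt, sp, geom)
  particles$x <- out$x
  particles$y <- out$y
  particles
}

# vector core of the diffusion-velocity update (shared with the engine)
diffuse_xy <- function(px, py, dt, sp, geom) {
  est <- sph_eval_cpp(px, py, px, py, sp$particle_mass, sp$h,
                      geom$ymin, geom$width)
  vx <- -sp$D_h * est$gx / (est$rho + sp$rho_star)
  vy <- -sp$D_h * est$gy / (est$rho + sp$rho_star)
  disp2 <- (dt * dt) * (vx * vx + vy * vy)
  # the step-size rule bounds typical displacements by 2R; strongly
  # anisotropic particle clusters can exceed it by a modest factor, so the
  # hard failure triggers at 1.5 x the nominal bound
  if (any(disp2 > (1.5 * 2 * sp$R)^2)) {
    stop(sprintf(
      "particle displacement %.3g um far exceeds the bound 2R = %g um; the time step is misconfigured",
      sqrt(max(disp2)), 2 * sp$R))
  }
  list(x = px + dt * vx, y = wrap_y(py + dt * vy, geom))
}

#' Degradation step: Poisson removal of particles
#'
#' Each particle is removed independently with probability
#' `1 - exp(-k dt)`. Optionally (default) particles inside the source strip
#' `[L - 2R, L]` are exempt, since the Dirichlet refill re-imposes the
#' source density there.
#'
#' @inheritParams diffusion_step
#' @param L Current tissue length (um), needed to locate the source strip
#'   when source-strip degradation is disabled; pass `NULL` to degrade
#'   everywhere.
#' @return Updated particle tibble.
#' @export
degradation_step <- function(particles, dt, sp, L = NULL) {
  if (nrow(particles) == 0) return(particles)
  keep <- degrade_keep(particles$x, dt, sp, L)
  particles[keep, , drop = FALSE]
}

# vector core of Poisson removal: survival mask (shared with the engine)
degrade_keep <- function(px, dt, sp, L = NULL) {
  stopifnot(sp$k_h * dt <= 0.1 + 1e-12)
  p <- -expm1(-sp$k_h * dt)
  doomed <- runif(length(px)) < p
  if (!sp$degrade_in_source && !is.null(L)) {
    doomed <- doomed & px < L - 2 * sp$R
  }
  !doomed
}

#' Enforce domain boundaries on the signal field
#'
#' Implements the two Dirichlet conditions of the signal equation on the
#' moving domain: particles absorbed at the fixed anterior wall (`x < 0`)
#' or beyond the front (`x > L`) are deleted, and the source strip
#' `[L - 2R, L]` across the full circumference is re-populated so that it
#' holds exactly `NS = round(2 R W rho0 / m)` particles, adding or removing
#' particles uniformly at random within the strip.
#'
#' @inheritParams diffusion_step
#' @param L Current tissue length (um); must exceed the strip depth `2R`.
#' @return Updated particle tibble.
#' @export
apply_boundaries <- function(particles, L, sp, geom) {
  out <- boundaries_xy(particles$x, particles$y, L, sp, geom)
  tibble::as_tibble(out)[, c("x", "y")]
}

# vector core of the Dirichlet boundary enforcement (shared with the engine)
boundaries_xy <- function(px, py, L, sp, geom) {
  if (L < 2 * sp$R) stop("tissue length is shorter than the source strip depth 2R")
  ns <- source_particle_count(sp, geom)
  keep <- px >= 0 & px <= L
  px <- px[keep]
  py <- py[keep]
  in_strip <- which(px >= L - 2 * sp$R)
  excess <- length(in_strip) - ns
  if (excess > 0) {
    drop <- sample(in_strip, excess)
    px <- px[-drop]
    py <- py[-drop]
  } else if (excess < 0) {
    px <- c(px, runif(-excess, L - 2 * sp$R, L))
    py <- c(py, runif(-excess, geom$ymin, geom$ymax))
  }
  list(x = px, y = py)
}

#' Number of source particles implied by the Dirichlet density
#'
#' @inheritParams apply_boundaries
#' @return Integer particle count `round(2 R W rho0 / m)`.
#' @export
source_particle_count <- function(sp, geom) {
  max(1L, as.integer(round(2 * sp$R * geom$width * sp$rho0 / sp$particle_mass)))
}

#' Time step for the signal scheme
#'
#' `dt = min(C (2R)^2 / D, 1/k)`, further capped so that `k dt <= 0.1`
#' (good Poisson-removal accuracy) and by an absolute cap (default 0.5 h)
#' so division events stay resolved when diffusion is very slow.
#'
#' @param sp A [signal_params()].
#' @param dt_max Absolute cap on the step (hours).
#' @return Time step in hours.
#' @export
choose_timestep <- function(sp, dt_max = 0.5) {
  if (sp$D_h <= 0 && sp$k_h <= 0) {
    stop("cannot choose a time step: both D and k are zero")
  }
  dt <- dt_max
  if (sp$D_h > 0) {
    dt <- min(dt, sp$cfl * (2 * sp$R)^2 / sp$D_h)
    # kernel-aware displacement cap: the drift speed of the scheme is
    # bounded by ~3.4 D/h (anisotropic neighbourhood worst case); the
    # factor 5 leaves headroom so every displacement stays below 2R.
    dt <- min(dt, 2 * sp$R * sp$h / (5 * sp$D_h))
  }
  if (sp$k_h > 0) dt <- min(dt, 1 / sp$k_h, 0.1 / sp$k_h)
  dt
}

#' Signal exposure of cells
#'
#' A cell is exposed to the signal only if at least two signalling
#' particles lie within the kernel radius of its centre; it is eligible for
#' recruitment if, in addition, the local SPH density exceeds the threshold
#' `rhos_min`.
#'
#' @param points Cell centres (tibble/data frame with `x`, `y`).
#' @inheritParams sph_density
#' @return A tibble with columns `rho`, `n_neighbours`, `exposed`,
#'   `eligible`.
#' @export
exposure <- function(points, particles, sp, geom) {
  d <- sph_density(points, particles, sp, geom)
  d$exposed <- d$n_neighbours >= 2
  d$eligible <- d$exposed & d$rho > sp$rhos_min
  d[, c("rho", "n_neighbours", "exposed", "eligible")]
}
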