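test_that("Poly6 kernel: value at origin, unit mass, compact support", {
  h <- 28
  expect_equal(poly6(c(0, 0), h), 4 / (pi * h^2))
  # radial quadrature of the kernel over the plane is 1
  integrand <- function(r) poly6(cbind(r, 0), h) * 2 * pi * r
  expect_equal(integrate(integrand, 0, h)$value, 1, tolerance = 1e-8)
  # support boundary: weight and gradient vanish
  expect_equal(poly6(c(h, 0), h), 0)
  expect_equal(as.numeric(poly6_grad(c(0, h), h)), c(0, 0))
  expect_equal(as.numeric(poly6_grad(c(0, 0), h)), c(0, 0))
  # gradient points down the displacement
  g <- poly6_grad(c(10, 0), h)
  expect_lt(g[1], 0)
  expect_equal(g[2], 0)
})

test_that("SPH density matches the quadratic brute-force oracle", {
  set.seed(201)
  geom <- domain_geometry(L0 = 150, ymin = 0, ymax = 50)
  sp <- signal_params(D = 1, k = 1, rho0 = 40, particle_mass = 3, R = 7)
  n <- 200
  particles <- tibble::tibble(x = runif(n, 0, 150), y = runif(n, 0, 50))
  pts <- tibble::tibble(x = runif(40, 0, 150), y = runif(40, 0, 50))
  est <- sph_density(pts, particles, sp, geom)
  h <- sp$h
  for (i in seq_len(nrow(pts))) {
    dx <- pts$x[i] - particles$x
    dy <- pts$y[i] - particles$y
    dy <- dy - 50 * round(dy / 50)
    r2 <- dx^2 + dy^2
    inh <- r2 < h^2
    expect_equal(est$rho[i],
                 3 * sum(4 / (pi * h^8) * (h^2 - r2[inh])^3), tolerance = 1e-12)
    expect_equal(est$grad_x[i],
                 3 * sum(-24 / (pi * h^8) * (h^2 - r2[inh])^2 * dx[inh]),
                 tolerance = 1e-12)
    expect_equal(est$n_neighbours[i], sum(inh))
  }
  # single particle evaluated at its own position
  one <- tibble::tibble(x = 75, y = 25)
  self <- sph_density(one, one, sp, geom)
  expect_equal(self$rho, 3 * 4 / (pi * h^2))
  # far from every particle the density vanishes
  far <- sph_density(tibble::tibble(x = 0, y = 0),
                     tibble::tibble(x = 150, y = 25), sp, geom)
  expect_equal(far$rho, 0)
  expect_true(all(est$rho >= 0))
})

test_that("diffusion: flat periodic lattice is stationary and particles are conserved", {
  geom <- domain_geometry(L0 = 140, ymin = 0, ymax = 70)
  sp <- signal_params(D = 1, k = 1, rho0 = 40, particle_mass = 10, R = 7)
  # uniform lattice filling the strip: interior rows feel zero net gradient
  gx <- seq(3.5, 136.5, by = 7)
  gy <- seq(3.5, 66.5, by = 7)
  lat <- tidyr::expand_grid(x = gx, y = gy)
  dt <- choose_timestep(sp)
  out <- diffusion_step(lat, dt, sp, geom)
  interior <- lat$x > 28 & lat$x < 112
  expect_equal(out$x[interior], lat$x[interior], tolerance = 1e-9)
  expect_equal(out$y[interior], lat$y[interior], tolerance = 1e-9)
  expect_equal(nrow(out), nrow(lat))
  # repeated stepping never changes the particle count
  p <- lat
  for (i in 1:50) p <- diffusion_step(p, dt, sp, geom)
  expect_equal(nrow(p), nrow(lat))
})

test_that("diffusion spreads a blob at a rate consistent with 2D", {
  set.seed(202)
  geom <- domain_geometry(L0 = 1500, ymin = -600, ymax = 600)
  # regularization density well below the blob density so it does not
  # throttle the flux; wide kernel keeps the ratio-estimator bias small
  sp <- signal_params(D = 0.5, k = 1, rho0 = 40, particle_mass = 1, R = 7,
                      h = 56, rho_star = 1e-4)
  n <- 3000
  p <- tibble::tibble(x = rnorm(n, 750, 80), y = rnorm(n, 0, 80))
  dt <- choose_timestep(sp)
  v0 <- var(p$x)
  nst <- 60
  for (i in seq_len(nst)) p <- diffusion_step(p, dt, sp, geom)
  slope <- (var(p$x) - v0) / (nst * dt)
  # empirical spreading rate within the regularization/sampling bias band
  expect_gt(slope, 0.55 * 2 * sp$D_h)
  expect_lt(slope, 1.25 * 2 * sp$D_h)
})

test_that("degradation is a per-particle Poisson process", {
  set.seed(203)
  sp <- signal_params(D = 1, k = 2.4, rho0 = 40, particle_mass = 1, R = 7)
  # k = 0: nothing is ever removed
  sp0 <- signal_params(D = 1, k = 0, rho0 = 40, particle_mass = 1, R = 7)
  p <- tibble::tibble(x = runif(1000, 0, 100), y = runif(1000, 0, 50))
  expect_equal(nrow(degradation_step(p, 0.5, sp0)), 1000)

  # one step: removed fraction within 3 binomial sd of 1 - e^(-k dt)
  n <- 1e5
  big <- tibble::tibble(x = runif(n, 0, 1000), y = runif(n, 0, 50))
  dt <- 0.5
  pexp <- 1 - exp(-sp$k_h * dt)
  kept <- nrow(degradation_step(big, dt, sp))
  expect_lt(abs((n - kept) / n - pexp), 3 * sqrt(pexp * (1 - pexp) / n))

  # survival over time follows e^(-kt): fitted half-life within 5%
  surv <- big
  times <- seq(dt, 20, by = dt)
  counts <- vapply(times, function(t) {
    surv <<- degradation_step(surv, dt, sp)
    nrow(surv)
  }, numeric(1))
  fit <- coef(lm(log(counts) ~ times))
  half_life <- -log(2) / fit[2]
  expect_lt(abs(half_life - log(2) / sp$k_h) / (log(2) / sp$k_h), 0.05)
})

test_that("boundaries impose absorption anteriorly and the source strip at the front", {
  set.seed(204)
  geom <- domain_geometry(L0 = 300, ymin = 0, ymax = 60)
  sp <- signal_params(D = 1, k = 1, rho0 = 40, particle_mass = 400, R = 7)
  ns <- source_particle_count(sp, geom)
  expect_equal(ns, round(2 * 7 * 60 * 40 / 400))

  # empty field: exactly NS particles created, all inside the strip
  empty <- tibble::tibble(x = numeric(), y = numeric())
  out <- apply_boundaries(empty, 300, sp, geom)
  expect_equal(nrow(out), ns)
  expect_true(all(out$x >= 300 - 14 & out$x <= 300))

  # a full strip with no strays is left unchanged
  out2 <- apply_boundaries(out, 300, sp, geom)
  expect_equal(out2, out)

  # strays: anterior particles absorbed, beyond-front particles deleted
  strays <- dplyr::bind_rows(out, tibble::tibble(x = c(-3, -0.1, 310),
                                                 y = c(5, 10, 20)))
  out3 <- apply_boundaries(strays, 300, sp, geom)
  expect_equal(nrow(out3), ns)
  expect_true(all(out3$x >= 0 & out3$x <= 300))

  # surplus in the strip is thinned back to NS
  crowded <- dplyr::bind_rows(out, tibble::tibble(x = runif(50, 287, 300),
                                                  y = runif(50, 0, 60)))
  out4 <- apply_boundaries(crowded, 300, sp, geom)
  expect_equal(sum(out4$x >= 286), ns)

  # the refilled strip carries the Dirichlet number density rho0
  expect_equal(nrow(out) * sp$particle_mass / (14 * 60), 40, tolerance = 0.05)

  expect_error(apply_boundaries(out, 10, sp, geom), "strip")
})

test_that("SPH density over a uniformly filled region reports the fill density", {
  # surround the probe region with the same density so the kernel support
  # is fully covered: the estimate must match within kernel edge effects
  set.seed(205)
  geom <- domain_geometry(L0 = 400, ymin = 0, ymax = 120)
  sp <- signal_params(D = 1, k = 1, rho0 = 40, particle_mass = 40, R = 7)
  n_dens <- 1 # particles per um^2
  n <- round(400 * 120 * n_dens)
  p <- tibble::tibble(x = runif(n, 0, 400), y = runif(n, 0, 120))
  probes <- tibble::tibble(x = runif(200, 100, 300), y = runif(200, 30, 90))
  est <- sph_density(probes, p, sp, geom)
  expect_equal(mean(est$rho), 40 * n_dens, tolerance = 0.02)
})

test_that("time step rule takes the binding branch and respects all caps", {
  # huge D: the diffusive displacement bounds bind; at the default h = 4R
  # the kernel-aware cap sits just below the CFL bound
  spD <- signal_params(D = 10, k = 0.001, rho0 = 40, particle_mass = 1, R = 7)
  expect_equal(choose_timestep(spD), 2 * 7 * spD$h / (5 * spD$D_h))
  expect_lte(choose_timestep(spD), 0.5 * 14^2 / spD$D_h)
  # with a wide kernel the classical CFL bound is the binding one
  spW <- signal_params(D = 10, k = 0.001, rho0 = 40, particle_mass = 1,
                       R = 7, h = 6 * 7)
  expect_equal(choose_timestep(spW), 0.5 * 14^2 / spW$D_h)
  # huge k: the degradation accuracy cap 0.1/k binds
  spk <- signal_params(D = 1e-6, k = 240, rho0 = 40, particle_mass = 1, R = 7)
  expect_equal(choose_timestep(spk), 0.1 / spk$k_h)
  # quoted example: D = 0.08 um^2/s (288 um^2/h), R = 7, C = 0.5
  sp <- signal_params(D = 0.08, k = 0.1, rho0 = 40, particle_mass = 1, R = 7)
  expect_equal(0.5 * (2 * 7)^2 / sp$D_h, 0.3402, tolerance = 1e-3)
  # absolute cap for very slow signals
  spslow <- signal_params(D = 1e-5, k = 0.01, rho0 = 40, particle_mass = 1,
                          R = 7)
  expect_equal(choose_timestep(spslow), 0.5)
  expect_error(choose_timestep(signal_params(D = 0, k = 0, rho0 = 1,
                                             particle_mass = 1, R = 7)))
})

test_that("exposure needs two particles in range and supra-threshold density", {
  geom <- domain_geometry(L0 = 200, ymin = 0, ymax = 100)
  sp <- signal_params(D = 1, k = 1, rho0 = 40, rhos_min = 3,
                      particle_mass = 40, R = 7)
  centre <- tibble::tibble(x = 100, y = 50)

  # no particles at all: not exposed
  none <- exposure(centre, tibble::tibble(x = numeric(), y = numeric()),
                   sp, geom)
  expect_false(none$exposed)
  expect_false(none$eligible)

  # a single particle exactly at the centre: high density but count 1
  one <- exposure(centre, centre, sp, geom)
  expect_equal(one$n_neighbours, 1L)
  expect_false(one$exposed)
  expect_false(one$eligible)

  # dense lattice above the threshold is eligible; diluted is not
  lat <- tidyr::expand_grid(x = seq(70, 130, by = 3), y = seq(20, 80, by = 3))
  dense <- exposure(centre, lat, sp, geom) # 40/9 = 4.4 signal units/um^2
  expect_true(dense$eligible)
  sparse <- lat[seq(1, nrow(lat), by = 24), ]
  thin <- exposure(centre, sparse, sp, geom)
  expect_true(thin$rho < sp$rhos_min || !thin$exposed)
  expect_false(thin$eligible)
})

test_that("the signal pipeline commutes with y-translation", {
  set.seed(206)
  geom <- domain_geometry(L0 = 200, ymin = 0, ymax = 60)
  sp <- signal_params(D = 0.5, k = 2, rho0 = 40, particle_mass = 100, R = 7)
  p <- tibble::tibble(x = runif(300, 0, 200), y = runif(300, 0, 60))
  dt <- choose_timestep(sp)
  shift <- 17.3
  a <- diffusion_step(p, dt, sp, geom)
  b <- diffusion_step(dplyr::mutate(p, y = wrap_y(y + shift, geom)),
                      dt, sp, geom)
  expect_equal(b$x, a$x, tolerance = 1e-9)
  expect_equal(b$y, wrap_y(a$y + shift, geom), tolerance = 1e-9)
})
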