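test_that("cycle lengths reproduce the configured moments", {
  set.seed(101)
  params <- cycle_params()
  slow <- sample_cycle_length(1e6, "slow", params)
  expect_true(all(slow > 0))
  expect_lt(abs(mean(slow) - 340), 0.5)
  expect_lt(abs(sd(slow) - 32), 0.5)
  fast <- sample_cycle_length(1e6, "fast", params)
  expect_lt(abs(mean(fast) - 119), 0.2)
  expect_lt(abs(sd(fast) - 10), 0.2)
  # degenerate sd: every draw equals the mean
  expect_equal(sample_cycle_length(5, "slow", cycle_params(sd_slow = 0)),
               rep(340, 5))
  expect_warning(sample_cycle_length(1, "slow", cycle_params(sd_slow = 400)),
                 "sd")
})

test_that("initial ages follow the truncated 2^(-2C/T) density", {
  set.seed(102)
  T_len <- rep(340, 1e5)
  ages <- sample_initial_age(T_len)
  expect_true(all(ages >= 0 & ages < 340))
  # analytic CDF: F(C) = (4/3)(1 - 4^(-C/T))
  Fa <- function(C) (4 / 3) * (1 - 4^(-C / 340))
  ks <- max(abs(Fa(sort(ages)) - seq_along(ages) / length(ages)))
  expect_lt(ks, 0.01)
  # density ratio between the two ends approaches 2^2 = 4
  hlo <- mean(ages < 34) / mean(ages >= 306)
  expect_equal(hlo, 4^(306 / 340) / 1, tolerance = 0.15)
  # quantile round trip
  expect_equal(qinitial_age(Fa(170), 340), 170, tolerance = 1e-9)
})

test_that("phase labels follow the cumulative boundaries", {
  params <- cycle_params()
  expect_equal(phase_of(0, 340, "slow", params), "G0/G1")
  expect_equal(phase_of(340 - 1e-9, 340, "slow", params), "G2/M")
  # oracle: direct interval lookup against cumulative boundaries
  set.seed(103)
  for (i in 1:200) {
    Tt <- runif(1, 50, 500)
    cc <- runif(1, 0, Tt)
    prog <- sample(c("slow", "fast"), 1)
    fr <- if (prog == "slow") params$frac_slow else params$frac_fast
    expected <- c("G0/G1", "S", "G2/M")[findInterval(
      cc / Tt, cumsum(c(0, fr[c("g1", "s")])), rightmost.closed = FALSE)]
    expect_equal(phase_of(cc, Tt, prog, params), expected)
  }
})

test_that("recruitment remaps the clock phase by phase and is idempotent", {
  params <- cycle_params()
  base <- tibble::tibble(cell_id = 1:1, x = 0, y = 0, T_len = 340, C = 0,
                         program = "slow", recruited = FALSE)

  # age 0: nothing to skip, fast program from the start of G1
  set.seed(104)
  out <- recruit_cells(base, 1, params)
  expect_equal(out$C, 0)
  expect_equal(out$program, "fast")
  expect_true(out$recruited)

  # 50% through the long S phase maps to 50% through the short S phase
  mid_s <- base
  mid_s$C <- 0.45 * 340 + 0.5 * 0.45 * 340
  out <- recruit_cells(mid_s, 1, params)
  frac_through_s <- (out$C - 0.20 * out$T_len) / (0.68 * out$T_len)
  expect_equal(frac_through_s, 0.5, tolerance = 1e-9)

  # end of long G1 lands at the end of short G1: remaining = short S + G2/M
  end_g1 <- base
  end_g1$C <- 0.45 * 340 - 1e-9
  out <- recruit_cells(end_g1, 1, params)
  expect_equal(out$C / out$T_len, 0.20, tolerance = 1e-6)
  expect_equal(out$T_len - out$C, (0.68 + 0.12) * out$T_len, tolerance = 1e-4)

  # G2/M: time to division is preserved exactly
  g2 <- base
  g2$C <- 340 - 12
  out <- recruit_cells(g2, 1, params)
  expect_equal(out$T_len - out$C, 12, tolerance = 1e-9)

  # idempotent: a second recruitment is a no-op (no RNG consumed)
  rng_before <- .Random.seed
  out2 <- recruit_cells(out, 1, params)
  expect_identical(out2, out)
  expect_identical(.Random.seed, rng_before)
})

test_that("recruitment never increases the remaining time to division", {
  set.seed(105)
  params <- cycle_params()
  n <- 10000
  cells <- tibble::tibble(
    cell_id = seq_len(n), x = 0, y = 0,
    T_len = sample_cycle_length(n, "slow", params),
    program = rep("slow", n), recruited = FALSE)
  cells$C <- runif(n, 0, cells$T_len)
  before <- cells$T_len - cells$C
  out <- recruit_cells(cells, seq_len(n), params)
  after <- out$T_len - out$C
  expect_true(all(after <= before + 1e-9))
  expect_true(all(out$C >= 0 & out$C < out$T_len))
})

test_that("clock divisions double the population on the branching-process clock", {
  set.seed(106)
  params <- cycle_params()
  geom <- small_geom()
  n0 <- 500
  cells <- tibble::tibble(
    cell_id = seq_len(n0), x = runif(n0, 0, 200), y = runif(n0, 0, 60),
    T_len = sample_cycle_length(n0, "slow", params),
    program = rep("slow", n0), recruited = FALSE, lineage = seq_len(n0))
  cells$C <- sample_initial_age(cells$T_len)
  t <- 0
  events <- list()
  while (t < 192) {
    out <- advance_and_divide(cells, 1, params, geom, 7, t_now = t + 1)
    cells <- out$cells
    if (nrow(out$events) > 0) events[[length(events) + 1]] <- out$events
    t <- t + 1
  }
  growth <- nrow(cells) / n0
  expect_lt(abs(growth - 2^(192 / 340)) / 2^(192 / 340), 0.1)
  ev <- dplyr::bind_rows(events)
  # conservation: every division adds exactly one cell, none are removed
  expect_equal(nrow(cells), n0 + nrow(ev))
  # ages stay within the cycle
  expect_true(all(cells$C >= 0 & cells$C < cells$T_len))
})

test_that("division bookkeeping: placement geometry and inheritance", {
  set.seed(107)
  params <- cycle_params()
  geom <- small_geom()
  cells <- tibble::tibble(cell_id = 1:2, x = c(50, 80), y = c(30, 31),
                          T_len = c(100, 500), C = c(99.5, 1),
                          program = c("slow", "slow"),
                          recruited = c(TRUE, FALSE), lineage = 1:2)
  out <- advance_and_divide(cells, 1, params, geom, 7, t_now = 1)
  expect_equal(nrow(out$cells), 3)
  expect_equal(nrow(out$events), 1)
  d2 <- out$cells[3, ]
  # daughter inherits recruitment flag and lineage
  expect_true(d2$recruited)
  expect_equal(d2$lineage, 1L)
  # placement within 2R of the mother slot, biased posteriorly
  dist <- periodic_distance(c(out$cells$x[1], out$cells$y[1]),
                            c(d2$x, d2$y), geom)
  expect_lt(dist, 14)
  expect_gte(d2$x, out$cells$x[1])
  # the angle bound pi/8 keeps the lateral offset below the axial one
  expect_lt(abs(d2$y - out$cells$y[1]), d2$x - out$cells$x[1] + 1e-9)
})

test_that("no division leaves the population unchanged except ages", {
  set.seed(108)
  params <- cycle_params()
  cells <- small_population(30)
  out <- advance_and_divide(cells, 0.5, params, small_geom(), 7)
  expect_equal(nrow(out$cells), nrow(cells))
  expect_equal(out$cells$C, cells$C + 0.5)
  expect_equal(nrow(out$events), 0)
})

test_that("Poisson division matches its binomial and exponential oracles", {
  params <- cycle_params(nu_slow = 0.004, nu_fast = 0.02)
  geom <- small_geom()

  # nu = 0 never divides
  p0 <- cycle_params(nu_slow = 0, nu_fast = 1e-9)
  set.seed(109)
  cells <- small_population(40)
  out <- poisson_divide(cells, 1, p0, geom, 7)
  expect_equal(nrow(out$cells), nrow(cells))

  # one large step: division fraction within 3 binomial sd of 1 - e^(-nu dt)
  set.seed(110)
  n <- 1e5
  big <- tibble::tibble(cell_id = seq_len(n), x = runif(n, 0, 1e4),
                        y = runif(n, 0, 60), T_len = 100, C = 0,
                        program = "slow", recruited = FALSE,
                        lineage = seq_len(n))
  gbig <- domain_geometry(L0 = 1e4, ymin = 0, ymax = 60)
  dt <- 5
  out <- poisson_divide(big, dt, params, gbig, 7)
  pexp <- 1 - exp(-0.004 * dt)
  frac <- (nrow(out$cells) - n) / n
  expect_lt(abs(frac - pexp), 3 * sqrt(pexp * (1 - pexp) / n))

  # expectation grows as e^(nu t) over many steps
  set.seed(111)
  pop <- big[1:1000, ]
  t <- 0
  while (t < 100) {
    pop <- poisson_divide(pop, 2, params, gbig, 7)$cells
    t <- t + 2
  }
  expect_lt(abs(nrow(pop) / 1000 - exp(0.004 * 100)) / exp(0.004 * 100), 0.05)

  # memoryless: a warning fires when nu dt is too coarse
  expect_warning(
    poisson_divide(big[1:10, ], 60, params, gbig, 7),
    "Poisson")
})

test_that("recruited lineages are monotone under division and recruitment", {
  set.seed(112)
  params <- cycle_params(nu_slow = 0.01, nu_fast = 0.05)
  geom <- small_geom()
  cells <- small_population(40)
  recruited_lineages <- integer(0)
  for (i in 1:50) {
    if (i == 10) cells <- recruit_cells(cells, cells$x > 150, params)
    cells <- poisson_divide(cells, 1, params, geom, 7)$cells
    now <- sort(unique(cells$lineage[cells$recruited]))
    expect_true(all(recruited_lineages %in% now))
    recruited_lineages <- now
  }
  expect_gt(length(recruited_lineages), 0)
})
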