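#' Cell-cycle parameters
#'
#' Ependymal cells cycle with lognormally distributed total cycle lengths:
#' a slow program for non-recruited cells (mean 340 h, sd 32 h) and a fast
#' program for recruited cells (mean 119 h, sd 10 h). `mean`/`sd` are the
#' moments of the distribution itself, not of its logarithm. Phase-duration
#' fractions split each cycle into G1, S and G2/M; recruitment shortens the
#' cycle by partially skipping G1 and proportionally mapping the long S
#' phase onto the short one. The Poisson division variant replaces the
#' clocks with memoryless division frequencies `nu_slow < nu_fast` (per
#' hour), defaulting to the doubling rates of the two mean cycle lengths.
#'
#' The phase fractions are configuration defaults (they are not identifiable
#' from the tissue-level observables this package targets); see the methods
#' vignette.
#'
#' @param mean_slow,sd_slow Slow-program cycle length mean and sd (hours).
#' @param mean_fast,sd_fast Fast-program cycle length mean and sd (hours).
#' @param frac_slow,frac_fast Named numeric vectors of phase-duration
#'   fractions `c(g1=, s=, g2m=)`; each must sum to 1.
#' @param nu_slow,nu_fast Poisson division frequencies (per hour),
#'   `nu_fast > nu_slow`.
#' @param theta_star Daughter-placement half-angle (radians) about the
#'   posterior direction.
#' @return An object of class `cycle_params`.
#' @export
cycle_params <- function(mean_slow = 340, sd_slow = 32,
                         mean_fast = 119, sd_fast = 10,
                         frac_slow = c(g1 = 0.45, s = 0.45, g2m = 0.10),
                         frac_fast = c(g1 = 0.20, s = 0.68, g2m = 0.12),
                         nu_slow = log(2) / 340, nu_fast = log(2) / 119,
                         theta_star = pi / 8) {
  stopifnot(mean_slow > 0, sd_slow >= 0, mean_fast > 0, sd_fast >= 0,
            mean_fast < mean_slow,
            abs(sum(frac_slow) - 1) < 1e-8, abs(sum(frac_fast) - 1) < 1e-8,
            all(frac_slow > 0), all(frac_fast > 0),
            nu_fast > nu_slow, nu_slow >= 0)
  structure(list(mean_slow = mean_slow, sd_slow = sd_slow,
                 mean_fast = mean_fast, sd_fast = sd_fast,
                 frac_slow = frac_slow, frac_fast = frac_fast,
                 nu_slow = nu_slow, nu_fast = nu_fast,
                 theta_star = theta_star),
            class = "cycle_params")
}

lognormal_pars <- function(m, s) {
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Draw cell-cycle lengths
#'
#' Samples total cycle lengths (hours) from the lognormal distribution of
#' the given program, parameterized by its mean and standard deviation.
#'
#' @param n Number of draws.
#' @param program `"slow"` or `"fast"`.
#' @param params A [cycle_params()].
#' @return Numeric vector of positive cycle lengths (hours).
#' @export
sample_cycle_length <- function(n, program = c("slow", "fast"),
                                params = cycle_params()) {
  program <- match.arg(program)
  m <- if (program == "slow") params$mean_slow else params$mean_fast
  s <- if (program == "slow") params$sd_slow else params$sd_fast
  if (s >= m) {
    warning(sprintf(
      "cycle-length sd (%g h) is not small compared to the mean (%g h); check the configuration", s, m))
  }
  if (s == 0) return(rep(m, n))
  lp <- lognormal_pars(m, s)
  rlnorm(n, lp$meanlog, lp$sdlog)
}

#' Draw initial cell-cycle ages
#'
#' Initial ages follow a truncated exponential density proportional to
#' \eqn{2^{-2C/T}} on `[0, T)` (rate `2 ln 2 / T`), normalized on the
#' interval and sampled by its inverse CDF, so the density at age 0 is four
#' times the density at age `T`.
#'
#' @param T_len Numeric vector of total cycle lengths (hours).
#' @return Ages in `[0, T_len)`, one per cycle length.
#' @export
sample_initial_age <- function(T_len) {
  stopifnot(all(T_len > 0))
  u <- runif(length(T_len))
  -T_len * log1p(-0.75 * u) / (2 * log(2))
}

#' Quantile function of the initial-age distribution
#'
#' Closed-form inverse CDF of the distribution sampled by
#' [sample_initial_age()]; exposed for validation.
#'
#' @param p Probabilities.
#' @param T_len Total cycle length (hours).
#' @return Ages (hours).
#' @export
qinitial_age <- function(p, T_len) {
  -T_len * log1p(-0.75 * p) / (2 * log(2))
}

phase_lengths <- function(T_len, program, params) {
  fr <- matrix(NA_real_, length(T_len), 3)
  sl <- program == "slow"
  if (any(sl)) fr[sl, ] <- matrix(params$frac_slow, sum(sl), 3, byrow = TRUE)
  if (any(!sl)) fr[!sl, ] <- matrix(params$frac_fast, sum(!sl), 3, byrow = TRUE)
  fr * T_len
}

#' Cell-cycle phase of a clock
#'
#' Deterministic phase label from age against the cumulative phase
#' boundaries of the active program: `G0/G1` for ages below the G1/S
#' boundary, `S` up to the S/G2 boundary, `G2/M` beyond.
#'
#' @param C Ages (hours).
#' @param T_len Total cycle lengths (hours).
#' @param program Character vector, `"slow"` or `"fast"` per cell.
#' @param params A [cycle_params()].
#' @return Character vector in `c("G0/G1", "S", "G2/M")`.
#' @export
phase_of <- function(C, T_len, program, params = cycle_params()) {
  pl <- phase_lengths(T_len, program, params)
  b1 <- pl[, 1]
  b2 <- pl[, 1] + pl[, 2]
  dplyr::case_when(C < b1 ~ "G0/G1", C < b2 ~ "S", TRUE ~ "G2/M")
}

#' Recruit cells: switch clocks to the fast program
#'
#' Recruitment is irreversible and maps the slow clock onto a freshly drawn
#' fast cycle length: a cell in G1 beyond the length of the short G1 is
#' placed at the end of the short G1 (partial G1 skip), a cell early in G1
#' keeps its age; a cell in S keeps its fractional progress through S
#' (proportional mapping); a cell in G2/M keeps its remaining time to
#' division. Already-recruited cells are left untouched (idempotent).
#'
#' @param cells Cell tibble with columns `T_len`, `C`, `program`,
#'   `recruited`.
#' @param idx Indices (or logical mask) of cells to recruit.
#' @param params A [cycle_params()].
#' @return The updated cell tibble.
#' @export
recruit_cells <- function(cells, idx, params = cycle_params()) {
  if (is.logical(idx)) idx <- which(idx)
  idx <- idx[!cells$recruited[idx]]
  if (length(idx) == 0) return(cells)
  Ts <- cells$T_len[idx]
  Cs <- cells$C[idx]
  Tf <- sample_cycle_length(length(idx), "fast", params)
  b1s <- params$frac_slow[["g1"]] * Ts
  b2s <- b1s + params$frac_slow[["s"]] * Ts
  g1f <- params$frac_fast[["g1"]] * Tf
  sf <- params$frac_fast[["s"]] * Tf
  newC <- numeric(length(idx))
  in_g1 <- Cs < b1s
  in_s <- !in_g1 & Cs < b2s
  in_g2 <- !in_g1 & !in_s
  newC[in_g1] <- pmin(Cs[in_g1], g1f[in_g1])
  phi <- (Cs[in_s] - b1s[in_s]) / (params$frac_slow[["s"]] * Ts[in_s])
  newC[in_s] <- g1f[in_s] + phi * sf[in_s]
  newC[in_g2] <- pmax(Tf[in_g2] - (Ts[in_g2] - Cs[in_g2]), 0)
  cells$T_len[idx] <- Tf
  cells$C[idx] <- newC
  cells$program[idx] <- "fast"
  cells$recruited[idx] <- TRUE
  cells
}

.no_events <- tibble::tibble(t = numeric(), mother_id = integer(),
                             daughter1 = integer(), daughter2 = integer(),
                             recruited = logical())

place_daughters <- function(cells, dividing, geom, R, params, t_now,
                            id_start) {
  n <- sum(dividing)
  if (n == 0) {
    return(list(cells = cells, events = .no_events))
  }
  mothers <- cells[dividing, ]
  u <- runif(n, 0, 2 * R)
  th <- runif(n, -params$theta_star, params$theta_star)
  d2 <- mothers
  d2$x <- pmax(mothers$x + u * cos(th), 0)
  d2$y <- wrap_y(mothers$y + u * sin(th), geom)
  d2$cell_id <- id_start + seq_len(n)
  d2$C <- 0
  events <- tibble::tibble(t = t_now, mother_id = mothers$cell_id,
                           daughter1 = mothers$cell_id,
                           daughter2 = d2$cell_id,
                           recruited = mothers$recruited)
  list(cells = dplyr::bind_rows(cells, d2), events = events)
}

#' Advance cell-cycle clocks and divide
#'
#' Ages every clock by `dt` hours; a cell whose age reaches its cycle
#' length divides: one daughter keeps the mother's position, the other is
#' placed at a uniform distance in `(0, 2R)` at a uniform angle in
#' `(-theta*, theta*)` about the posterior direction. Both daughters draw
#' fresh cycle lengths from their program; the residual age beyond division
#' is carried into the daughter keeping the mother's slot to reduce
#' time-step bias. Recruitment status is inherited.
#'
#' @param cells Cell tibble (columns `cell_id`, `x`, `y`, `T_len`, `C`,
#'   `program`, `recruited`, `lineage`).
#' @param dt Time step (hours); should be well below the shortest cycle.
#' @param params A [cycle_params()].
#' @param geom A [domain_geometry()].
#' @param R Cell radius (um).
#' @param t_now Absolute time (hours) recorded in the division event log.
#' @return `list(cells = <tibble>, events = <tibble>)`; events have columns
#'   `t`, `mother_id`, `daughter1`, `daughter2`, `recruited`.
#' @export
advance_and_divide <- function(cells, dt, params, geom, R, t_now = NA_real_) {
  stopifnot(dt > 0)
  if (nrow(cells) > 0 && dt > 0.1 * min(cells$T_len)) {
    warning("time step is not small compared to the shortest cell cycle; division events may be under-resolved")
  }
  cells$C <- cells$C + dt
  dividing <- cells$C >= cells$T_len
  if (any(dividing)) {
    residual <- cells$C[dividing] - cells$T_len[dividing]
    Tn <- numeric(sum(dividing))
    slow_idx <- cells$program[dividing] == "slow"
    Tn[slow_idx] <- sample_cycle_length(sum(slow_idx), "slow", params)
    Tn[!slow_idx] <- sample_cycle_length(sum(!slow_idx), "fast", params)
    cells$T_len[dividing] <- Tn
    cells$C[dividing] <- pmin(residual, Tn * 0.999)
  }
  out <- place_daughters(cells, dividing, geom, R, params, t_now,
                         id_start = max(cells$cell_id, 0L))
  # daughter-2 cells draw their own cycle lengths and start at age 0
  nd <- nrow(out$events)
  if (nd > 0) {
    new_rows <- out$cells$cell_id > max(cells$cell_id)
    prog2 <- out$cells$program[new_rows]
    T2 <- numeric(nd)
    T2[prog2 == "slow"] <- sample_cycle_length(sum(prog2 == "slow"), "slow", params)
    T2[prog2 != "slow"] <- sample_cycle_length(sum(prog2 != "slow"), "fast", params)
    out$cells$T_len[new_rows] <- T2
  }
  out
}

#' Poisson-variant division step
#'
#' Simplified division model: each cell divides within `dt` independently
#' with probability `1 - exp(-nu dt)`, where `nu` is `nu_fast` for
#' recruited cells and `nu_slow` otherwise. Daughter placement matches
#' [advance_and_divide()]. Clock columns are carried along untouched.
#'
#' @inheritParams advance_and_divide
#' @return `list(cells, events)` as for [advance_and_divide()].
#' @export
poisson_divide <- function(cells, dt, params, geom, R, t_now = NA_real_) {
  stopifnot(dt > 0)
  nu <- ifelse(cells$recruited, params$nu_fast, params$nu_slow)
  if (length(nu) > 0 && max(nu) * dt > 0.2) {
    warning("nu * dt > 0.2: the per-step division probability is a poor Poisson approximation")
  }
  p <- -expm1(-nu * dt)
  dividing <- runif(nrow(cells)) < p
  if (any(dividing)) cells$C[dividing] <- 0
  place_daughters(cells, dividing, geom, R, params, t_now,
                  id_start = max(cells$cell_id, 0L))
}
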