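#' Simulation configuration
#'
#' Collects every model parameter with explicit units at the configuration
#' surface: `D` in um^2/s, `k` in 1/day, times in days, lengths in um.
#' Internally the engine works in hours and micrometres.
#'
#' @param D,k,rho0,rhos_min,particle_mass,h,rho_star,cfl,degrade_in_source
#'   Signal parameters, see [signal_params()].
#' @param R Cell radius (um).
#' @param L0,ymin,ymax Domain geometry, see [domain_geometry()].
#' @param kappa Hard-disc repulsion intensity.
#' @param cycle A [cycle_params()].
#' @param division_model `"clock"` (non-Markovian cell-cycle clocks) or
#'   `"poisson"` (memoryless division frequencies).
#' @param t_end Simulated time (days).
#' @param seed Integer seed; recorded in every output.
#' @param record_every Observable recording cadence (days).
#' @param snapshot_days Times (days) at which full cell snapshots are kept.
#' @param n_throw Cells thrown at initialization before trimming; defaults
#'   to 1.05 times the disc area of the initial domain, so the relaxed,
#'   trimmed packing starts at its jammed density and cell divisions
#'   translate into tissue elongation rather than silent densification.
#' @param relax_tol Stopping tolerance of the overlap descent as a fraction
#'   of the cell diameter. The population invariant only requires overlaps
#'   below a tenth of a diameter, but stopping the descent there lets the
#'   packing compact a little after every division and the tissue absorbs
#'   growth instead of elongating; the tighter default keeps the packing
#'   fraction stationary so that cell divisions translate into tissue
#'   length.
#' @param dt_max Absolute time-step cap (hours).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(D = 1, k = 1, rho0 = 40, rhos_min = 3,
                              particle_mass = 400, R = 7, h = 4 * R,
                              rho_star = rho0 / 100, cfl = 0.5,
                              degrade_in_source = FALSE,
                              L0 = 1000, ymin = 0, ymax = 180, kappa = 1,
                              cycle = cycle_params(),
                              division_model = c("clock", "poisson"),
                              t_end = 8, seed = 1L, record_every = 0.2,
                              snapshot_days = NULL, n_throw = NULL,
                              relax_tol = 0.02, dt_max = 0.5) {
  division_model <- match.arg(division_model)
  geom <- domain_geometry(L0 = L0, ymin = ymin, ymax = ymax)
  sp <- signal_params(D = D, k = k, rho0 = rho0, rhos_min = rhos_min,
                      particle_mass = particle_mass, R = R, h = h,
                      rho_star = rho_star, cfl = cfl,
                      degrade_in_source = degrade_in_source)
  if (is.null(n_throw)) {
    n_throw <- max(2L, round(1.05 * L0 * (ymax - ymin) / (pi * R^2)))
  }
  structure(list(geom = geom, sp = sp, cycle = cycle, R = R, kappa = kappa,
                 division_model = division_model, t_end = t_end,
                 seed = as.integer(seed), record_every = record_every,
                 snapshot_days = snapshot_days, n_throw = n_throw,
                 relax_tol = relax_tol, dt_max = dt_max),
            class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' Accepts a YAML file whose top-level keys match the arguments of
#' [simulation_config()] (units as documented there); `cycle` may be a
#' mapping with the arguments of [cycle_params()].
#'
#' @param path Path to a YAML file.
#' @return A `simulation_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$cycle)) raw$cycle <- do.call(cycle_params, raw$cycle)
  do.call(simulation_config, raw)
}

empty_events <- function() .no_events

#' Run the hybrid regeneration simulation
#'
#' Operator-splitting loop over a fixed signal time step: (1) diffusion
#' (particles move along their regularized density gradient), (2)
#' stochastic degradation, (3) Dirichlet boundaries on the moving domain
#' (anterior absorption, front-strip source refill), (4) recruitment of
#' eligible cells (supra-threshold local density with at least two
#' particles in range), (5) cell division by clock or Poisson model, (6)
#' hard-disc overlap relaxation, (7) tissue length update from the front
#' cells, and periodic recording of observables. Deterministic given the
#' configuration seed.
#'
#' @param config A [simulation_config()].
#' @param quiet Unused hook for progress reporting; kept for CLI symmetry.
#' @return An object of class `regen_sim`: a list with `observables`
#'   (tibble of time series), `recruitment_events`, `division_events`,
#'   `snapshots` (named list of cell tibbles), `cells`, `particles` (final
#'   states, amputation-plane coordinate column `z` added), and `config`.
#' @export
run_simulation <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  geom <- config$geom
  sp <- config$sp
  cyc <- config$cycle
  R <- config$R

  cells <- initialize_cells(geom, config$n_throw, R, config$kappa,
                            eps = config$relax_tol)
  n <- nrow(cells)
  cells$T_len <- sample_cycle_length(n, "slow", cyc)
  cells$C <- sample_initial_age(cells$T_len)
  cells$program <- rep("slow", n)
  cells$recruited <- rep(FALSE, n)
  cells$lineage <- cells$cell_id
  cells <- as.data.frame(cells)

  L <- tissue_length(cells, geom, R)
  # the amputation plane is the realized initial front: a trimmed random
  # packing ends slightly anterior of the nominal L0
  L0e <- L
  pp <- boundaries_xy(numeric(0), numeric(0), L, sp, geom)

  dt <- choose_timestep(sp, config$dt_max)
  t_end_h <- config$t_end * 24
  n_steps <- ceiling(t_end_h / dt)
  rec_every_h <- config$record_every * 24
  snap_h <- sort(unique(c(config$snapshot_days))) * 24

  rec <- vector("list", floor(t_end_h / rec_every_h) + 2L)
  recruit_t <- numeric(0)
  recruit_id <- integer(0)
  div_events <- list()
  snapshots <- list()

  record_row <- function(t_h) {
    ls <- if (any(cells$recruited)) min(cells$x[cells$recruited]) else L
    xi <- if (any(cells$recruited)) ls - L0e else NA_real_
    tibble::tibble(
      t_days = t_h / 24, n_cells = nrow(cells),
      n_recruited = sum(cells$recruited), n_particles = length(pp$x),
      L = L, outgrowth = L - L0e, xi = xi,
      Ls = ls, Lf = L - ls)
  }
  take_snapshot <- function(t_h) {
    snap <- as_tibble(cells)
    snap$z <- snap$x - L0e
    snap$phase <- phase_of(snap$C, snap$T_len, snap$program, cyc)
    snapshots[[sprintf("day_%g", t_h / 24)]] <<- snap
  }

  ri <- 1L
  rec[[ri]] <- record_row(0)
  next_rec <- rec_every_h
  next_snap_i <- 1L
  if (length(snap_h) > 0 && snap_h[1] == 0) {
    take_snapshot(0)
    next_snap_i <- 2L
  }

  t_h <- 0
  for (step in seq_len(n_steps)) {
    dt_i <- min(dt, t_end_h - t_h)
    if (dt_i <= 0) break
    pp <- diffuse_xy(pp$x, pp$y, dt_i, sp, geom)
    keep <- degrade_keep(pp$x, dt_i, sp, L)
    pp <- boundaries_xy(pp$x[keep], pp$y[keep], L, sp, geom)

    ex <- sph_eval_cpp(pp$x, pp$y, cells$x, cells$y, sp$particle_mass,
                       sp$h, geom$ymin, geom$width)
    newly <- which(ex$count >= 2L & ex$rho > sp$rhos_min & !cells$recruited)
    if (length(newly) > 0) {
      if (config$division_model == "clock") {
        cells <- recruit_cells(cells, newly, cyc)
      } else {
        cells$program[newly] <- "fast"
        cells$recruited[newly] <- TRUE
      }
      recruit_t <- c(recruit_t, rep(t_h + dt_i, length(newly)))
      recruit_id <- c(recruit_id, cells$cell_id[newly])
    }

    if (config$division_model == "clock") {
      out <- advance_and_divide(cells, dt_i, cyc, geom, R, t_now = t_h + dt_i)
    } else {
      out <- poisson_divide(cells, dt_i, cyc, geom, R, t_now = t_h + dt_i)
    }
    cells <- out$cells
    if (nrow(out$events) > 0) {
      div_events[[length(div_events) + 1L]] <- out$events
      cells <- relax_overlaps(cells, geom, R, config$kappa,
                              eps = config$relax_tol)
      attr(cells, "iterations") <- NULL
      attr(cells, "max_overlap") <- NULL
    }
    L <- tissue_length(cells, geom, R)
    t_h <- t_h + dt_i

    if (t_h + 1e-9 >= next_rec) {
      ri <- ri + 1L
      rec[[ri]] <- record_row(t_h)
      next_rec <- next_rec + rec_every_h
    }
    while (next_snap_i <= length(snap_h) && t_h + 1e-9 >= snap_h[next_snap_i]) {
      take_snapshot(t_h)
      next_snap_i <- next_snap_i + 1L
    }
  }

  obs <- dplyr::bind_rows(rec[seq_len(ri)])
  cells_out <- as_tibble(cells)
  cells_out$z <- cells_out$x - L0e
  cells_out$phase <- phase_of(cells_out$C, cells_out$T_len,
                              cells_out$program, cyc)
  div <- if (length(div_events) > 0) {
    dplyr::bind_rows(div_events)
  } else {
    empty_events()
  }
  div$t <- div$t / 24
  structure(list(
    observables = obs,
    recruitment_events = tibble::tibble(t_days = recruit_t / 24,
                                        cell_id = recruit_id),
    division_events = dplyr::rename(div, t_days = "t"),
    snapshots = snapshots,
    cells = cells_out,
    particles = tibble::tibble(x = pp$x, y = pp$y),
    L0_effective = L0e,
    dt_hours = dt,
    config = config,
    seed = config$seed), class = "regen_sim")
}

#' @export
print.regen_sim <- function(x, ...) {
  ob <- x$observables
  last <- ob[nrow(ob), ]
  cat(sprintf(
    "<regen_sim> %s model, %g days, seed %d\n  cells: %d (%d recruited), outgrowth %.1f um, recruitment limit %s um\n",
    x$config$division_model, x$config$t_end, x$seed, last$n_cells,
    last$n_recruited, last$outgrowth,
    ifelse(is.na(last$xi), "NA", sprintf("%.1f", last$xi))))
  invisible(x)
}

#' Recruitment limit of a cell population
#'
#' The anterior-posterior position of the most anteriorly recruited cell,
#' in amputation-plane coordinates (`z = x - L0`; negative = anterior of
#' the plane). `NA` when no cell is recruited.
#'
#' @param cells Cell table with columns `x` and `recruited`.
#' @param geom A [domain_geometry()].
#' @return Recruitment limit in micrometres, or `NA`.
#' @export
recruitment_limit <- function(cells, geom) {
  if (!any(cells$recruited)) return(NA_real_)
  min(cells$x[cells$recruited]) - geom$L0
}

#' Spatial cell-cycle phase profile
#'
#' Fractions of cells in the pooled reporter channels G0/G1 versus S/G2
#' (S and G2/M pooled, matching the two-colour cell-cycle reporter), in
#' bins along the anterior-posterior axis (amputation-plane coordinates).
#' Empty bins are reported with `NA` fractions, not zeros.
#'
#' @param cells Cell table with `x`, `T_len`, `C`, `program`.
#' @param params A [cycle_params()].
#' @param geom A [domain_geometry()].
#' @param bin_width Bin width along the AP axis (um).
#' @return A tibble with `z_mid`, `n`, `frac_g0g1`, `frac_sg2`.
#' @export
phase_profile <- function(cells, params, geom, bin_width = 50) {
  stopifnot(bin_width > 0)
  z <- cells$x - geom$L0
  lo <- floor(min(z) / bin_width) * bin_width
  hi <- ceiling(max(z) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  mids <- breaks[-1] - bin_width / 2
  bin <- findInterval(z, breaks, rightmost.closed = TRUE)
  ph <- phase_of(cells$C, cells$T_len, cells$program, params)
  g01 <- ph == "G0/G1"
  n <- tabulate(bin, nbins = length(mids))
  n01 <- tabulate(bin[g01], nbins = length(mids))
  tibble::tibble(
    z_mid = mids, n = n,
    frac_g0g1 = ifelse(n > 0, n01 / n, NA_real_),
    frac_sg2 = ifelse(n > 0, 1 - n01 / n, NA_real_))
}

#' Newly recruited cells per time window
#'
#' Histogram of signal-driven recruitment events (inheritance by daughters
#' is not an event) in fixed windows, by default 0.2 days.
#'
#' @param events Recruitment-event table with column `t_days`, or a
#'   `regen_sim` (its `recruitment_events` are used).
#' @param window Window width (days).
#' @param t_end End of the covered period (days); defaults to the last
#'   event (or one window when there are none).
#' @return A tibble with `t_mid` (window midpoint, days) and `count`.
#' @export
newly_recruited_counts <- function(events, window = 0.2, t_end = NULL) {
  if (inherits(events, "regen_sim")) {
    if (is.null(t_end)) t_end <- events$config$t_end
    events <- events$recruitment_events
  }
  tt <- sort(events$t_days)
  if (is.null(t_end)) t_end <- if (length(tt) > 0) max(tt) else window
  nb <- max(1L, as.integer(ceiling((t_end - 1e-9) / window)))
  nb <- max(nb, if (length(tt) > 0) as.integer(ceiling(max(tt) / window)) else 1L)
  idx <- pmax(1L, as.integer(ceiling(tt / window)))
  counts <- tabulate(idx, nbins = nb)
  tibble::tibble(t_mid = (seq_len(nb) - 0.5) * window, count = counts)
}

#' Signal-only simulation on a fixed domain
#'
#' Runs the signalling scale alone (no cells, fixed tissue length):
#' diffusion, degradation and the two Dirichlet boundaries, accumulating a
#' time-averaged one-dimensional density profile after a burn-in. Used to
#' validate the particle scheme against the analytic steady state
#' [steady_state_profile()].
#'
#' @param L Fixed tissue length (um).
#' @param sp A [signal_params()].
#' @param geom A [domain_geometry()] (only the strip width is used).
#' @param t_total Total simulated hours.
#' @param burn_in Hours discarded before averaging.
#' @param bin_width Profile bin width (um).
#' @param seed Integer seed.
#' @return A list with `profile` (tibble `x_mid`, `rho`), `particles`,
#'   `dt_hours`, `n_averaged`.
#' @export
simulate_signal_field <- function(L, sp, geom, t_total, burn_in,
                                  bin_width = 20, seed = 1L) {
  set.seed(seed)
  dt <- choose_timestep(sp)
  particles <- data.frame(x = numeric(), y = numeric())
  particles <- apply_boundaries(particles, L, sp, geom)
  breaks <- seq(0, L, by = bin_width)
  if (breaks[length(breaks)] < L) breaks <- c(breaks, L)
  acc <- numeric(length(breaks) - 1)
  n_avg <- 0L
  t_h <- 0
  while (t_h < t_total) {
    particles <- diffusion_step(particles, dt, sp, geom)
    particles <- degradation_step(particles, dt, sp, L)
    particles <- apply_boundaries(particles, L, sp, geom)
    t_h <- t_h + dt
    if (t_h > burn_in) {
      acc <- acc + tabulate(findInterval(particles$x, breaks,
                                         rightmost.closed = TRUE),
                            nbins = length(breaks) - 1)
      n_avg <- n_avg + 1L
    }
  }
  widths <- diff(breaks)
  rho <- sp$particle_mass * acc / (n_avg * widths * geom$width)
  list(profile = tibble::tibble(x_mid = breaks[-1] - widths / 2, rho = rho),
       particles = as_tibble(particles), dt_hours = dt, n_averaged = n_avg)
}

#' Write cell snapshots to CSV
#'
#' Tabular snapshot schema: `t_days`, `cell_id`, `x_shifted`,
#' `z_amputation`, `y`, `recruited`, `phase`.
#'
#' @param sim A `regen_sim`.
#' @param path Output CSV path.
#' @return The written tibble, invisibly.
#' @export
write_cell_snapshots <- function(sim, path) {
  stopifnot(inherits(sim, "regen_sim"))
  rows <- purrr::imap(sim$snapshots, function(snap, name) {
    tibble::tibble(
      t_days = as.numeric(sub("day_", "", name)),
      cell_id = snap$cell_id, x_shifted = snap$x, z_amputation = snap$z,
      y = snap$y, recruited = snap$recruited, phase = snap$phase)
  })
  out <- dplyr::bind_rows(rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
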