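#' Trapezoidal squared-curve error
#'
#' Distance between two curves sampled at common (or interpolatable)
#' times: with \eqn{C(t_i) = |a(t_i) - b(t_i)|},
#' \deqn{E = \sum_{n=1}^{N-1} \frac{C(t_n)^2 + C(t_{n+1})^2}{2}\Delta t_n,}
#' i.e. the trapezoid-rule integral of the squared absolute difference
#' over time. Symmetric, non-negative, zero iff the curves agree on the
#' grid, and quadratic under common rescaling of the values.
#'
#' @param sim,ref Curves: tibbles/data frames with columns `t` and
#'   `value`. If the grids differ, `ref` is linearly interpolated onto the
#'   `sim` grid (constant extrapolation at the ends).
#' @return The error `E` (value-units squared times time-units).
#' @export
curve_error <- function(sim, ref) {
  sim <- as.data.frame(sim)
  ref <- as.data.frame(ref)
  if (nrow(sim) < 2) stop("curve error needs at least two time points")
  stopifnot(!is.unsorted(sim$t, strictly = TRUE))
  rv <- if (isTRUE(all.equal(sim$t, ref$t))) {
    ref$value
  } else {
    if (nrow(ref) < 2) stop("reference curve has fewer than two points")
    approx(ref$t, ref$value, xout = sim$t, rule = 2)$y
  }
  C2 <- (sim$value - rv)^2
  n <- length(C2)
  sum((C2[-n] + C2[-1]) / 2 * diff(sim$t))
}

interp_profile <- function(pos, val, xout) {
  approx(pos, val, xout = xout, rule = 2)$y
}

#' Relative error against per-animal phase profiles
#'
#' Compares simulated spatial fractions of cells in the two pooled
#' cell-cycle reporter channels (S/G2 and G0/G1) against a set of
#' per-animal experimental profiles at one timepoint: for each animal and
#' each channel, the curve error of simulation versus animal is normalized
#' by the curve error of the animal's profile versus zero, and the
#' reported error is the minimum over animals of the minimum over the two
#' channels. Zero iff the simulation matches one animal's channel exactly.
#'
#' @param sim Simulated profile: tibble with columns `position`, `sg2`,
#'   `g0g1` (fractions along the AP axis).
#' @param experiments Per-animal profiles: tibble with columns
#'   `animal_id`, `position`, `sg2`, `g0g1`; interpolated onto the
#'   simulated positions.
#' @return Non-negative scalar error.
#' @export
relative_phase_error <- function(sim, experiments) {
  sim <- as.data.frame(sim)
  xout <- sim$position
  zero <- tibble::tibble(t = xout, value = 0)
  per_animal <- experiments |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_map(function(an, key) {
      errs <- purrr::map_dbl(c("sg2", "g0g1"), function(ch) {
        ev <- interp_profile(an$position, an[[ch]], xout)
        exp_curve <- tibble::tibble(t = xout, value = ev)
        denom <- curve_error(exp_curve, zero)
        if (denom == 0) {
          warning(sprintf("zero-norm experimental %s profile skipped", ch))
          return(NA_real_)
        }
        sim_curve <- tibble::tibble(t = xout, value = sim[[ch]])
        curve_error(sim_curve, exp_curve) / denom
      })
      min(errs, na.rm = TRUE)
    })
  min(unlist(per_animal))
}

#' Grid sweep fit of the signal parameters
#'
#' For every `(D, k)` (optionally with a threshold column) in `grid`, the
#' `runner` produces a simulated recruitment-limit curve per seed; the
#' seed-mean curve is compared with the reference by [curve_error()]
#' computed on millimetre-scaled curves (so the default tolerance
#' `eps_fit = 0.5` admits roughly a quarter-millimetre average deviation
#' over the fitted window), and points with error below `eps_fit` form the
#' accepted set. Each grid point is annotated with its implied
#' characteristic length.
#'
#' @param grid Tibble with columns `D` (um^2/s) and `k` (per day); extra
#'   columns are passed through to `runner`.
#' @param ref Reference curve: tibble with `t` (days) and `value` (um).
#' @param runner `function(D, k, seed, ...)` returning a tibble with `t`
#'   (days) and `value` (um); called once per seed per grid point.
#' @param eps_fit Acceptance tolerance on the error (mm^2 day).
#' @param seeds Integer seeds averaged per grid point.
#' @return A `regen_fit`: the grid with columns `error`, `accepted`,
#'   `lambda`, plus attributes `eps_fit` and `seeds`.
#' @export
fit_sweep <- function(grid, ref, runner, eps_fit = 0.5, seeds = 1:5) {
  stopifnot(all(c("D", "k") %in% names(grid)))
  ref_mm <- tibble::tibble(t = ref$t, value = ref$value / 1000)
  res <- purrr::pmap_dbl(grid, function(D, k, ...) {
    curves <- purrr::map(seeds, function(s) runner(D = D, k = k, seed = s, ...))
    tmpl <- curves[[1]]$t
    vals <- purrr::map(curves, function(cu) {
      if (isTRUE(all.equal(cu$t, tmpl))) cu$value
      else approx(cu$t, cu$value, xout = tmpl, rule = 2)$y
    })
    mean_curve <- tibble::tibble(t = tmpl,
                                 value = Reduce(`+`, vals) / length(vals) / 1000)
    curve_error(mean_curve, ref_mm)
  })
  out <- as_tibble(grid)
  out$error <- res
  out$accepted <- out$error < eps_fit
  out$lambda <- characteristic_length(out$D, out$k)
  if (!any(out$accepted)) {
    message("fit_sweep: no grid point met the tolerance; the accepted set is empty")
  }
  structure(out, class = c("regen_fit", class(out)),
            eps_fit = eps_fit, seeds = seeds)
}

#' Synthetic recruitment-limit (switchpoint) curve
#'
#' Stand-in for an experimental recruitment-limit time series: daily
#' samples of the theoretical recruitment limit for a known
#' characteristic length, plus i.i.d. Gaussian noise. The generating
#' `lambda_true` is recorded as an attribute so recovery studies can be
#' scored.
#'
#' @param lambda_true Characteristic length (um) of the generating theory;
#'   must be below `L0`.
#' @param params A [theory_params()] **without** its `lambda` (the
#'   remaining fields are reused); alternatively `NULL` to use defaults.
#' @param noise_sd Gaussian noise sd (um).
#' @param days Sample times (days).
#' @return A tibble with `t` (days), `value` (um), `sd`; attribute
#'   `lambda_true`.
#' @export
synth_switchpoint_curve <- function(lambda_true, params = NULL,
                                    noise_sd = 10, days = 0:8) {
  if (is.null(params)) {
    params <- theory_params(lambda = lambda_true)
  } else {
    params <- theory_params(lambda = lambda_true, rho0 = params$rho0,
                            rhos_min = params$rhos_min,
                            nu_slow = params$nu_slow,
                            nu_fast = params$nu_fast, L0 = params$L0)
  }
  xi <- theory_recruitment_limit(days * 24, params)$xi
  out <- tibble::tibble(t = days, value = xi + rnorm(length(days), 0, noise_sd),
                        sd = noise_sd)
  attr(out, "lambda_true") <- lambda_true
  out
}

#' Synthetic per-animal cell-cycle phase profiles
#'
#' Stand-in for two-colour cell-cycle reporter data: runs one seeded
#' simulation, extracts the daily spatial phase profile, and emulates
#' per-animal finite-count sampling by drawing, for every bin, a binomial
#' G0/G1 count with the bin's cell count as the number of trials. The two
#' channels sum to one before noise and per animal after noise (the two
#' fractions are complementary by construction).
#'
#' @param config A [simulation_config()]; snapshot days are set to `days`.
#' @param n_animals Number of synthetic animals (noise replicates).
#' @param days Daily timepoints (days).
#' @param bin_width Profile bin width (um).
#' @return A list: `profiles` (tibble `animal_id`, `t_days`, `position`,
#'   `g0g1`, `sg2`), `truth` (noiseless profiles), `sim` (the
#'   `regen_sim`).
#' @export
synth_fucci_profiles <- function(config, n_animals = 3, days = 0:5,
                                 bin_width = 50) {
  stopifnot(n_animals >= 1)
  config$snapshot_days <- days
  sim <- run_simulation(config)
  truth <- purrr::imap(sim$snapshots, function(snap, name) {
    pr <- phase_profile(snap, config$cycle, config$geom, bin_width)
    pr$t_days <- as.numeric(sub("day_", "", name))
    pr
  }) |> dplyr::bind_rows()
  profiles <- purrr::map(seq_len(n_animals), function(a) {
    ok <- truth$n > 0
    g01_count <- rbinom(sum(ok), truth$n[ok], truth$frac_g0g1[ok])
    out <- truth[ok, ]
    out$g0g1 <- g01_count / out$n
    out$sg2 <- 1 - out$g0g1
    tibble::tibble(animal_id = a, t_days = out$t_days, position = out$z_mid,
                   g0g1 = out$g0g1, sg2 = out$sg2)
  }) |> dplyr::bind_rows()
  truth_out <- tibble::tibble(t_days = truth$t_days, position = truth$z_mid,
                              n = truth$n, g0g1 = truth$frac_g0g1,
                              sg2 = truth$frac_sg2)
  list(profiles = profiles, truth = truth_out, sim = sim)
}
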