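#' Tidy a simulation into its observable time series
#'
#' @param x A `regen_sim`.
#' @param ... Unused.
#' @return The observables tibble (one row per recorded time) with the
#'   seed attached as a column.
#' @export
tidy.regen_sim <- function(x, ...) {
  out <- x$observables
  out$seed <- x$seed
  out
}

#' One-row summary of a simulation
#'
#' @param x A `regen_sim`.
#' @param ... Unused.
#' @return A one-row tibble: final time, cell/recruited/particle counts,
#'   outgrowth, recruitment limit, total signal-driven recruitment events,
#'   division count, model and seed.
#' @export
glance.regen_sim <- function(x, ...) {
  ob <- x$observables
  last <- ob[nrow(ob), ]
  tibble::tibble(
    t_days = last$t_days, n_cells = last$n_cells,
    n_recruited = last$n_recruited, n_particles = last$n_particles,
    outgrowth = last$outgrowth, xi = last$xi,
    n_recruitment_events = nrow(x$recruitment_events),
    n_divisions = nrow(x$division_events),
    division_model = x$config$division_model, seed = x$seed)
}

#' Tidy a fit sweep
#'
#' @param x A `regen_fit`.
#' @param ... Unused.
#' @return The grid tibble with `error`, `accepted` and implied `lambda`.
#' @export
tidy.regen_fit <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-row summary of a fit sweep
#'
#' @param x A `regen_fit`.
#' @param ... Unused.
#' @return A one-row tibble: grid size, accepted count, tolerance, error
#'   range, and the median and coefficient of variation of the accepted
#'   characteristic lengths.
#' @export
glance.regen_fit <- function(x, ...) {
  acc <- x$lambda[x$accepted]
  tibble::tibble(
    n_grid = nrow(x), n_accepted = sum(x$accepted),
    eps_fit = attr(x, "eps_fit"),
    min_error = min(x$error), max_error = max(x$error),
    lambda_median = if (length(acc) > 0) stats::median(acc) else NA_real_,
    lambda_cv = if (length(acc) > 1) sd(acc) / mean(acc) else NA_real_)
}
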