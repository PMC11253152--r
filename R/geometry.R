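#' Domain geometry of the ependymal strip
#'
#' The tissue is modelled as a strip that is periodic in `y` (the arc length
#' along the circumference of the central canal) and grows freely at its
#' posterior end. Internally all cell and particle positions use shifted
#' coordinates `x` in `[0, L(t)]` with the fixed anterior wall at `x = 0`;
#' positions reported to the user are converted to amputation-plane
#' coordinates `z = x - L0`, so the amputation plane is `z = 0` and anterior
#' positions are negative.
#'
#' @param L0 Initial tissue length in micrometres (distance from the fixed
#'   anterior boundary to the amputation plane).
#' @param ymin,ymax Circumference bounds in micrometres; the domain is
#'   periodic in `y` with period `ymax - ymin`.
#' @return An object of class `domain_geometry`.
#' @examples
#' geom <- domain_geometry(L0 = 400, ymin = 0, ymax = 60)
#' @export
domain_geometry <- function(L0 = 1000, ymin = 0, ymax = 180) {
  stopifnot(L0 > 0, ymax > ymin)
  structure(list(L0 = L0, ymin = ymin, ymax = ymax, width = ymax - ymin),
            class = "domain_geometry")
}

#' @export
print.domain_geometry <- function(x, ...) {
  cat(sprintf(
    "<domain_geometry> L0 = %g um, y in [%g, %g) um (periodic)\n",
    x$L0, x$ymin, x$ymax))
  invisible(x)
}

#' Wrap y-coordinates into the periodic strip
#'
#' @param y Numeric vector of y positions (um).
#' @param geom A [domain_geometry()].
#' @return Numeric vector with all values in `[ymin, ymax)`.
#' @export
wrap_y <- function(y, geom) {
  geom$ymin + ((y - geom$ymin) %% geom$width)
}

#' Minimal-image distance on the periodic strip
#'
#' Euclidean distance between points with the y-difference taken modulo the
#' strip width (minimal image); the x-direction is not periodic.
#'
#' @param p,q Two-column matrices (or length-2 vectors) of `(x, y)`
#'   positions in micrometres. Recycled row-wise.
#' @param geom A [domain_geometry()].
#' @return Numeric vector of distances (um).
#' @examples
#' geom <- domain_geometry(100, 0, 10)
#' periodic_distance(c(0, 0.5), c(0, 9.5), geom) # wraps: distance 1
#' @export
periodic_distance <- function(p, q, geom) {
  p <- matrix(as.numeric(p), ncol = 2)
  q <- matrix(as.numeric(q), ncol = 2)
  dx <- p[, 1] - q[, 1]
  dy <- p[, 2] - q[, 2]
  W <- geom$width
  dy <- dy - W * round(dy / W)
  sqrt(dx^2 + dy^2)
}

#' Resolve hard-disc overlaps by repulsion descent
#'
#' Cells are hard discs of common radius `R`; configurations produced by cell
#' division overlap, and overlaps are removed by explicit-Euler descent on a
#' short-range pairwise repulsion potential
#' \eqn{\Phi(r) = 2\kappa R^2 (r-1)^2} for \eqn{r = d/2R < 1} (zero
#' otherwise), iterated until the largest pair overlap is below
#' `eps * 2R` (default: a tenth of a cell diameter). The anterior wall is
#' enforced by clamping `x >= 0` after every step and `y` is re-wrapped.
#'
#' @param cells A tibble with numeric columns `x`, `y` (um); other columns
#'   are preserved untouched.
#' @param geom A [domain_geometry()].
#' @param R Cell radius (um).
#' @param kappa Repulsion intensity (arbitrary units; only the fixed point
#'   matters).
#' @param eps Stopping tolerance of the descent as a fraction of the cell
#'   diameter.
#' @param eps_hard Hard invariant: if, after the iteration cap, the
#'   maximum overlap still exceeds `eps_hard * 2R` (a tenth of a diameter
#'   by default — the model's non-overlap criterion), the relaxation
#'   fails. Between `eps` and `eps_hard` the configuration is accepted: a
#'   pressurized packing can balance small residual overlaps against
#'   neighbour forces, which is a force equilibrium, not a failure.
#' @param max_iter Iteration cap of the descent.
#' @param track_energy If `TRUE`, attach the per-iteration total potential
#'   energy as attribute `"energy"` (used by convergence audits).
#' @return The cells tibble with updated `x`, `y`; attributes `"iterations"`
#'   and `"max_overlap"` report the descent, plus `"energy"` if requested.
#' @export
relax_overlaps <- function(cells, geom, R, kappa = 1, eps = 0.1,
                           eps_hard = 0.1, max_iter = 1e5,
                           track_energy = FALSE) {
  stopifnot(kappa > 0, nrow(cells) >= 0)
  if (nrow(cells) == 0) return(cells)
  res <- relax_cpp(cells$x, cells$y, R, kappa, geom$ymin, geom$width,
                   eps, as.integer(max_iter), track_energy, eps_hard)
  if (!res$converged && res$max_overlap >= max(eps_hard, eps) * 2 * R) {
    stop(sprintf(
      "hard-disc relaxation did not converge in %d iterations (max overlap %.3g um, %d cells, density %.3g/um^2)",
      as.integer(max_iter), res$max_overlap, nrow(cells),
      nrow(cells) / (diff(range(cells$x)) * geom$width + pi * R^2)))
  }
  cells$x <- res$x
  cells$y <- res$y
  attr(cells, "iterations") <- res$iterations
  attr(cells, "max_overlap") <- res$max_overlap
  if (track_energy) attr(cells, "energy") <- res$energy
  cells
}

#' Initialize a non-overlapping cell population
#'
#' Throws `n_throw` cell centres uniformly at random into
#' `[0, L0] x [ymin, ymax]`, relaxes the configuration to a hard-disc
#' steady state, and removes every cell whose x-position exceeds `L0`.
#' Cell-cycle state columns are attached by the caller (see
#' [run_simulation()]); this function only handles geometry.
#'
#' @inheritParams relax_overlaps
#' @param n_throw Number of cells thrown before relaxation (`N1` in the
#'   initialization scheme); must exceed the number finally kept.
#' @return A tibble with columns `cell_id`, `x`, `y`.
#' @export
initialize_cells <- function(geom, n_throw, R, kappa = 1, eps = 0.1,
                             max_iter = 1e5) {
  stopifnot(n_throw >= 1)
  area <- geom$L0 * geom$width
  if (n_throw * pi * R^2 > 1.2 * area) {
    stop(sprintf(
      "packing infeasible: %d cells of radius %g in area %g um^2 (density %.2f)",
      n_throw, R, area, n_throw * pi * R^2 / area))
  }
  cells <- tibble::tibble(
    cell_id = seq_len(n_throw),
    x = runif(n_throw, 0, geom$L0),
    y = runif(n_throw, geom$ymin, geom$ymax))
  if (n_throw > 1) cells <- relax_overlaps(cells, geom, R, kappa, eps, max_iter)
  cells <- dplyr::filter(cells, .data$x <= geom$L0)
  cells$cell_id <- seq_len(nrow(cells))
  attr(cells, "iterations") <- NULL
  attr(cells, "max_overlap") <- NULL
  cells
}

#' Identify front cells
#'
#' A cell `i` is a front cell if there is no cell `j` posterior to it
#' (`x_j > x_i`) whose y-coordinate falls within the open band
#' `(y_i - R, y_i + R)`, the band taken with periodic wrap.
#'
#' @inheritParams relax_overlaps
#' @return Logical vector marking front cells.
#' @export
find_front_cells <- function(cells, geom, R) {
  if (nrow(cells) == 0) stop("cannot identify front cells: empty population")
  front_cells_cpp(cells$x, cells$y, R, geom$ymin, geom$width)
}

#' Tissue length from front cells
#'
#' The tissue length `L(t)` is the mean x-coordinate (shifted coordinates)
#' of the front cells.
#'
#' @inheritParams find_front_cells
#' @return Length in micrometres.
#' @export
tissue_length <- function(cells, geom, R) {
  mean(cells$x[find_front_cells(cells, geom, R)])
}
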