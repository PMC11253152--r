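#' Theory parameters for the fast reaction-diffusion limit
#'
#' In the limit of instantaneous diffusion and degradation the signal
#' relaxes at every instant to the steady-state profile
#' \eqn{\rho_s(x) = \rho_0 \sinh(x/\lambda)/\sinh(L/\lambda)} on the
#' current domain `[0, L(t)]`, and the tissue splits into a slow-cycling
#' (non-recruited) anterior zone and a fast-cycling (recruited) posterior
#' zone whose lengths grow exponentially with the Poisson division
#' frequencies.
#'
#' @param lambda Characteristic length \eqn{\lambda = \sqrt{D/k}} (um);
#'   must be smaller than `L0`.
#' @param rho0 Signal density at the posterior front.
#' @param rhos_min Recruitment threshold density; must not exceed `rho0`.
#' @param nu_slow,nu_fast Division frequencies (per hour), fast > slow.
#' @param L0 Initial tissue length (um).
#' @return An object of class `theory_params`.
#' @export
theory_params <- function(lambda, rho0 = 40, rhos_min = 3,
                          nu_slow = log(2) / 340, nu_fast = log(2) / 119,
                          L0 = 1000) {
  stopifnot(lambda > 0, rho0 > 0, rhos_min > 0, L0 > 0, nu_fast > nu_slow)
  if (lambda >= L0) stop("the theory requires lambda < L0")
  if (rhos_min > rho0) {
    stop("rhos_min > rho0: the threshold exceeds the source density and no cell is ever recruited")
  }
  structure(list(lambda = lambda, rho0 = rho0, rhos_min = rhos_min,
                 nu_slow = nu_slow, nu_fast = nu_fast, L0 = L0),
            class = "theory_params")
}

#' Characteristic length of a reaction-diffusion signal
#'
#' \eqn{\lambda = \sqrt{D/k}}: the distance over which an exponentially
#' decaying profile falls to 1/e of its source value. Inputs are taken in
#' the units the biology is quoted in (`D` in um^2/s, `k` per day) and
#' converted to a consistent system before the square root.
#'
#' @param D Diffusion coefficient (um^2 per second).
#' @param k Degradation rate (per day).
#' @return Characteristic length in micrometres.
#' @examples
#' characteristic_length(D = 0.08, k = 0.1) # ~263 um
#' @export
characteristic_length <- function(D, k) {
  stopifnot(D > 0, k > 0)
  sqrt((D * 86400) / k)
}

# log(sinh(a)) computed without overflow
log_sinh <- function(a) a + log1p(-exp(-2 * a)) - log(2)

# stable sinh(x/lam)/sinh(L/lam) for possibly huge arguments
sinh_ratio <- function(x, L, lambda) {
  a <- x / lambda
  b <- L / lambda
  out <- numeric(length(a))
  zero <- a <= 0
  out[zero] <- 0
  i <- !zero
  out[i] <- exp((a[i] - b) + log1p(-exp(-2 * a[i])) - log1p(-exp(-2 * b)))
  out
}

#' Steady-state signal profile
#'
#' \eqn{\rho_s(x) = \rho_0 \sinh(x/\lambda) / \sinh(L/\lambda)} on
#' `[0, L]`: zero at the absorbing anterior wall, `rho0` at the front,
#' strictly increasing in between. Evaluated through exponential-shifted
#' logs so that `L/lambda` of order 100 does not overflow.
#'
#' @param x Positions in shifted coordinates (um), `0 <= x <= L`.
#' @param L Tissue length (um).
#' @param lambda Characteristic length (um).
#' @param rho0 Front density.
#' @return Densities in `[0, rho0]`.
#' @export
steady_state_profile <- function(x, L, lambda, rho0) {
  stopifnot(lambda > 0, L > 0)
  rho0 * sinh_ratio(x, L, lambda)
}

# stable lambda * asinh(r * sinh(L/lambda))
stable_xstar <- function(L, lambda, r) {
  log_z <- log(r) + log_sinh(L / lambda)
  if (log_z > 30) {
    lambda * (log_z + log(2))
  } else {
    lambda * asinh(exp(log_z))
  }
}

#' Recruitment position on a tissue of length L
#'
#' The position \eqn{x^*} at which the steady-state profile crosses the
#' recruitment threshold:
#' \eqn{x^*(L) = \lambda\,\mathrm{asinh}\!\big(\tfrac{\rho_s^{min}}{\rho_0}
#' \sinh(L/\lambda)\big)}. Cells posterior to \eqn{x^*} see
#' supra-threshold signal.
#'
#' @param L Tissue length (um); vectorized.
#' @param params A [theory_params()].
#' @return Positions `x*` in `[0, L]` (shifted coordinates).
#' @export
recruitment_position <- function(L, params) {
  r <- params$rhos_min / params$rho0
  vapply(L, stable_xstar, numeric(1), lambda = params$lambda, r = r)
}

#' Initial recruitment limit (amputation-plane coordinates)
#'
#' \eqn{\xi(0) = x^*(L_0) - L_0 \in [-L_0, 0]}: the anterior extent of the
#' initially recruited zone, negative of the amputation plane. Equal to 0
#' when the threshold equals the source density, and tending to 0 as
#' \eqn{\lambda \to 0}.
#'
#' @param params A [theory_params()].
#' @return `xi(0)` in micrometres (non-positive).
#' @export
xi0 <- function(params) {
  recruitment_position(params$L0, params) - params$L0
}

#' Closed-form zone lengths under the fast-diffusion theory
#'
#' \eqn{L_f(t) = -\xi(0) e^{\nu_F t}} (recruited zone) and
#' \eqn{L_s(t) = (\xi(0)+L_0) e^{\nu_S t}} (non-recruited zone), valid when
#' the recruitment position stays inside the recruited zone (see
#' [proposition1_condition()]).
#'
#' @param t Times in hours (vectorized).
#' @param params A [theory_params()].
#' @return A tibble with columns `t`, `Ls`, `Lf`, `L`, `outgrowth`.
#' @export
population_lengths <- function(t, params) {
  x0 <- xi0(params)
  Ls <- (x0 + params$L0) * exp(params$nu_slow * t)
  Lf <- -x0 * exp(params$nu_fast * t)
  tibble::tibble(t = t, Ls = Ls, Lf = Lf, L = Ls + Lf,
                 outgrowth = Ls + Lf - params$L0)
}

#' Theoretical outgrowth
#'
#' `Outgrowth(t) = Ls(t) + Lf(t) - L0`; zero at `t = 0` and strictly
#' increasing for positive division frequencies.
#'
#' @inheritParams population_lengths
#' @return Outgrowth in micrometres.
#' @export
theory_outgrowth <- function(t, params) {
  population_lengths(t, params)$outgrowth
}

#' Theoretical recruitment limit curve
#'
#' The recruitment limit is the anterior-posterior position of the most
#' anteriorly recruited cell, in amputation-plane coordinates. Which
#' closed-form expression describes it depends on the regime: when the
#' initial condition satisfies [proposition1_condition()], the threshold
#' position \eqn{x^*(t)} stays inside the already-recruited zone, no cell
#' is recruited after the initial instant, and the limit is the moving
#' slow/fast boundary \eqn{L_s(t) - L_0} (`"boundary"`); otherwise
#' recruitment is ongoing and the limit tracks the threshold crossing
#' \eqn{x^*(L(t)) - L_0} (`"threshold"`). Both coincide at `t = 0` with
#' \eqn{\xi(0)}.
#'
#' @inheritParams population_lengths
#' @param regime `"auto"` (decide by the Proposition-1 condition),
#'   `"boundary"`, or `"threshold"`.
#' @return A tibble with columns `t` (hours), `xi` (um).
#' @export
theory_recruitment_limit <- function(t, params,
                                     regime = c("auto", "boundary",
                                                "threshold")) {
  regime <- match.arg(regime)
  if (regime == "auto") {
    regime <- if (proposition1_condition(params)) "boundary" else "threshold"
  }
  pl <- population_lengths(t, params)
  xi <- if (regime == "boundary") {
    pl$Ls - params$L0
  } else {
    recruitment_position(pl$L, params) - params$L0
  }
  tibble::tibble(t = t, xi = xi)
}

#' Condition for the recruitment zone to stay recruited
#'
#' The closed-form zone lengths are exact when
#' \deqn{\nu_F L_F(0) > \nu_S L_S(0)
#'   \frac{\sqrt{(\rho_0/\rho_s^{min})^2 - 1}}{\cosh(L_0/\lambda)},}
#' in which case the recruitment position satisfies
#' \eqn{x^*(t) > L_s(t)} for all `t > 0` and no new cell is ever recruited
#' after the initial instant.
#'
#' @param params A [theory_params()].
#' @param Ls0,Lf0 Initial zone lengths (um); default to the theory's own
#'   initial split from `xi(0)`.
#' @return `TRUE` iff the (strict) inequality holds.
#' @export
proposition1_condition <- function(params, Ls0 = NULL, Lf0 = NULL) {
  x0 <- xi0(params)
  if (is.null(Ls0)) Ls0 <- x0 + params$L0
  if (is.null(Lf0)) Lf0 <- -x0
  ratio2 <- (params$rho0 / params$rhos_min)^2 - 1
  if (ratio2 < 0) stop("rhos_min > rho0: condition undefined")
  a <- params$L0 / params$lambda
  log_cosh <- a + log1p(exp(-2 * a)) - log(2)
  lhs <- log(params$nu_fast) + log(Lf0)
  if (params$nu_slow == 0 || Ls0 == 0 || ratio2 == 0) return(Lf0 > 0)
  rhs <- log(params$nu_slow) + log(Ls0) + 0.5 * log(ratio2) - log_cosh
  lhs > rhs
}

#' Integrate the zone-growth ODE
#'
#' Fixed-step RK4 integration of the growth law
#' \eqn{L_s' = \nu_S L_s}, \eqn{L_f' = \nu_F L_f} (so
#' \eqn{L' = \nu_S L_s + \nu_F L_f}), with, after every step, a projection
#' transferring the slow-zone excess beyond the recruitment position into
#' the recruited zone. When [proposition1_condition()] holds the projection
#' never fires and the trajectories coincide with the closed forms.
#'
#' @param params A [theory_params()].
#' @param t_end End time (hours).
#' @param dt Step (hours); default 0.24 h (0.01 day).
#' @param Ls0,Lf0 Initial zone lengths (um); default to the theory's split.
#' @return A tibble with columns `t`, `Ls`, `Lf`, `L`, `xstar`.
#' @export
integrate_growth_ode <- function(params, t_end, dt = 0.24,
                                 Ls0 = NULL, Lf0 = NULL) {
  stopifnot(t_end > 0, dt > 0)
  if (dt > 0.05 / params$nu_fast) {
    stop("ODE step too large relative to 1/nu_fast")
  }
  x0 <- xi0(params)
  if (is.null(Ls0)) Ls0 <- x0 + params$L0
  if (is.null(Lf0)) Lf0 <- -x0
  n <- ceiling(t_end / dt)
  ts <- seq(0, by = dt, length.out = n + 1)
  Ls <- numeric(n + 1)
  Lf <- numeric(n + 1)
  Ls[1] <- Ls0
  Lf[1] <- Lf0
  for (i in seq_len(n)) {
    s <- Ls[i]; f <- Lf[i]
    # linear ODE: RK4 on each component
    rk <- function(v, nu) {
      k1 <- nu * v
      k2 <- nu * (v + dt / 2 * k1)
      k3 <- nu * (v + dt / 2 * k2)
      k4 <- nu * (v + dt * k3)
      v + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    s2 <- rk(s, params$nu_slow)
    f2 <- rk(f, params$nu_fast)
    xs <- recruitment_position(s2 + f2, params)
    if (s2 > xs) { # recruitment eats into the slow zone
      f2 <- f2 + (s2 - xs)
      s2 <- xs
    }
    Ls[i + 1] <- s2
    Lf[i + 1] <- f2
  }
  L <- Ls + Lf
  tibble::tibble(t = ts, Ls = Ls, Lf = Lf, L = L,
                 xstar = recruitment_position(L, params))
}
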