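#' Ideal active-gas swim pressure
#'
#' The swim pressure of a dilute 2D run-and-tumble gas with no torque
#' interactions: `gamma * rho * v^2 * tau / 2`.
#'
#' @param rho number density
#' @param v self-propulsion speed
#' @param tau persistence time (inverse tumbling rate)
#' @param gamma translational drag
#' @return pressure (force per unit length in reduced units)
#' @export
ideal_swim_pressure <- function(rho, v, tau, gamma = 1) {
  stopifnot(rho >= 0, v >= 0, tau >= 0, gamma >= 0)
  gamma * rho * v^2 * tau / 2
}

#' Ideal-gas steady density profile
#'
#' For a non-interacting run-and-tumble gas in a spatially varying speed
#' field the stationary density satisfies `rho(r) v(r) = const`; the
#' constant is fixed by conservation of the total number over the box.
#' Exact for the ideal gas (the stationary one-particle distribution
#' `P(r, theta) propto 1/v(r)` solves the kinetic equation pointwise).
#'
#' @param pattern a [speed_pattern()]
#' @param rho_mean box-averaged number density
#' @param L box side
#' @param bin grid bin side
#' @return a [field_map()] with the predicted density
#' @export
steady_density_profile <- function(pattern, rho_mean, L, bin = 1) {
  stopifnot(rho_mean >= 0, L > 0)
  nbins <- resolve_grid(L, bin)
  g <- (seq_len(nbins) - 0.5) * bin
  pts <- as.matrix(expand.grid(x = g, y = g))
  v <- speed_at(pattern, pts, L)
  if (any(v == 0))
    stop("steady_density_profile: zero speed region; profile undefined")
  inv <- matrix(1 / v, nbins, nbins)
  vals <- rho_mean * inv / mean(inv)
  field_map(vals, bin, L, 1, "rho_ideal")
}

#' Bead interaction time scale
#'
#' The typical duration of a swimmer-bead encounter, `a / v`: the time a
#' swimmer moving at speed `v` takes to slide past a bead of radius `a`.
#' When this is shorter than the persistence time it, rather than `tau`,
#' controls the effective swim pressure on the bead.
#'
#' @param a bead radius
#' @param v swimming speed (> 0)
#' @return time in reduced units
#' @export
interaction_time_scale <- function(a, v) {
  stopifnot(a >= 0, v > 0)
  a / v
}
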