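#' Rod (swimmer) parameters
#'
#' Parameters of the run-and-tumble spherocylindrical rods in reduced units.
#' The reference parameter set is `ell = 1`, `sigma = 1/2`, `alpha = 0.1`
#' (persistence time `tau = 10`), `gamma = 1`. A rod is a spherocylinder of
#' tip-to-tip length `ell` and thickness `sigma`: a straight shaft of length
#' `ell - sigma` with hemispherical caps of diameter `sigma`, so the rod
#' cross-section area is `(ell - sigma) * sigma + pi * sigma^2 / 4`.
#'
#' @param ell rod length (tip to tip); must exceed `sigma`
#' @param sigma rod thickness (contact diameter)
#' @param alpha tumbling rate; the persistence time is `tau = 1/alpha`
#' @param gamma translational drag coefficient along the propulsion direction
#' @param gamma_rot rotational drag; default is the slender-body-like scaling
#'   `gamma * ell^2 / 12`
#' @param k_rep stiffness of the harmonic overlap repulsion
#' @return object of class `rod_params`
#' @export
rod_params <- function(ell = 1, sigma = 0.5, alpha = 0.1, gamma = 1,
                       gamma_rot = gamma * ell^2 / 12, k_rep = 100) {
  stopifnot(ell > 0, sigma > 0, ell > sigma, alpha >= 0, gamma > 0,
            gamma_rot > 0, k_rep > 0)
  structure(list(ell = ell, sigma = sigma, shaft = ell - sigma,
                 alpha = alpha,
                 tau = if (alpha > 0) 1 / alpha else Inf,
                 gamma = gamma, gamma_rot = gamma_rot, k_rep = k_rep),
            class = "rod_params")
}

#' Rod cross-section area
#'
#' Area of one spherocylinder (shaft `(ell - sigma) x sigma` plus the two
#' circular caps), used to convert between swimmer count and area packing
#' fraction.
#'
#' @param params a [rod_params()]
#' @return area in reduced units
#' @export
rod_area <- function(params) {
  params$shaft * params$sigma + pi * params$sigma^2 / 4
}

#' Passive colloidal bead
#'
#' @param a bead radius
#' @param center length-2 centre; `NULL` places it at the box centre when the
#'   simulation is set up
#' @param gamma_bead translational drag. The default `16 a` (reduced units,
#'   `gamma = ell = 1`) combines the bulk Stokes drag ratio of a sphere of
#'   radius `a` to a length-1 rod (about `8 a`) with a factor ~2 for the
#'   near-wall enhancement of a sedimented sphere in a shallow chamber; the
#'   bead drag only sets the drift-speed scale (fields and drift direction
#'   are insensitive to it) and this value reproduces the observed drift
#'   scale of about 1 percent of the fast swimming speed
#' @param mobile if `FALSE` the bead is held fixed (pressure-measurement
#'   protocol); if `TRUE` it moves under the contact forces (drift protocol)
#' @return object of class `bead_spec`
#' @export
bead_spec <- function(a = 2.5, center = NULL, gamma_bead = 16 * a,
                      mobile = TRUE) {
  stopifnot(a > 0, gamma_bead > 0, is.logical(mobile))
  if (!is.null(center)) stopifnot(length(center) == 2, all(is.finite(center)))
  structure(list(a = a, center = center, gamma_bead = gamma_bead,
                 mobile = mobile),
            class = "bead_spec")
}

#' Simulation configuration
#'
#' Square periodic box of side `L` containing `N` rods at area packing
#' fraction `phi = N * A_rod / L^2`. Exactly one of `N` and `phi` must be
#' given; the other is derived.
#'
#' @param L box side
#' @param phi area packing fraction (exclusive with `N`)
#' @param N swimmer count (exclusive with `phi`)
#' @param dt integration time step
#' @param n_steps number of steps
#' @param save_every frame-saving cadence (steps)
#' @param feedback_every cadence (steps) of the disc-follows-bead feedback;
#'   0 disables feedback (static pattern)
#' @param interactions_on if `FALSE`, rod-rod forces are dropped while
#'   rod-bead repulsion is kept, so the bead stays impenetrable
#' @param transient_fraction fraction of frames discarded as transient by the
#'   analysis stages
#' @param rod a [rod_params()] used to resolve `phi <-> N`
#' @return object of class `sim_config`
#' @export
sim_config <- function(L, phi = NULL, N = NULL, dt = 2e-3, n_steps = 1000L,
                       save_every = 100L, feedback_every = 1L,
                       interactions_on = TRUE, transient_fraction = 0.2,
                       rod = rod_params()) {
  stopifnot(L > 0, dt > 0, n_steps >= 0, save_every >= 1,
            feedback_every >= 0, is.logical(interactions_on),
            transient_fraction >= 0, transient_fraction < 1)
  if (is.null(phi) == is.null(N))
    stop("sim_config: give exactly one of phi and N")
  A <- rod_area(rod)
  if (is.null(N)) {
    stopifnot(phi >= 0, phi <= 0.6)
    N <- as.integer(round(phi * L^2 / A))
  }
  N <- as.integer(N)
  stopifnot(N >= 0)
  phi <- N * A / L^2
  structure(list(L = L, N = N, phi = phi, dt = dt,
                 n_steps = as.integer(n_steps),
                 save_every = as.integer(save_every),
                 feedback_every = as.integer(feedback_every),
                 interactions_on = interactions_on,
                 transient_fraction = transient_fraction),
            class = "sim_config")
}

#' Reference simulation geometry
#'
#' The disc geometry used throughout: bead radius `a`, disc radius `R = 8 a`,
#' box side `L`. The `"full"` geometry matches the experimental aspect ratio
#' (`a = 2.5`, `R = 20`, `L = 60`); the `"reduced"` geometry halves all
#' lengths (`a = 1.25`, `R = 10`, `L = 30`) and is the scale used by the
#' shipped analyses and acceptance checks so that ensembles of runs complete
#' on a single CPU.
#'
#' @param scale `"reduced"` or `"full"`
#' @return list with `L`, `a`, `R`
#' @export
reference_geometry <- function(scale = c("reduced", "full")) {
  scale <- match.arg(scale)
  if (scale == "full") list(L = 60, a = 2.5, R = 20)
  else list(L = 30, a = 1.25, R = 10)
}

#' Map packing fraction to optical density
#'
#' Linear experimental calibration anchored at packing fraction 0.38 being
#' equivalent to optical density 13.5 (and 0 to 0). Plot metadata only.
#'
#' @param phi area packing fraction
#' @return optical density
#' @export
phi_to_od <- function(phi) phi * 13.5 / 0.38
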