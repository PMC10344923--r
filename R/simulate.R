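#' Place rods without overlaps
#'
#' Random sequential insertion with rejection: candidate positions and
#' orientations are drawn uniformly and accepted when the new rod overlaps
#' neither previously placed rods nor the bead. Above packing fraction 0.4
#' (or whenever insertion stalls) placement falls back to an aligned lattice,
#' which is overlap-free by construction; lattice angles are then randomised
#' by the tumbling dynamics within a few persistence times, well inside the
#' discarded transient.
#'
#' @param config a [sim_config()]
#' @param rod a [rod_params()]
#' @param bead a [bead_spec()] or `NULL`
#' @param contact_scale rod-rod contact distance used during insertion, as a
#'   fraction of `sigma`; values below 1 permit slight initial overlaps
#' @return list with `positions` (N x 2), `angles` (length N) and `method`
#' @export
initialize_rods <- function(config, rod = rod_params(), bead = NULL,
                            contact_scale = 1) {
  N <- config$N
  L <- config$L
  if (config$phi > 0.6)
    stop(sprintf("initialize_rods: packing fraction %.3f exceeds 0.6", config$phi))
  if (N == 0)
    return(list(positions = matrix(numeric(0), 0, 2), angles = numeric(0),
                method = "empty"))
  bp <- !is.null(bead)
  bc <- if (bp) bead_center_or_default(bead, L) else c(0, 0)
  if (config$phi <= 0.4) {
    res <- place_rods_cpp(N, L, rod$shaft, rod$sigma, contact_scale, bp,
                          bc[1], bc[2], if (bp) bead$a else 0, 20000L)
    if (isTRUE(res$ok))
      return(list(positions = res$positions, angles = res$angles,
                  method = "rsa"))
  }
  lattice_place(N, L, rod, bead = if (bp) bead else NULL, bc = bc,
                phi = config$phi)
}

bead_center_or_default <- function(bead, L) {
  if (is.null(bead$center)) c(L / 2, L / 2) else bead$center
}

# aligned lattice placement; overlap-free for any phi the cell grid can hold
lattice_place <- function(N, L, rod, bead, bc, phi) {
  sx <- rod$ell + 0.05
  sy <- rod$sigma + 0.05
  nx <- floor(L / sx)
  ny <- floor(L / sy)
  xs <- (seq_len(nx) - 0.5) * (L / nx)
  ys <- (seq_len(ny) - 0.5) * (L / ny)
  g <- expand.grid(x = xs, y = ys)
  if (!is.null(bead)) {
    dx <- g$x - bc[1]; dx <- dx - L * round(dx / L)
    dy <- g$y - bc[2]; dy <- dy - L * round(dy / L)
    clear <- bead$a + rod$sigma / 2 + rod$shaft / 2 + 0.05
    g <- g[dx^2 + dy^2 > clear^2, , drop = FALSE]
  }
  if (nrow(g) < N)
    stop(sprintf(
      "initialize_rods: cannot place %d rods at phi = %.3f (lattice capacity %d)",
      N, phi, nrow(g)))
  keep <- sample.int(nrow(g), N)
  list(positions = cbind(g$x[keep], g$y[keep]), angles = rep(0, N),
       method = "lattice")
}

#' Pairwise steric force between two rods
#'
#' Harmonic overlap repulsion along the minimum-distance vector between the
#' rod shafts, applied at the closest-approach points so that the matching
#' torques are generated; Newton's third law holds exactly. Force is zero
#' beyond the contact distance `sigma`.
#'
#' @param r_i,r_j rod centres (length-2, minimum image is applied)
#' @param theta_i,theta_j rod orientations (radians)
#' @param rod a [rod_params()]
#' @param L box side
#' @param idx indices of the two rods, used only to seed the deterministic
#'   fallback direction when the closest points coincide
#' @return list with `f_i`, `tau_i`, `f_j`, `tau_j`, `virial`, `contact`
#' @export
pair_force <- function(r_i, theta_i, r_j, theta_j, rod = rod_params(), L,
                       idx = c(0L, 1L)) {
  pair_force_rr_cpp(r_i, theta_i, r_j, theta_j, rod$shaft, rod$sigma,
                    rod$k_rep, L, idx[1], idx[2])
}

#' Steric force between a rod and the bead
#'
#' @param r_i rod centre; `theta_i` its orientation
#' @param theta_i rod orientation (radians)
#' @param bead_center bead centre (length-2)
#' @param a bead radius
#' @param rod a [rod_params()]
#' @param L box side
#' @return list with `f_i`, `tau_i`, `f_bead`, `virial`, `contact`
#' @export
pair_force_bead <- function(r_i, theta_i, bead_center, a,
                            rod = rod_params(), L) {
  pair_force_rb_cpp(r_i, theta_i, bead_center, a, rod$shaft, rod$sigma,
                    rod$k_rep, L)
}

#' Pair potentials (for numerical-gradient checks)
#'
#' The harmonic overlap potentials whose negative gradients are
#' [pair_force()] and [pair_force_bead()].
#'
#' @inheritParams pair_force
#' @return potential energy (scalar)
#' @export
pair_potential <- function(r_i, theta_i, r_j, theta_j, rod = rod_params(), L) {
  pair_potential_rr_cpp(r_i, theta_i, r_j, theta_j, rod$shaft, rod$sigma,
                        rod$k_rep, L)
}

#' @rdname pair_potential
#' @inheritParams pair_force_bead
#' @export
pair_potential_bead <- function(r_i, theta_i, bead_center, a,
                                rod = rod_params(), L) {
  pair_potential_rb_cpp(r_i, theta_i, bead_center, a, rod$shaft, rod$sigma,
                        rod$k_rep, L)
}

#' Apply tumbling events to a set of orientations
#'
#' Each rod independently tumbles with probability `1 - exp(-alpha * dt)`;
#' a tumbling rod's orientation is resampled uniformly on `[0, 2 pi)`.
#'
#' @param angles numeric vector of orientations
#' @param alpha tumbling rate
#' @param dt time step
#' @return updated orientation vector
#' @export
tumble_events <- function(angles, alpha, dt) {
  stopifnot(alpha >= 0, dt > 0)
  if (alpha == 0) return(angles)
  p <- 1 - exp(-alpha * dt)
  hit <- stats::runif(length(angles)) < p
  angles[hit] <- stats::runif(sum(hit), 0, 2 * pi)
  angles
}

#' Run one simulation
#'
#' Integrates the overdamped dynamics of `config$N` run-and-tumble rods (and
#' optionally one passive bead) forward by `config$n_steps` Euler steps of
#' size `config$dt`, saving a frame every `config$save_every` steps. The
#' swimming speed of each rod is evaluated at its centre from `pattern`; the
#' modulation disc follows the bead at the `feedback_every` cadence. All
#' randomness (placement and tumbling) is drawn from the R RNG, so
#' `set.seed(seed)` makes runs bitwise reproducible.
#'
#' @param config a [sim_config()]
#' @param rod a [rod_params()]
#' @param bead a [bead_spec()] or `NULL` for a pure bath
#' @param pattern a [speed_pattern()]; for disc patterns the disc centre is
#'   initialised from the bead and `delta` unless `feedback_every = 0`
#' @param seed integer seed; `NULL` leaves the RNG state untouched
#' @param init optional list with `positions` and `angles` to start from
#'   (bypasses placement)
#' @param contact_scale passed to [initialize_rods()]
#' @return an `rt_traj` object: saved times, rod positions (N x 2 x frames),
#'   angles (N x frames), bead and disc tracks, the instantaneous rod-to-bead
#'   force at each saved frame, and the run metadata
#' @export
simulate_run <- function(config, rod = rod_params(), bead = NULL,
                         pattern, seed = NULL, init = NULL,
                         contact_scale = 1) {
  stopifnot(inherits(config, "sim_config"), inherits(rod, "rod_params"),
            inherits(pattern, "speed_pattern"))
  v_max <- max(pattern$v_minus, pattern$v_plus, pattern$v_zero)
  if (config$dt * v_max >= rod$sigma / 10)
    stop(sprintf("simulate_run: dt * v_max = %.3g violates the stability bound sigma/10 = %.3g",
                 config$dt * v_max, rod$sigma / 10))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init))
    init <- initialize_rods(config, rod, bead, contact_scale = contact_scale)

  bp <- !is.null(bead)
  bc <- if (bp) bead_center_or_default(bead, config$L) else c(0, 0)
  if (pattern$type == "disc" && bp && config$feedback_every > 0)
    pattern <- update_disc(pattern, bc, config$L)

  res <- rt_engine_cpp(
    init$positions, init$angles,
    rod = unclass(rod),
    beadL = list(present = bp, x = bc[1], y = bc[2],
                 a = if (bp) bead$a else 0,
                 gamma_bead = if (bp) bead$gamma_bead else 1,
                 mobile = bp && bead$mobile),
    pat = list(ptype = pattern_type_code(pattern),
               v_minus = pattern$v_minus, v_plus = pattern$v_plus,
               v_zero = pattern$v_zero, R = pattern$R,
               delta = pattern$delta, ax = pattern$axis[1],
               ay = pattern$axis[2], dcx = pattern$disc_center[1],
               dcy = pattern$disc_center[2]),
    runc = list(L = config$L, dt = config$dt, n_steps = config$n_steps,
                save_every = config$save_every,
                feedback_every = config$feedback_every,
                interactions_on = config$interactions_on))

  structure(
    list(times = res$times, positions = res$positions, angles = res$angles,
         bead = if (bp) res$bead else NULL,
         bead_unwrapped = if (bp) res$bead_unwrapped else NULL,
         disc = res$disc, bead_force = if (bp) res$bead_force else NULL,
         n_frames = res$n_frames, config = config, rod = rod,
         bead_spec = if (bp) bead else NULL, pattern = pattern,
         seed = seed, placement = init$method, format_version = 1L),
    class = "rt_traj")
}

#' @export
print.rt_traj <- function(x, ...) {
  cat(sprintf(
    "rt_traj: %d rods, %d frames (t = 0..%.4g), L = %.4g, phi = %.3f%s\n",
    x$config$N, x$n_frames, max(x$times), x$config$L, x$config$phi,
    if (!is.null(x$bead)) sprintf(", bead a = %.3g (%s)", x$bead_spec$a,
                                  if (x$bead_spec$mobile) "mobile" else "fixed")
    else ""))
  invisible(x)
}

#' Frame indices after the transient
#'
#' @param traj an `rt_traj`
#' @param transient_fraction fraction of frames discarded from the start;
#'   defaults to the value stored in the trajectory's configuration
#' @return integer vector of frame indices
#' @export
post_transient_frames <- function(traj, transient_fraction = NULL) {
  if (is.null(transient_fraction))
    transient_fraction <- traj$config$transient_fraction
  stopifnot(transient_fraction >= 0, transient_fraction < 1)
  nf <- traj$n_frames
  first <- floor(transient_fraction * nf) + 1
  if (first > nf) stop("post_transient_frames: no frames left after transient")
  seq.int(first, nf)
}
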