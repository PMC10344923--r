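#' Passive repulsive-rod fixture
#'
#' A small box of passive (`v = 0`) repulsive rods inserted with slight
#' initial overlaps and recorded while they relax, so the frames carry
#' non-zero contact virials. Used as the test bed for the virial
#' pressure-map estimator against the brute-force global oracle.
#' Deterministic given `seed`.
#'
#' @param n rod count (<= 50)
#' @param L box side
#' @param seed integer seed
#' @param n_steps relaxation steps recorded
#' @param rod a [rod_params()]
#' @return an `rt_traj`
#' @export
make_passive_gas <- function(n, L = 10, seed = 1, n_steps = 200L,
                             rod = rod_params(alpha = 0)) {
  stopifnot(n <= 50)
  cfg <- sim_config(L = L, N = n, dt = 5e-3, n_steps = n_steps,
                    save_every = 10L, feedback_every = 0L,
                    transient_fraction = 0, rod = rod)
  pat <- speed_pattern(0, 0, 0, type = "uniform")
  simulate_run(cfg, rod, bead = NULL, pattern = pat, seed = seed,
               contact_scale = 0.7)
}

#' Step-profile ideal-gas fixture
#'
#' A non-interacting run-and-tumble gas in a half/half box: speed `v_left`
#' for `x < L/2` and `v_right` for `x >= L/2`. In the steady state the
#' density in each half satisfies `rho v = const`.
#'
#' @param n swimmer count
#' @param v_left,v_right region speeds
#' @param L box side
#' @param seed integer seed
#' @param n_steps steps
#' @param dt time step
#' @param alpha tumbling rate
#' @param save_every frame cadence
#' @return an `rt_traj`
#' @export
make_step_profile_gas <- function(n, v_left, v_right, L = 40, seed = 1,
                                  n_steps = 60000L, dt = 0.01,
                                  alpha = 0.1, save_every = 100L) {
  rod <- rod_params(alpha = alpha)
  cfg <- sim_config(L = L, N = n, dt = dt, n_steps = n_steps,
                    save_every = save_every, feedback_every = 0L,
                    interactions_on = FALSE, rod = rod)
  # for step patterns v_minus/v_plus are simply the left/right speeds
  pat <- speed_pattern(v_left, v_right, v_zero = max(v_left, v_right),
                       type = "step")
  simulate_run(cfg, rod, bead = NULL, pattern = pat, seed = seed)
}

#' Half-box mean densities of a step-profile run
#'
#' Mean number density in the left and right halves over the post-transient
#' frames, excluding a boundary shell around the two interfaces (the one at
#' `L/2` and the periodic one at `0`).
#'
#' @param traj an `rt_traj` from [make_step_profile_gas()]
#' @param shell excluded shell half-width
#' @param transient_fraction overrides the stored transient
#' @param n_blocks number of time blocks for the standard errors (block
#'   averaging absorbs the frame-to-frame autocorrelation)
#' @return list with `rho_left`, `rho_right`, `sem_left`, `sem_right`
#'   (block-averaged standard errors)
#' @export
step_profile_densities <- function(traj, shell = 1,
                                   transient_fraction = NULL,
                                   n_blocks = 10) {
  frames <- post_transient_frames(traj, transient_fraction)
  L <- traj$config$L
  area <- (L / 2 - 2 * shell) * L
  nl <- nr <- numeric(length(frames))
  for (k in seq_along(frames)) {
    x <- traj$positions[, 1, frames[k]]
    nl[k] <- sum(x > shell & x < L / 2 - shell)
    nr[k] <- sum(x > L / 2 + shell & x < L - shell)
  }
  blk <- cut(seq_along(frames), n_blocks, labels = FALSE)
  bl <- tapply(nl, blk, mean)
  br <- tapply(nr, blk, mean)
  list(rho_left = mean(nl) / area, rho_right = mean(nr) / area,
       sem_left = stats::sd(bl) / sqrt(n_blocks) / area,
       sem_right = stats::sd(br) / sqrt(n_blocks) / area)
}

#' Synthetic drifting-bead tracks
#'
#' Straight-line drift along x plus independent Gaussian jitter per frame;
#' used for parameter-recovery tests of the drift estimator. The box is
#' made large enough that no wrapping occurs.
#'
#' @param v_true true drift speed
#' @param noise_sd per-frame Gaussian jitter
#' @param n_runs number of tracks
#' @param n_frames frames per track
#' @param dt_frame time between frames
#' @param seed integer seed
#' @return list of bead-only `rt_traj` objects
#' @export
make_drift_synthetic <- function(v_true, noise_sd, n_runs, n_frames = 200L,
                                 dt_frame = 1, seed = 1) {
  set.seed(seed)
  t <- (seq_len(n_frames) - 1) * dt_frame
  span <- abs(v_true) * max(t) + 10 * noise_sd + 10
  L <- max(1e6, 100 * span)
  lapply(seq_len(n_runs), function(r) {
    x <- L / 2 + v_true * t + stats::rnorm(n_frames, 0, noise_sd)
    y <- L / 2 + stats::rnorm(n_frames, 0, noise_sd)
    structure(
      list(times = t, positions = NULL, angles = NULL,
           bead = rbind(x, y), n_frames = n_frames,
           config = list(L = L, transient_fraction = 0),
           pattern = list(axis = c(1, 0)),
           format_version = 1L),
      class = "rt_traj")
  })
}

#' Flat-wall ideal-gas fixture
#'
#' Non-interacting run-and-tumble point swimmers confined between two flat
#' harmonic walls (periodic in y). The walls exert purely normal forces, so
#' no torques reorient the swimmers and the measured mechanical pressure on
#' either wall equals the ideal swim pressure `gamma rho v^2 tau / 2` of the
#' bulk gas. Wall forces are accumulated every step after a burn-in.
#'
#' @param rho bulk-targeted mean number density (count over box area)
#' @param v swimming speed
#' @param tau persistence time
#' @param Lx,Ly box extents (x confined, y periodic)
#' @param seed integer seed
#' @param n_steps steps
#' @param dt time step
#' @param k_wall wall stiffness
#' @param measure_frac fraction of the run discarded before measuring
#' @return list with `pressure` (mean of the two walls), `pressure_right`,
#'   `pressure_left`, `rho_bulk` (measured in the middle third), `times`,
#'   `positions`, `angles`, and the generation parameters
#' @export
make_flat_wall_gas <- function(rho, v, tau, Lx = 60, Ly = 20, seed = 1,
                               n_steps = 150000L, dt = 0.01, k_wall = 100,
                               measure_frac = 0.25) {
  stopifnot(rho >= 0, v >= 0, tau > 0)
  set.seed(seed)
  n <- max(1L, round(rho * Lx * Ly))
  pos0 <- cbind(stats::runif(n, 0, Lx), stats::runif(n, 0, Ly))
  ang0 <- stats::runif(n, 0, 2 * pi)
  res <- wall_gas_cpp(pos0, ang0, Lx, Ly, v, 1 / tau, 1, dt,
                      as.integer(n_steps), k_wall, 1000L, measure_frac)
  nf <- length(res$times)
  first <- floor(measure_frac * nf) + 1
  mid <- 0
  for (f in seq.int(first, nf)) {
    x <- res$positions[, 1, f]
    mid <- mid + sum(x > Lx / 3 & x < 2 * Lx / 3)
  }
  rho_bulk <- mid / ((nf - first + 1) * (Lx / 3) * Ly)
  list(pressure = (res$pressure_right + res$pressure_left) / 2,
       pressure_right = res$pressure_right,
       pressure_left = res$pressure_left,
       rho_bulk = rho_bulk, times = res$times,
       positions = res$positions, angles = res$angles,
       params = list(rho = rho, v = v, tau = tau, Lx = Lx, Ly = Ly,
                     seed = seed, n = n))
}
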