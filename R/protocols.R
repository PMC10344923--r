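#' Reference pressure-measurement protocol
#'
#' Runs the interacting bath at packing fraction 0.38 with the bead held
#' fixed fully inside the slow or the fast half-disc (bead centre at
#' `delta = -4a` or `+4a`, i.e. centred in the half-disc), for an ensemble
#' of seeds, and aggregates the wall-pressure profile and the field maps.
#' Speeds are the reference set (7:17:19 scaled to background 1); geometry
#' is [reference_geometry()].
#'
#' @param side `"fast"` or `"slow"`
#' @param seeds integer vector of seeds (one run each)
#' @param n_steps steps per run
#' @param phi packing fraction
#' @param scale geometry scale, see [reference_geometry()]
#' @param save_every frame cadence
#' @param n_theta angular bins for the wall profile
#' @return list with per-run contour means (`p_w`, `p_d`, `p_s`), their
#'   ensemble means and standard errors, the pooled angular profile, the
#'   ensemble-averaged polarization and direct-pressure maps, the pattern
#'   and the run metadata
#' @export
pressure_protocol <- function(side = c("fast", "slow"), seeds = 1:6,
                              n_steps = 2e5, phi = 0.38,
                              scale = "reduced", save_every = 25L,
                              n_theta = 36L) {
  side <- match.arg(side)
  geo <- reference_geometry(scale)
  v <- reference_speeds()
  rod <- rod_params()
  delta <- if (side == "fast") 4 * geo$a else -4 * geo$a
  cfg <- sim_config(L = geo$L, phi = phi, dt = 2e-3, n_steps = n_steps,
                    save_every = save_every, rod = rod)
  bead <- bead_spec(a = geo$a, mobile = FALSE)
  pat <- speed_pattern(v$v_minus, v$v_plus, v$v_zero, R = geo$R,
                       delta = delta)
  p_w <- p_d <- numeric(0)
  prof_sum <- NULL
  m_sum <- pd_sum <- NULL
  pattern_used <- NULL
  for (s in seeds) {
    tr <- simulate_run(cfg, rod, bead, pat, seed = s)
    wp <- wall_pressure(tr, n_theta = n_theta)
    p_w <- c(p_w, wp$mean_p_w)
    p_d <- c(p_d, wp$mean_p_d)
    prof_sum <- if (is.null(prof_sum)) wp$profile[c("p_w", "p_d")] else
      prof_sum + wp$profile[c("p_w", "p_d")]
    mm <- polarization_map(tr, bin = 1)
    pdm <- direct_pressure_map(tr, bin = 1)
    m_sum <- if (is.null(m_sum)) mm$values else m_sum + mm$values
    pd_sum <- if (is.null(pd_sum)) pdm$values else pd_sum + pdm$values
    pattern_used <- tr$pattern
    frames_each <- mm$frames_averaged
  }
  n <- length(seeds)
  profile <- data.frame(
    theta = (seq_len(n_theta) - 0.5) * 2 * pi / n_theta,
    p_w = prof_sum$p_w / n, p_d = prof_sum$p_d / n)
  profile$p_s <- profile$p_w - profile$p_d
  list(side = side,
       p_w = p_w, p_d = p_d, p_s = p_w - p_d,
       mean_p_w = mean(p_w), sem_p_w = stats::sd(p_w) / sqrt(n),
       mean_p_d = mean(p_d), sem_p_d = stats::sd(p_d) / sqrt(n),
       mean_p_s = mean(p_w - p_d),
       sem_p_s = stats::sd(p_w - p_d) / sqrt(n),
       profile = profile,
       m_map = field_map(m_sum / n, 1, geo$L, frames_each * n, "m"),
       pd_map = field_map(pd_sum / n, 1, geo$L, frames_each * n, "p_D"),
       pattern = pattern_used, config = cfg, bead = bead,
       seeds = seeds)
}

#' Reference drift-measurement protocol
#'
#' Runs the mobile-bead simulation with the feedback-locked pattern for an
#' ensemble of seeds and returns the drift estimate along the slow-to-fast
#' axis. Speeds are the reference 7:17:19 set; by default the bead sits at
#' the slow/fast interface (`delta = 0`).
#'
#' @param seeds integer vector of seeds
#' @param n_steps steps per run
#' @param phi packing fraction
#' @param delta bead offset from the disc centre (in reduced length units)
#' @param interactions_on `FALSE` drops rod-rod forces (the bead stays
#'   impenetrable)
#' @param swap_speeds if `TRUE`, exchange the slow and fast half speeds
#'   (mirror test)
#' @param scale geometry scale, see [reference_geometry()]
#' @param save_every frame cadence
#' @return a [drift_speed()] estimate; the trajectories are discarded
#' @export
drift_protocol <- function(seeds = 1:10, n_steps = 2e5, phi = 0.38,
                           delta = 0, interactions_on = TRUE,
                           swap_speeds = FALSE, scale = "reduced",
                           save_every = 100L) {
  geo <- reference_geometry(scale)
  v <- reference_speeds()
  rod <- rod_params()
  cfg <- sim_config(L = geo$L, phi = phi, dt = 2e-3, n_steps = n_steps,
                    save_every = save_every,
                    interactions_on = interactions_on, rod = rod)
  bead <- bead_spec(a = geo$a, mobile = TRUE)
  pat <- speed_pattern(v$v_minus, v$v_plus, v$v_zero, R = geo$R,
                       delta = delta)
  if (swap_speeds) {
    # swapping v- and v+ is equivalent to mirroring the pattern axis
    pat$axis <- -pat$axis
    est_axis <- c(1, 0)
  } else est_axis <- NULL
  trajs <- lapply(seeds, function(s) simulate_run(cfg, rod, bead, pat,
                                                  seed = s))
  drift_speed(trajs, axis = est_axis)
}
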