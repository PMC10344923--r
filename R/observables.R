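#' Bead drift-speed estimate
#'
#' Per run, the least-squares slope of the bead position projected on `axis`
#' (unwrapped across periodic images by minimum-image increments between
#' saved frames) against time, over the post-transient frames; the estimate
#' is the mean of the per-run slopes with its standard error over runs.
#' Positive values point from the slow toward the fast half.
#'
#' @param trajs an `rt_traj` or a list of them (independent runs)
#' @param axis projection axis (defaults to each trajectory's pattern axis)
#' @param transient_fraction overrides the stored transient fraction
#' @return object of class `drift_estimate` with `v_drift`, `sem`, `n_runs`,
#'   `slopes`, `transient_fraction`
#' @export
drift_speed <- function(trajs, axis = NULL, transient_fraction = NULL) {
  if (inherits(trajs, "rt_traj")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1)
  slopes <- vapply(trajs, function(tr) {
    if (is.null(tr$bead)) stop("drift_speed: trajectory has no bead")
    ax <- if (is.null(axis)) tr$pattern$axis else axis / sqrt(sum(axis^2))
    frames <- post_transient_frames(tr, transient_fraction)
    if (length(frames) < 2)
      stop("drift_speed: trajectory shorter than the transient")
    pos <- unwrap_track(tr$bead, tr$config$L)
    x <- pos[1, frames] * ax[1] + pos[2, frames] * ax[2]
    t <- tr$times[frames]
    if (stats::var(t) == 0) return(0)
    stats::cov(x, t) / stats::var(t)
  }, numeric(1))
  n <- length(slopes)
  structure(list(v_drift = mean(slopes),
                 sem = if (n > 1) stats::sd(slopes) / sqrt(n) else 0,
                 n_runs = n, slopes = slopes,
                 transient_fraction = transient_fraction),
            class = "drift_estimate")
}

#' @export
print.drift_estimate <- function(x, ...) {
  cat(sprintf("drift_estimate: v = %.5g +/- %.3g (n = %d runs)\n",
              x$v_drift, x$sem, x$n_runs))
  invisible(x)
}

# unwrap a 2 x nf wrapped track across the periodic box
unwrap_track <- function(track, L) {
  if (ncol(track) < 2) return(track)
  inc <- track[, -1, drop = FALSE] - track[, -ncol(track), drop = FALSE]
  inc <- inc - L * round(inc / L)
  cbind(track[, 1], track[, 1] + t(apply(inc, 1, cumsum)))
}

#' Region density ratios
#'
#' Mean rod number density in the slow half-disc, the fast half-disc and the
#' background, expressed as ratios to the background. Regions are evaluated
#' in the disc frame of each saved frame (the masks follow the feedback), a
#' boundary shell of width `shell` around the region interfaces is excluded,
#' and so is a shell around the bead. Region areas are obtained by
#' classifying a deterministic fine grid of points with the same masks.
#'
#' @param traj an `rt_traj` with a disc pattern
#' @param transient_fraction overrides the stored transient
#' @param shell excluded boundary-shell width (default: rod thickness)
#' @return object of class `density_ratios` with `rho_minus_over_0`,
#'   `rho_plus_over_0` and the absolute densities
#' @export
density_ratios <- function(traj, transient_fraction = NULL, shell = NULL) {
  stopifnot(traj$pattern$type == "disc")
  if (is.null(shell)) shell <- traj$rod$sigma
  frames <- post_transient_frames(traj, transient_fraction)
  L <- traj$config$L
  R <- traj$pattern$R
  ax <- traj$pattern$axis
  a_excl <- if (!is.null(traj$bead_spec))
    traj$bead_spec$a + traj$rod$sigma / 2 + shell else 0

  classify <- function(dx, dy, bx, by) {
    # dx, dy relative to the disc centre (minimum image); bx, by relative
    # bead offset from the disc centre
    r2 <- dx^2 + dy^2
    s <- dx * ax[1] + dy * ax[2]
    db2 <- (dx - bx)^2 + (dy - by)^2
    lab <- integer(length(dx))  # 0 = excluded
    inside <- r2 <= (R - shell)^2 & db2 > a_excl^2
    lab[inside & s < -shell] <- 1L               # slow
    lab[inside & s > shell] <- 2L                # fast
    lab[r2 >= (R + shell)^2 & db2 > a_excl^2] <- 3L  # background
    lab
  }

  counts <- c(0, 0, 0)
  for (f in frames) {
    dx <- traj$positions[, 1, f] - traj$disc[1, f]
    dy <- traj$positions[, 2, f] - traj$disc[2, f]
    dx <- dx - L * round(dx / L)
    dy <- dy - L * round(dy / L)
    if (!is.null(traj$bead)) {
      bx <- traj$bead[1, f] - traj$disc[1, f]
      by <- traj$bead[2, f] - traj$disc[2, f]
      bx <- bx - L * round(bx / L)
      by <- by - L * round(by / L)
    } else bx <- by <- 1e9
    lab <- classify(dx, dy, bx, by)
    counts <- counts + tabulate(lab, 3L)
  }

  # deterministic area estimate with the same masks (disc frame, bead at
  # its pattern offset delta)
  ng <- 400L
  g <- (seq_len(ng) - 0.5) / ng * L - L / 2
  gg <- expand.grid(dx = g, dy = g)
  bx0 <- if (!is.null(traj$bead)) traj$pattern$delta * ax[1] else 1e9
  by0 <- if (!is.null(traj$bead)) traj$pattern$delta * ax[2] else 1e9
  lab_g <- classify(gg$dx, gg$dy, bx0, by0)
  areas <- tabulate(lab_g, 3L) * (L / ng)^2
  if (any(areas == 0)) stop("density_ratios: empty region mask")

  dens <- counts / (length(frames) * areas)
  if (dens[3] <= 0) stop("density_ratios: empty background region")
  structure(list(rho_minus_over_0 = dens[1] / dens[3],
                 rho_plus_over_0 = dens[2] / dens[3],
                 rho = c(slow = dens[1], fast = dens[2],
                         background = dens[3]),
                 n_frames = length(frames)),
            class = "density_ratios")
}

#' @export
print.density_ratios <- function(x, ...) {
  cat(sprintf("density_ratios: rho-/rho0 = %.3f, rho+/rho0 = %.3f\n",
              x$rho_minus_over_0, x$rho_plus_over_0))
  invisible(x)
}

#' Parameter sweep of the drift protocol
#'
#' Runs `n_runs` independent mobile-bead simulations at each value of the
#' swept parameter (`phi`, `delta` or `v_zero`) and tabulates the drift
#' estimate and region density ratios. For a `phi` sweep the returned table
#' carries the linear fit `drift ~ phi` as attributes (`intercept_phi` is
#' the zero-drift packing fraction); for a `v_zero` sweep a
#' `drift_norm` column (drift normalized to its maximum) is added.
#'
#' @param vary one of `"phi"`, `"delta"`, `"v_zero"`
#' @param values numeric vector of swept values
#' @param n_runs independent runs per value (>= 2)
#' @param config base [sim_config()] (its `phi` is overridden in a phi sweep)
#' @param rod a [rod_params()]
#' @param bead a [bead_spec()]; mobility is forced on
#' @param pattern base [speed_pattern()]
#' @param seed0 base seed; run `r` at value index `k` uses
#'   `seed0 + 1000 * k + r`
#' @param density_ratios_too also compute density ratios (slower)
#' @return data frame with one row per swept value
#' @export
sweep_drift <- function(vary = c("phi", "delta", "v_zero"), values, n_runs,
                        config, rod = rod_params(), bead = bead_spec(),
                        pattern, seed0 = 1, density_ratios_too = TRUE) {
  vary <- match.arg(vary)
  stopifnot(all(is.finite(values)), n_runs >= 2)
  bead$mobile <- TRUE
  rows <- lapply(seq_along(values), function(k) {
    val <- values[k]
    cfg <- config
    pat <- pattern
    if (vary == "phi")
      cfg <- sim_config(L = config$L, phi = val, dt = config$dt,
                        n_steps = config$n_steps,
                        save_every = config$save_every,
                        feedback_every = config$feedback_every,
                        interactions_on = config$interactions_on,
                        transient_fraction = config$transient_fraction,
                        rod = rod)
    if (vary == "delta") pat$delta <- val
    if (vary == "v_zero") pat$v_zero <- val
    trajs <- lapply(seq_len(n_runs), function(r)
      simulate_run(cfg, rod, bead, pat, seed = seed0 + 1000L * k + r))
    dr <- drift_speed(trajs)
    ratios <- if (density_ratios_too) {
      rr <- lapply(trajs, density_ratios)
      c(mean(vapply(rr, `[[`, numeric(1), "rho_minus_over_0")),
        mean(vapply(rr, `[[`, numeric(1), "rho_plus_over_0")))
    } else c(NA_real_, NA_real_)
    data.frame(sweep_var = vary, value = val, drift = dr$v_drift,
               sem = dr$sem, rho_minus_ratio = ratios[1],
               rho_plus_ratio = ratios[2], n_runs = n_runs,
               seed0 = seed0 + 1000L * k)
  })
  out <- do.call(rbind, rows)
  if (vary == "phi" && length(values) >= 2) {
    fit <- stats::lm(drift ~ value, data = out)
    cf <- stats::coef(fit)
    attr(out, "fit_slope") <- unname(cf[2])
    attr(out, "fit_intercept") <- unname(cf[1])
    # packing fraction at which the fitted drift extrapolates to zero
    attr(out, "intercept_phi") <- unname(-cf[1] / cf[2])
  }
  if (vary == "v_zero")
    out$drift_norm <- out$drift / max(out$drift)
  out
}
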