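#' Field map container
#'
#' A scalar or 2-vector field on a regular square grid over the periodic box.
#' Scalar fields are `nbins x nbins` matrices; vector fields are
#' `nbins x nbins x 2` arrays. Bin `[i, j]` covers
#' `[(i-1) b, i b) x [(j-1) b, j b)` with `b = L / nbins`.
#'
#' @param values matrix or 3D array of bin values
#' @param bin bin side length
#' @param L box side
#' @param frames_averaged number of frames averaged
#' @param kind short label (`"density"`, `"p_D"`, `"m"`, `"f_S"`, ...)
#' @return object of class `field_map`
#' @export
field_map <- function(values, bin, L, frames_averaged, kind = "field") {
  stopifnot(is.numeric(values), bin > 0, L > 0, frames_averaged >= 1)
  if (any(!is.finite(values))) stop("field_map: values must be finite")
  structure(list(values = values, bin = bin, L = L,
                 frames_averaged = frames_averaged, kind = kind),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("field_map [%s]: %d x %d bins of side %.3g (%s), %d frames\n",
              x$kind, d[1], d[2], x$bin,
              if (length(d) == 3) "vector" else "scalar", x$frames_averaged))
  invisible(x)
}

#' Bin-centre coordinates of a field map grid
#'
#' @param fm a [field_map()] (or any list with `bin` and `L`)
#' @return list with vectors `x` and `y` of bin centres
#' @export
grid_centers <- function(fm) {
  n <- round(fm$L / fm$bin)
  g <- (seq_len(n) - 0.5) * fm$bin
  list(x = g, y = g)
}

resolve_grid <- function(L, bin) {
  nbins <- round(L / bin)
  if (abs(nbins * bin - L) > 1e-9 * L)
    stop("grid bin size must divide the box side")
  as.integer(nbins)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$bin, b$bin)) && isTRUE(all.equal(a$L, b$L))
}

bin_index <- function(x, L, nbins) {
  i <- floor(x %% L / L * nbins) + 1L
  pmin(i, nbins)
}

#' Time-averaged number-density map
#'
#' Counts rod centres per bin over the post-transient frames and divides by
#' bin area and frame count, so the box integral equals the rod count N.
#'
#' @param traj an `rt_traj`
#' @param bin grid bin side
#' @param transient_fraction overrides the trajectory's stored transient
#' @return a [field_map()] of number density
#' @export
density_map <- function(traj, bin = 1, transient_fraction = NULL) {
  frames <- post_transient_frames(traj, transient_fraction)
  if (length(frames) == 0) stop("density_map: empty frame selection")
  nbins <- resolve_grid(traj$config$L, bin)
  xs <- as.vector(traj$positions[, 1, frames, drop = FALSE])
  ys <- as.vector(traj$positions[, 2, frames, drop = FALSE])
  ix <- bin_index(xs, traj$config$L, nbins)
  iy <- bin_index(ys, traj$config$L, nbins)
  counts <- matrix(tabulate(ix + nbins * (iy - 1L), nbins * nbins),
                   nbins, nbins)
  field_map(counts / (length(frames) * bin^2), bin, traj$config$L,
            length(frames), "density")
}

#' Polarization field map
#'
#' The number-density-weighted mean orientation `m = rho <e>`: per bin the
#' time-averaged sum of rod orientation unit vectors divided by the bin area.
#'
#' @inheritParams density_map
#' @return a 2-vector [field_map()]
#' @export
polarization_map <- function(traj, bin = 1, transient_fraction = NULL) {
  frames <- post_transient_frames(traj, transient_fraction)
  nbins <- resolve_grid(traj$config$L, bin)
  xs <- as.vector(traj$positions[, 1, frames, drop = FALSE])
  ys <- as.vector(traj$positions[, 2, frames, drop = FALSE])
  th <- as.vector(traj$angles[, frames, drop = FALSE])
  idx <- bin_index(xs, traj$config$L, nbins) +
    nbins * (bin_index(ys, traj$config$L, nbins) - 1L)
  s <- rowsum(cbind(cos(th), sin(th)), idx)
  present <- as.integer(rownames(s))
  mx <- my <- numeric(nbins * nbins)
  mx[present] <- s[, 1]
  my[present] <- s[, 2]
  vals <- array(0, dim = c(nbins, nbins, 2))
  vals[, , 1] <- matrix(mx, nbins, nbins) / (length(frames) * bin^2)
  vals[, , 2] <- matrix(my, nbins, nbins) / (length(frames) * bin^2)
  field_map(vals, bin, traj$config$L, length(frames), "m")
}

#' Direct (virial) pressure map
#'
#' Localizes the rod-rod interaction pressure by assigning each contact
#' pair's full virial `r_ij . f_ij` to the bin containing the pair midpoint:
#' `p_D = <sum_pairs r_ij . f_ij> / (2 A_bin)` per bin (2D virial trace),
#' averaged over the post-transient frames. Rod-bead forces are wall forces
#' and are excluded. The bin must not be smaller than twice the rod
#' thickness, otherwise the midpoint estimator is biased.
#'
#' @inheritParams density_map
#' @return a scalar [field_map()] of `p_D`
#' @export
direct_pressure_map <- function(traj, bin = 1, transient_fraction = NULL) {
  if (bin < 2 * traj$rod$sigma)
    stop("direct_pressure_map: bin smaller than the interaction range 2*sigma")
  frames <- post_transient_frames(traj, transient_fraction)
  if (length(frames) == 0) stop("direct_pressure_map: empty frame selection")
  nbins <- resolve_grid(traj$config$L, bin)
  if (!traj$config$interactions_on)
    # rod-rod forces were off during the run; recomputed overlaps carry no
    # stress
    return(field_map(matrix(0, nbins, nbins), bin, traj$config$L,
                     length(frames), "p_D"))
  sums <- virial_map_cpp(traj$positions, traj$angles, traj$config$N,
                         as.integer(frames), traj$rod$shaft, traj$rod$sigma,
                         traj$rod$k_rep, traj$config$L, nbins)
  field_map(sums / (length(frames) * 2 * bin^2), bin, traj$config$L,
            length(frames), "p_D")
}

#' Global (unbinned) virial pressure of one frame
#'
#' Brute-force sum of `r_ij . f_ij` over all rod pairs of a single frame,
#' divided by `2 L^2`: the box-averaged direct pressure without any spatial
#' binning. Quadratic in N; intended as an independent oracle for
#' [direct_pressure_map()] on small fixtures.
#'
#' @param traj an `rt_traj`
#' @param frame frame index
#' @return scalar pressure
#' @export
global_virial_pressure <- function(traj, frame) {
  N <- traj$config$N
  if (N < 2 || !traj$config$interactions_on) return(0)
  tot <- 0
  for (i in seq_len(N - 1)) {
    for (j in seq.int(i + 1, N)) {
      pf <- pair_force(traj$positions[i, , frame], traj$angles[i, frame],
                       traj$positions[j, , frame], traj$angles[j, frame],
                       traj$rod, traj$config$L, idx = c(i - 1L, j - 1L))
      tot <- tot + pf$virial
    }
  }
  tot / (2 * traj$config$L^2)
}

#' Wall pressure profile on the bead contour
#'
#' Time-averaged normal contact force per unit contour length exerted by the
#' rods on the bead, resolved in angular bins, for a trajectory segment in
#' which the bead is held fixed. The direct pressure on the contour is
#' estimated from the pair virials whose midpoints fall in a thin annulus
#' right outside the contact shell (radii `a + sigma/2` to
#' `a + sigma/2 + sigma`), resolved in the same angular wedges; an annulus
#' estimator is used instead of sampling the square-binned pressure map
#' because square bins straddling the bead boundary would dilute `p_D` with
#' the pair-free area inside the contact shell. The swim pressure on the
#' contour is defined empirically as `p_S = p_W - p_D`.
#'
#' @param traj an `rt_traj` with a fixed bead
#' @param n_theta number of angular bins
#' @param transient_fraction overrides the stored transient
#' @return object of class `wall_pressure_profile`: a data frame
#'   (`theta`, `p_w`, `p_d`, `p_s`) plus contour means and the net contact
#'   force, with theta the lab-frame polar angle on the contour
#' @export
wall_pressure <- function(traj, n_theta = 36, transient_fraction = NULL) {
  if (is.null(traj$bead)) stop("wall_pressure: trajectory has no bead")
  frames <- post_transient_frames(traj, transient_fraction)
  b <- traj$bead[, frames, drop = FALSE]
  if (max(abs(b - b[, 1])) > 0)
    stop("wall_pressure: bead moved during the analyzed segment")
  a <- traj$bead_spec$a
  prof <- wall_profile_cpp(traj$positions, traj$angles, traj$bead,
                           traj$config$N, as.integer(frames), traj$rod$shaft,
                           traj$rod$sigma, a, traj$rod$k_rep,
                           traj$config$L, as.integer(n_theta))
  arc <- 2 * pi * a / n_theta
  p_w <- prof$force_sum / (length(frames) * arc)
  theta <- (seq_len(n_theta) - 0.5) * 2 * pi / n_theta

  # direct pressure in annular wedges just outside the contact shell
  r1 <- a + traj$rod$sigma / 2
  r2 <- r1 + traj$rod$sigma
  if (traj$config$interactions_on) {
    pd_sums <- contour_pd_cpp(traj$positions, traj$angles, traj$config$N,
                              as.integer(frames), traj$bead, traj$rod$shaft,
                              traj$rod$sigma, traj$rod$k_rep, traj$config$L,
                              r1, r2, as.integer(n_theta))
    a_wedge <- pi * (r2^2 - r1^2) / n_theta
    p_d <- pd_sums / (length(frames) * 2 * a_wedge)
  } else p_d <- numeric(n_theta)
  structure(
    list(profile = data.frame(theta = theta, p_w = p_w, p_d = p_d,
                              p_s = p_w - p_d),
         mean_p_w = mean(p_w), mean_p_d = mean(p_d),
         mean_p_s = mean(p_w) - mean(p_d),
         net_force = prof$net_force / length(frames),
         force_vec = prof$force_vec / length(frames),
         n_theta = n_theta, a = a, n_frames = length(frames)),
    class = "wall_pressure_profile")
}

#' @export
print.wall_pressure_profile <- function(x, ...) {
  cat(sprintf(
    "wall_pressure_profile: %d bins, mean p_W = %.4g, p_D = %.4g, p_S = %.4g\n",
    x$n_theta, x$mean_p_w, x$mean_p_d, x$mean_p_s))
  invisible(x)
}

#' Swim force density field
#'
#' `f_S(r) = gamma v(r) m(r)`: the polarization field scaled by the drag and
#' the local imposed speed, evaluated at the bin centres.
#'
#' @param m_map a 2-vector polarization [field_map()]
#' @param pattern the [speed_pattern()] the trajectory was run with
#' @param gamma translational drag
#' @return a 2-vector [field_map()]
#' @export
swim_force_density <- function(m_map, pattern, gamma = 1) {
  stopifnot(inherits(m_map, "field_map"), length(dim(m_map$values)) == 3)
  g <- grid_centers(m_map)
  pts <- as.matrix(expand.grid(x = g$x, y = g$y))
  v <- matrix(speed_at(pattern, pts, m_map$L), length(g$x), length(g$y))
  vals <- m_map$values
  vals[, , 1] <- gamma * v * vals[, , 1]
  vals[, , 2] <- gamma * v * vals[, , 2]
  field_map(vals, m_map$bin, m_map$L, m_map$frames_averaged, "f_S")
}

# periodic Gaussian smoothing by FFT convolution
periodic_smooth <- function(x, sigma) {
  n <- nrow(x)
  d <- pmin(0:(n - 1), n - (0:(n - 1)))
  k <- exp(-0.5 * (d / sigma)^2)
  k <- k / sum(k)
  K <- outer(k, k)
  Re(stats::fft(stats::fft(x) * stats::fft(K), inverse = TRUE)) / n^2
}

# centered finite-difference gradient on the periodic grid
periodic_gradient <- function(values, bin) {
  n <- nrow(values)
  up <- c(2:n, 1)
  dn <- c(n, 1:(n - 1))
  gx <- (values[up, , drop = FALSE] - values[dn, , drop = FALSE]) / (2 * bin)
  gy <- (values[, up, drop = FALSE] - values[, dn, drop = FALSE]) / (2 * bin)
  array(c(gx, gy), dim = c(n, ncol(values), 2))
}

#' Momentum-balance residual
#'
#' In a no-current steady state the swim force density must balance the
#' direct pressure gradient, `gamma v(r) m(r) = grad p_D`. This computes the
#' residual field `f_S - grad p_D` (gradient by centred differences on the
#' periodic grid) and a scalar summary:
#' `median |residual| / median |f_S|` restricted to bins where `|f_S|`
#' exceeds its own median, which avoids division noise in the force-free
#' bulk.
#'
#' @param f_s_map 2-vector [field_map()] from [swim_force_density()]
#' @param p_d_map scalar [field_map()] from [direct_pressure_map()]
#' @param smooth_sigma optional width (in bins) of a periodic Gaussian
#'   kernel applied to both fields before differencing. Because convolution
#'   commutes with the gradient, smoothing both sides preserves the balance
#'   identity exactly while suppressing bin-scale misassignment noise;
#'   0 disables it
#' @return list with `residual` (2-vector [field_map()]) and `summary`
#' @export
momentum_balance_residual <- function(f_s_map, p_d_map, smooth_sigma = 0) {
  stopifnot(inherits(f_s_map, "field_map"), inherits(p_d_map, "field_map"))
  if (!same_grid(f_s_map, p_d_map))
    stop("momentum_balance_residual: field maps are on different grids")
  if (smooth_sigma > 0) {
    f_s_map$values[, , 1] <- periodic_smooth(f_s_map$values[, , 1],
                                             smooth_sigma)
    f_s_map$values[, , 2] <- periodic_smooth(f_s_map$values[, , 2],
                                             smooth_sigma)
    p_d_map$values <- periodic_smooth(p_d_map$values, smooth_sigma)
  }
  grad <- periodic_gradient(p_d_map$values, p_d_map$bin)
  res <- f_s_map$values - grad
  fmag <- sqrt(f_s_map$values[, , 1]^2 + f_s_map$values[, , 2]^2)
  rmag <- sqrt(res[, , 1]^2 + res[, , 2]^2)
  sel <- fmag > stats::median(fmag)
  summary <- if (any(sel))
    stats::median(rmag[sel]) / stats::median(fmag[sel]) else NA_real_
  list(residual = field_map(res, f_s_map$bin, f_s_map$L,
                            f_s_map$frames_averaged, "residual"),
       summary = summary)
}

#' Export a wall pressure profile as CSV
#'
#' @param profile a [wall_pressure()] result
#' @param path output file
#' @return `path`, invisibly
#' @export
write_wall_profile <- function(profile, path) {
  stopifnot(inherits(profile, "wall_pressure_profile"))
  utils::write.csv(profile$profile, path, row.names = FALSE)
  invisible(path)
}
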