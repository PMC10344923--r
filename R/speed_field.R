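#' Light-defined speed pattern
#'
#' Constructs the activity landscape imposed by the virtual light pattern: a
#' modulation disc of radius `R` split by a diameter into a slow half (speed
#' `v_minus`) and a fast half (`v_plus`), embedded in a uniform background of
#' speed `v_zero`. The bead centre sits at signed offset `delta` from the disc
#' centre along `axis`, the unit vector pointing from the slow toward the fast
#' half. Points exactly on the dividing diameter count as slow; points exactly
#' at distance `R` are inside the disc.
#'
#' All quantities are in reduced units (rod length = 1, background speed of
#' the reference parameter set = 1).
#'
#' @param v_minus swimming speed in the slow half-disc (must be <= `v_plus`)
#' @param v_plus swimming speed in the fast half-disc
#' @param v_zero background swimming speed outside the disc
#' @param R disc radius
#' @param delta signed displacement of the bead centre from the disc centre
#'   along `axis`
#' @param axis length-2 vector from the slow toward the fast half; normalised
#'   internally
#' @param disc_center length-2 disc centre
#' @param type `"disc"` for the modulation disc, `"step"` for a half/half box
#'   split at x = L/2 (left half `v_minus`, right half `v_plus`), `"uniform"`
#'   for `v_zero` everywhere
#' @return an object of class `speed_pattern`
#' @export
speed_pattern <- function(v_minus, v_plus, v_zero, R = 1, delta = 0,
                          axis = c(1, 0), disc_center = c(0, 0),
                          type = c("disc", "step", "uniform")) {
  type <- match.arg(type)
  stopifnot(is.numeric(v_minus), is.numeric(v_plus), is.numeric(v_zero),
            length(axis) == 2, length(disc_center) == 2)
  if (any(!is.finite(c(v_minus, v_plus, v_zero, R, delta, axis, disc_center))))
    stop("speed_pattern: all parameters must be finite")
  if (v_minus < 0 || v_plus < 0 || v_zero < 0)
    stop("speed_pattern: speeds must be >= 0")
  if (type == "disc" && v_minus > v_plus)
    stop("speed_pattern: v_minus must be <= v_plus")
  if (type == "disc" && R <= 0)
    stop("speed_pattern: R must be > 0")
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("speed_pattern: axis must be non-zero")
  structure(
    list(v_minus = v_minus, v_plus = v_plus, v_zero = v_zero, R = R,
         delta = delta, axis = axis / nrm, disc_center = disc_center,
         type = type),
    class = "speed_pattern")
}

#' @export
print.speed_pattern <- function(x, ...) {
  cat(sprintf("speed_pattern [%s]: v- = %.4g, v+ = %.4g, v0 = %.4g\n",
              x$type, x$v_minus, x$v_plus, x$v_zero))
  if (x$type == "disc")
    cat(sprintf("  R = %.4g, delta = %.4g, axis = (%.3f, %.3f), centre = (%.3f, %.3f)\n",
                x$R, x$delta, x$axis[1], x$axis[2],
                x$disc_center[1], x$disc_center[2]))
  invisible(x)
}

pattern_type_code <- function(pattern) {
  switch(pattern$type, disc = 0L, step = 1L, uniform = 2L)
}

#' Swimming speed at a point
#'
#' Evaluates the position-dependent swimming speed imposed by a
#' [speed_pattern()] using the minimum-image convention on a periodic square
#' box of side `L`.
#'
#' @param pattern a [speed_pattern()]
#' @param points a length-2 vector or an n x 2 matrix of positions
#' @param L box side
#' @return numeric vector of speeds, one per point
#' @export
speed_at <- function(pattern, points, L) {
  stopifnot(inherits(pattern, "speed_pattern"), is.numeric(L), L > 0)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  if (ncol(points) != 2) stop("speed_at: points must be n x 2")
  if (any(!is.finite(points))) stop("speed_at: non-finite point")
  speed_at_cpp(points[, 1], points[, 2], pattern_type_code(pattern),
               pattern$disc_center[1], pattern$disc_center[2],
               pattern$axis[1], pattern$axis[2], pattern$R,
               pattern$v_minus, pattern$v_plus, pattern$v_zero, L)
}

#' Region label at a point
#'
#' Classifies points into the three activity regions of a disc pattern.
#'
#' @inheritParams speed_at
#' @return character vector with values `"slow"`, `"fast"` or `"background"`
#' @export
region_at <- function(pattern, points, L) {
  stopifnot(inherits(pattern, "speed_pattern"), pattern$type == "disc")
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  if (any(!is.finite(points))) stop("region_at: non-finite point")
  out <- rep("background", nrow(points))
  dx <- points[, 1] - pattern$disc_center[1]
  dy <- points[, 2] - pattern$disc_center[2]
  dx <- dx - L * round(dx / L)
  dy <- dy - L * round(dy / L)
  inside <- dx^2 + dy^2 <= pattern$R^2
  s <- dx * pattern$axis[1] + dy * pattern$axis[2]
  out[inside & s > 0] <- "fast"
  out[inside & s <= 0] <- "slow"
  out
}

#' Feedback update of the modulation disc
#'
#' Re-centres the modulation disc so that the bead centre sits at the signed
#' offset `delta` from the disc centre along the pattern axis, mimicking the
#' optical feedback loop that keeps the light pattern locked to the bead.
#' Pure function: returns a new pattern.
#'
#' @param pattern a disc-type [speed_pattern()]
#' @param bead_center length-2 bead centre
#' @param L box side (disc centre is wrapped into the box)
#' @return the updated `speed_pattern`
#' @export
update_disc <- function(pattern, bead_center, L) {
  stopifnot(inherits(pattern, "speed_pattern"), pattern$type == "disc",
            length(bead_center) == 2, all(is.finite(bead_center)))
  centre <- bead_center - pattern$delta * pattern$axis
  pattern$disc_center <- centre %% L
  pattern
}

#' Light-intensity to swimming-speed calibration
#'
#' Monotone piecewise-linear interpolation through measured
#' (intensity, speed) anchor pairs. Carried as experimental metadata; the
#' dynamics itself works directly in reduced speed units.
#'
#' @param anchors data frame with columns `intensity` (mW/mm^2) and `speed`
#'   (um/s); defaults to the reference calibration I = 0.1, 0.7, 0.9 mW/mm^2
#'   at v = 7, 17, 19 um/s
#' @return an object of class `intensity_calibration`
#' @export
intensity_calibration <- function(anchors = data.frame(
                                    intensity = c(0.1, 0.7, 0.9),
                                    speed = c(7, 17, 19))) {
  stopifnot(is.data.frame(anchors),
            all(c("intensity", "speed") %in% names(anchors)),
            nrow(anchors) >= 2)
  o <- order(anchors$intensity)
  anchors <- anchors[o, , drop = FALSE]
  if (is.unsorted(anchors$speed))
    stop("intensity_calibration: speeds must be non-decreasing with intensity")
  structure(list(anchors = anchors), class = "intensity_calibration")
}

#' Interpolate swimming speed from light intensity
#'
#' @param cal an [intensity_calibration()]
#' @param I light intensity (mW/mm^2), within the anchor range
#' @return interpolated speed (um/s)
#' @export
intensity_to_speed <- function(cal, I) {
  stopifnot(inherits(cal, "intensity_calibration"))
  rng <- range(cal$anchors$intensity)
  if (any(!is.finite(I)) || any(I < rng[1]) || any(I > rng[2]))
    stop(sprintf("intensity_to_speed: I outside calibrated range [%g, %g]",
                 rng[1], rng[2]))
  stats::approx(cal$anchors$intensity, cal$anchors$speed, xout = I,
                method = "linear")$y
}

#' Reference speed set
#'
#' The three region speeds in reduced units (background speed = 1), taken
#' from the calibrated experimental speeds 7, 17 and 19 um/s for the slow
#' half, background and fast half respectively.
#'
#' @return named list with `v_minus`, `v_zero`, `v_plus`
#' @export
reference_speeds <- function() {
  list(v_minus = 7 / 17, v_zero = 1, v_plus = 19 / 17)
}
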