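# shared helpers for the test suite

# a minimal hand-built trajectory carrying explicit frames, for analyzer
# tests that need exact control over positions/angles
manual_traj <- function(positions, angles, L, rod = rod_params(),
                        bead = NULL, times = NULL, pattern = NULL) {
  nf <- dim(positions)[3]
  N <- dim(positions)[1]
  if (is.null(times)) times <- seq_len(nf) - 1
  cfg <- sim_config(L = L, N = N, n_steps = nf - 1L, save_every = 1L,
                    transient_fraction = 0, rod = rod)
  bp <- !is.null(bead)
  bc <- if (bp) bead_center_or_default(bead, L)
  structure(
    list(times = times, positions = positions, angles = angles,
         bead = if (bp) matrix(bc, 2, nf) else NULL,
         disc = matrix(if (is.null(pattern)) c(L / 2, L / 2)
                       else pattern$disc_center, 2, nf),
         bead_spec = bead, n_frames = nf, config = cfg, rod = rod,
         pattern = if (is.null(pattern))
           speed_pattern(0, 0, 0, type = "uniform") else pattern,
         format_version = 1L),
    class = "rt_traj")
}

# random rod configuration (possibly overlapping), for force-law tests
random_rod_pair <- function(L = 10, spread = 1.2) {
  r1 <- runif(2, 0, L)
  r2 <- r1 + runif(2, -spread, spread)
  list(r1 = r1, th1 = runif(1, 0, 2 * pi),
       r2 = r2 %% L, th2 = runif(1, 0, 2 * pi))
}

# ensemble cache so expensive reference runs are computed once per session
.run_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}
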