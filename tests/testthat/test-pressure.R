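test_that("density map integrates to N and is flat for a uniform gas", {
  tr <- make_step_profile_gas(n = 300, v_left = 1, v_right = 1, L = 20,
                              seed = 2, n_steps = 4000L, save_every = 100L)
  dm <- density_map(tr, bin = 1)
  # counting estimator: box integral equals the swimmer count exactly
  expect_equal(sum(dm$values) * dm$bin^2, 300)
  # uniform speed: flat within sampling error (relative sd of bin counts)
  expect_lt(sd(dm$values) / mean(dm$values), 0.5)
})

test_that("a fully aligned frame has |m| = rho exactly", {
  L <- 10
  pos <- array(0, dim = c(40, 2, 1))
  set.seed(6)
  pos[, , 1] <- matrix(runif(80, 0, L), 40)
  ang <- matrix(0.3, 40, 1)  # all rods aligned
  tr <- manual_traj(pos, ang, L)
  m <- polarization_map(tr, bin = 2)
  rho <- density_map(tr, bin = 2)
  expect_equal(sqrt(m$values[, , 1]^2 + m$values[, , 2]^2), rho$values)
})

test_that("an isotropic bulk has |m| near zero", {
  tr <- make_step_profile_gas(n = 400, v_left = 1, v_right = 1, L = 20,
                              seed = 9, n_steps = 20000L, save_every = 100L)
  m <- polarization_map(tr, bin = 5)
  rho <- density_map(tr, bin = 5)
  expect_lt(max(sqrt(m$values[, , 1]^2 + m$values[, , 2]^2) / rho$values),
            0.2)
})

test_that("binned direct pressure reproduces the brute-force global virial", {
  # non-interacting gas: p_D identically zero
  tr0 <- make_step_profile_gas(n = 50, v_left = 0.5, v_right = 1, L = 12,
                               seed = 3, n_steps = 500L, save_every = 100L)
  pd0 <- direct_pressure_map(tr0, bin = 1)
  expect_equal(max(abs(pd0$values)), 0)

  # passive relaxing gas with real contacts: binned sum equals the global
  # brute-force virial frame by frame, to machine precision
  tr <- make_passive_gas(n = 20, L = 8, seed = 14, n_steps = 100L)
  found_contact <- FALSE
  for (f in c(1, 3, 6)) {
    tf <- tr
    tf$positions <- tr$positions[, , f, drop = FALSE]
    tf$angles <- tr$angles[, f, drop = FALSE]
    tf$n_frames <- 1L
    tf$config$transient_fraction <- 0
    pd <- direct_pressure_map(tf, bin = 1)
    glob <- global_virial_pressure(tr, f)
    found_contact <- found_contact || glob > 0
    expect_equal(mean(pd$values), glob, tolerance = 1e-12)
  }
  expect_true(found_contact)
})

test_that("a two-rod overlap carries the hand-computed virial", {
  rod <- rod_params()
  L <- 8
  d <- 0.4  # centre separation of two parallel side-by-side rods
  pos <- array(0, dim = c(2, 2, 1))
  pos[1, , 1] <- c(4, 4)
  pos[2, , 1] <- c(4, 4 + d)
  ang <- matrix(0, 2, 1)  # both along x: shaft separation is exactly d
  tr <- manual_traj(pos, ang, L, rod = rod)
  pd <- direct_pressure_map(tr, bin = 1)
  # hand virial: f = k (sigma - d), w = d * f; box average = w / (2 L^2)
  w <- d * rod$k_rep * (rod$sigma - d)
  expect_equal(sum(pd$values) * pd$bin^2, w / 2, tolerance = 1e-12)
  # and it is assigned to the bin containing the pair midpoint
  expect_equal(which(pd$values != 0, arr.ind = TRUE)[1, ],
               c(row = 5, col = 5))
})

test_that("wall pressure profile integrates back to the recorded net force", {
  pr <- cached("wall_small", {
    geo <- reference_geometry()
    v <- reference_speeds()
    cfg <- sim_config(L = geo$L, phi = 0.38, n_steps = 60000L,
                      save_every = 25L)
    bead <- bead_spec(a = geo$a, mobile = FALSE)
    pat <- speed_pattern(v$v_minus, v$v_plus, v$v_zero, R = geo$R,
                         delta = 0)
    tr <- simulate_run(cfg, rod_params(), bead, pat, seed = 23)
    list(tr = tr, wp = wall_pressure(tr, n_theta = 36))
  })
  wp <- pr$wp
  tr <- pr$tr
  # bins without contacts report zero pressure
  expect_true(all(wp$profile$p_w >= 0))
  # vector integral of the binned contact forces equals the net force
  expect_equal(rowSums(wp$force_vec), wp$net_force, tolerance = 1e-12)
  # and matches the instantaneous rod-to-bead force the dynamics recorded
  # at the same frames
  frames <- post_transient_frames(tr)
  expect_equal(wp$net_force, rowMeans(tr$bead_force[, frames]),
               tolerance = 1e-10)
  # bead at the interface: the slow (left) side presses harder
  left <- wp$profile$theta > pi / 2 & wp$profile$theta < 3 * pi / 2
  expect_gt(mean(wp$profile$p_w[left]), mean(wp$profile$p_w[!left]))
  expect_error(wall_pressure(tr, transient_fraction = -1))
})

test_that("wall pressure demands a fixed bead", {
  cfg <- sim_config(L = 15, phi = 0.2, n_steps = 2000L, save_every = 100L)
  bead <- bead_spec(a = 1, mobile = TRUE)
  tr <- simulate_run(cfg, rod_params(), bead,
                     speed_pattern(0.4, 1.2, 1, R = 5), seed = 4)
  expect_error(wall_pressure(tr), "moved")
})

test_that("swim force density scales linearly with speed and vanishes with m", {
  L <- 20
  m0 <- array(0, dim = c(20, 20, 2))
  m0[5, 5, 1] <- 0.7
  m0[12, 3, 2] <- -0.2
  mm <- field_map(m0, 1, L, 10, "m")
  pat1 <- speed_pattern(0, 0, v_zero = 0.5, type = "uniform")
  pat2 <- speed_pattern(0, 0, v_zero = 1.0, type = "uniform")
  f1 <- swim_force_density(mm, pat1)
  f2 <- swim_force_density(mm, pat2)
  expect_equal(f2$values, 2 * f1$values)
  expect_equal(f1$values[5, 5, 1], 0.5 * 0.7)
  zero <- swim_force_density(field_map(array(0, dim = c(20, 20, 2)), 1, L,
                                       1, "m"), pat2)
  expect_equal(max(abs(zero$values)), 0)
})

test_that("momentum-balance residual machinery behaves on analytic fields", {
  # f_S = grad p_D exactly => residual 0
  L <- 16
  g <- (1:16) - 0.5
  p <- outer(sin(2 * pi * g / L), cos(2 * pi * g / L))
  fs <- array(0, dim = c(16, 16, 2))
  up <- c(2:16, 1); dn <- c(16, 1:15)
  fs[, , 1] <- (p[up, ] - p[dn, ]) / 2
  fs[, , 2] <- (p[, up] - p[, dn]) / 2
  res <- momentum_balance_residual(field_map(fs, 1, L, 1, "f_S"),
                                   field_map(p, 1, L, 1, "p_D"))
  expect_equal(res$summary, 0)
  expect_equal(max(abs(res$residual$values)), 0)
  # grid mismatch is an error
  expect_error(momentum_balance_residual(
    field_map(fs, 1, L, 1, "f_S"), field_map(p[1:8, 1:8], 2, L, 1, "p_D")),
    "grids")
  # non-interacting gas: p_D = 0, so the residual equals f_S
  pd0 <- field_map(matrix(0, 16, 16), 1, L, 1, "p_D")
  res0 <- momentum_balance_residual(field_map(fs, 1, L, 1, "f_S"), pd0)
  expect_equal(res0$residual$values, fs)
})
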