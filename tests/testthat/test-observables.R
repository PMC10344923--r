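test_that("drift estimator is exact on noiseless tracks and unbiased under noise", {
  # fixed bead: 0 +/- 0
  cfg <- sim_config(L = 15, phi = 0.05, n_steps = 1000L, save_every = 100L)
  tr <- simulate_run(cfg, rod_params(), bead_spec(a = 1, mobile = FALSE),
                     speed_pattern(0.4, 1.2, 1, R = 5), seed = 1)
  d0 <- drift_speed(tr)
  expect_equal(d0$v_drift, 0)
  expect_equal(d0$sem, 0)

  # noiseless synthetic drift is recovered exactly
  tr1 <- make_drift_synthetic(v_true = 0.01, noise_sd = 0, n_runs = 3,
                              seed = 2)
  d1 <- drift_speed(tr1)
  expect_equal(d1$v_drift, 0.01, tolerance = 1e-12)

  # zero drift under noise: estimate within 2 sem of 0
  tr2 <- make_drift_synthetic(v_true = 0, noise_sd = 0.5, n_runs = 50,
                              seed = 3)
  d2 <- drift_speed(tr2)
  expect_lt(abs(d2$v_drift), 2 * d2$sem)

  # parameter recovery over 100 noisy runs
  tr3 <- make_drift_synthetic(v_true = 0.01, noise_sd = 0.3, n_runs = 100,
                              seed = 4)
  d3 <- drift_speed(tr3)
  expect_lt(abs(d3$v_drift - 0.01), 2 * d3$sem)
  expect_error(drift_speed(tr3, transient_fraction = 0.9999), "transient")
})

test_that("drift estimator unwraps tracks across the periodic boundary", {
  # a bead drifting through the boundary several times
  L <- 10
  t <- 0:400
  x <- (2 + 0.07 * t) %% L
  traj <- structure(
    list(times = t, bead = rbind(x, rep(5, length(t))),
         n_frames = length(t),
         config = list(L = L, transient_fraction = 0),
         pattern = list(axis = c(1, 0)), format_version = 1L),
    class = "rt_traj")
  d <- drift_speed(traj)
  expect_equal(d$v_drift, 0.07, tolerance = 1e-10)
})

test_that("density ratios are unity for uniform speed and track the masks", {
  pr <- cached("uniform_disc", {
    geo <- reference_geometry()
    cfg <- sim_config(L = geo$L, phi = 0.2, n_steps = 30000L,
                      save_every = 100L, interactions_on = FALSE)
    bead <- bead_spec(a = geo$a, mobile = FALSE)
    # disc present but speeds equal everywhere
    pat <- speed_pattern(1, 1, 1, R = geo$R, delta = 0)
    tr <- simulate_run(cfg, rod_params(), bead, pat, seed = 6)
    density_ratios(tr)
  })
  expect_lt(abs(pr$rho_minus_over_0 - 1), 0.12)
  expect_lt(abs(pr$rho_plus_over_0 - 1), 0.12)
})

test_that("non-interacting region densities follow the 1/v ideal-gas law", {
  dr <- cached("ideal_disc_ratio", {
    geo <- reference_geometry()
    v <- reference_speeds()
    cfg <- sim_config(L = geo$L, phi = 0.2, n_steps = 60000L,
                      save_every = 100L, interactions_on = FALSE)
    bead <- bead_spec(a = geo$a, mobile = FALSE)
    pat <- speed_pattern(v$v_minus, v$v_plus, v$v_zero, R = geo$R,
                         delta = 0)
    tr <- simulate_run(cfg, rod_params(), bead, pat, seed = 7)
    density_ratios(tr)
  })
  # rho- / rho0 -> v0 / v- = 17/7; boundary layers make this approximate
  expect_lt(abs(dr$rho_minus_over_0 - 17 / 7) / (17 / 7), 0.15)
  expect_lt(abs(dr$rho_plus_over_0 - 17 / 19) / (17 / 19), 0.15)
})

test_that("sweep tabulates drift and fits the phi dependence", {
  geo <- reference_geometry()
  v <- reference_speeds()
  cfg <- sim_config(L = 20, phi = 0.1, n_steps = 8000L, save_every = 200L)
  pat <- speed_pattern(v$v_minus, v$v_plus, v$v_zero, R = 6)
  out <- sweep_drift("phi", values = c(0.08, 0.2), n_runs = 2,
                     config = cfg, bead = bead_spec(a = 1.25),
                     pattern = pat, seed0 = 5, density_ratios_too = FALSE)
  expect_equal(nrow(out), 2)
  expect_true(all(c("value", "drift", "sem", "n_runs") %in% names(out)))
  expect_false(is.null(attr(out, "intercept_phi")))
  out2 <- sweep_drift("v_zero", values = c(0.8, 1.0), n_runs = 2,
                      config = cfg, bead = bead_spec(a = 1.25),
                      pattern = pat, seed0 = 6, density_ratios_too = FALSE)
  expect_equal(max(out2$drift_norm), 1)
})
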