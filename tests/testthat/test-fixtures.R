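test_that("fixtures regenerate bitwise-identically from the same seed", {
  a <- make_passive_gas(n = 15, L = 8, seed = 42)
  b <- make_passive_gas(n = 15, L = 8, seed = 42)
  expect_identical(a$positions, b$positions)
  expect_identical(a$angles, b$angles)
  c <- make_step_profile_gas(n = 50, v_left = 0.5, v_right = 1, L = 12,
                             seed = 42, n_steps = 200L)
  d <- make_step_profile_gas(n = 50, v_left = 0.5, v_right = 1, L = 12,
                             seed = 42, n_steps = 200L)
  expect_identical(c$positions, d$positions)
  e <- make_drift_synthetic(0.01, 0.1, 3, seed = 42)
  f <- make_drift_synthetic(0.01, 0.1, 3, seed = 42)
  expect_identical(e[[1]]$bead, f[[1]]$bead)
})

test_that("two separated passive rods exert no pressure", {
  rod <- rod_params(alpha = 0)
  pos <- array(0, dim = c(2, 2, 1))
  pos[1, , 1] <- c(2, 2); pos[2, , 1] <- c(6, 6)
  tr <- manual_traj(pos, matrix(0, 2, 1), L = 10, rod = rod)
  pd <- direct_pressure_map(tr, bin = 1)
  expect_equal(max(abs(pd$values)), 0)
})

test_that("step-profile gas keeps zero net flux across the interface", {
  tr <- cached("step_gas", {
    make_step_profile_gas(n = 500, v_left = 7 / 17, v_right = 1, L = 30,
                          seed = 11, n_steps = 60000L, dt = 0.01,
                          save_every = 200L)
  })
  frames <- post_transient_frames(tr)
  # in the steady state the left-half population is stationary: the mean
  # count in the first and second halves of the record must agree within
  # the block-to-block scatter (frames are autocorrelated, so compare
  # coarse block means rather than per-frame values)
  counts <- vapply(frames, function(f)
    sum(tr$positions[, 1, f] < tr$config$L / 2), numeric(1))
  blocks <- tapply(counts, cut(seq_along(counts), 10, labels = FALSE), mean)
  half1 <- mean(blocks[1:5]); half2 <- mean(blocks[6:10])
  scatter <- sd(blocks) / sqrt(5)
  expect_lt(abs(half1 - half2), 4 * scatter)
})

test_that("flat-wall gas pressure vanishes without activity and follows the ideal law", {
  still <- make_flat_wall_gas(rho = 0.2, v = 0, tau = 10, Lx = 20, Ly = 10,
                              seed = 5, n_steps = 2000L)
  expect_equal(still$pressure, 0)

  res <- cached("wall_gas", {
    make_flat_wall_gas(rho = 0.15, v = 1, tau = 5, Lx = 60, Ly = 20,
                       seed = 8, n_steps = 120000L, dt = 0.01)
  })
  ideal <- ideal_swim_pressure(rho = res$rho_bulk, v = 1, tau = 5)
  expect_lt(abs(res$pressure - ideal) / ideal, 0.2)

  # doubling the density doubles the pressure (non-interacting gas)
  res2 <- cached("wall_gas2", {
    make_flat_wall_gas(rho = 0.3, v = 1, tau = 5, Lx = 60, Ly = 20,
                       seed = 9, n_steps = 120000L, dt = 0.01)
  })
  expect_lt(abs(res2$pressure / res$pressure - 2), 0.3)
})
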