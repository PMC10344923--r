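test_that("placement produces non-overlapping rods at the requested packing", {
  rod <- rod_params()
  # empty state
  cfg0 <- sim_config(L = 20, N = 0)
  st0 <- initialize_rods(cfg0, rod)
  expect_equal(nrow(st0$positions), 0)
  # two rods: positive clearance
  set.seed(3)
  cfg2 <- sim_config(L = 20, N = 2)
  st2 <- initialize_rods(cfg2, rod)
  pf <- pair_force(st2$positions[1, ], st2$angles[1],
                   st2$positions[2, ], st2$angles[2], rod, 20)
  expect_false(pf$contact)
  # requested packing is recovered from the placed rods within 1 %
  set.seed(4)
  geo <- reference_geometry()
  cfg <- sim_config(L = geo$L, phi = 0.38, rod = rod)
  st <- initialize_rods(cfg, rod, bead_spec(a = geo$a, mobile = FALSE))
  phi_achieved <- nrow(st$positions) * rod_area(rod) / geo$L^2
  expect_lt(abs(phi_achieved - 0.38) / 0.38, 0.01)
  # no overlaps among placed rods (spot check on a random subset)
  idx <- sample(nrow(st$positions), 60)
  for (i in idx[1:30]) for (j in idx[31:60]) {
    if (i == j) next
    pf <- pair_force(st$positions[i, ], st$angles[i],
                     st$positions[j, ], st$angles[j], rod, geo$L)
    expect_false(pf$contact)
  }
  expect_error(initialize_rods(sim_config(L = 10, phi = 0.65), rod),
               "0.6")
})

test_that("pair forces obey Newton's third law for random configurations", {
  set.seed(11)
  rod <- rod_params()
  for (k in 1:200) {
    p <- random_rod_pair()
    pf <- pair_force(p$r1, p$th1, p$r2, p$th2, rod, 10)
    expect_identical(pf$f_i, -pf$f_j)
  }
  # rod-bead reaction
  for (k in 1:50) {
    r <- runif(2, 0, 10)
    bc <- r + runif(2, -2, 2)
    pf <- pair_force_bead(r, runif(1, 0, 2 * pi), bc %% 10, a = 1.25,
                          rod, 10)
    expect_identical(pf$f_i, -pf$f_bead)
  }
})

test_that("forces are zero beyond contact and match -grad U at contact", {
  rod <- rod_params()
  # separation beyond cutoff
  pf <- pair_force(c(1, 1), 0, c(3, 1), pi / 3, rod, 20)
  expect_false(pf$contact)
  expect_equal(pf$f_i, c(0, 0))
  expect_equal(pf$tau_i, 0)
  # central finite differences of the pair potential reproduce the force
  set.seed(21)
  eps <- 1e-6
  n_checked <- 0
  for (k in 1:400) {
    p <- random_rod_pair(spread = 0.8)
    pf <- pair_force(p$r1, p$th1, p$r2, p$th2, rod, 10)
    if (!pf$contact) next
    # skip configurations too close to contact onset or to degeneracy,
    # where U is not differentiable
    d <- rod$sigma - sqrt(sum(pf$f_i^2)) / rod$k_rep
    if (rod$sigma - d < 0.02 || d < 0.05) next
    n_checked <- n_checked + 1
    num <- numeric(2)
    for (c in 1:2) {
      dr <- c(0, 0); dr[c] <- eps
      num[c] <- -(pair_potential(p$r1 + dr, p$th1, p$r2, p$th2, rod, 10) -
                  pair_potential(p$r1 - dr, p$th1, p$r2, p$th2, rod, 10)) /
        (2 * eps)
    }
    expect_equal(num, pf$f_i, tolerance = 1e-5)
    # torque = -dU/dtheta
    numt <- -(pair_potential(p$r1, p$th1 + eps, p$r2, p$th2, rod, 10) -
              pair_potential(p$r1, p$th1 - eps, p$r2, p$th2, rod, 10)) /
      (2 * eps)
    expect_equal(numt, pf$tau_i, tolerance = 1e-5)
  }
  expect_gt(n_checked, 30)
})

test_that("tumbling has the prescribed rate and uniform resampling", {
  set.seed(5)
  alpha <- 0.1; dt <- 0.05
  n <- 2000; reps <- 50
  tumbled <- 0
  new_angles <- numeric(0)
  for (r in 1:reps) {
    th <- rep(1, n)
    th2 <- tumble_events(th, alpha, dt)
    hit <- th2 != 1
    tumbled <- tumbled + sum(hit)
    new_angles <- c(new_angles, th2[hit])
  }
  # expected rate alpha per unit time, within 3 binomial standard errors
  p <- 1 - exp(-alpha * dt)
  expect_lt(abs(tumbled - n * reps * p), 3 * sqrt(n * reps * p * (1 - p)))
  # resampled angles uniform on [0, 2pi): chi-square at the 1 % level
  h <- table(cut(new_angles, seq(0, 2 * pi, length.out = 11)))
  chi <- sum((h - length(new_angles) / 10)^2 / (length(new_angles) / 10))
  expect_lt(chi, qchisq(0.99, df = 9))
  # alpha = 0 leaves the state untouched
  expect_identical(tumble_events(rep(1, 10), 0, dt), rep(1, 10))
})

test_that("a free rod moves dt * v along its orientation", {
  rod <- rod_params(alpha = 0)  # no tumbling
  cfg <- sim_config(L = 20, N = 1, dt = 2e-3, n_steps = 1L,
                    save_every = 1L, rod = rod)
  th0 <- 0.7
  init <- list(positions = matrix(c(5, 5), 1), angles = th0)
  pat <- speed_pattern(0, 0, v_zero = 1, type = "uniform")
  tr <- simulate_run(cfg, rod, NULL, pat, init = init)
  expect_equal(tr$positions[1, , 2] - tr$positions[1, , 1],
               2e-3 * c(cos(th0), sin(th0)))
  expect_equal(tr$angles[1, 2], th0)
})

test_that("equal seeds give bitwise-identical trajectories", {
  cfg <- sim_config(L = 15, phi = 0.2, n_steps = 500L, save_every = 50L)
  pat <- speed_pattern(0.4, 1.2, 1, R = 5)
  bead <- bead_spec(a = 1, mobile = TRUE)
  t1 <- simulate_run(cfg, rod_params(), bead, pat, seed = 99)
  t2 <- simulate_run(cfg, rod_params(), bead, pat, seed = 99)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$angles, t2$angles)
  expect_identical(t1$bead, t2$bead)
  t3 <- simulate_run(cfg, rod_params(), bead, pat, seed = 100)
  expect_false(identical(t1$positions, t3$positions))
})

test_that("n_steps = 0 yields only the initial frame", {
  cfg <- sim_config(L = 15, phi = 0.1, n_steps = 0L)
  tr <- simulate_run(cfg, rod_params(), NULL,
                     speed_pattern(0, 0, 1, type = "uniform"), seed = 1)
  expect_equal(tr$n_frames, 1)
  expect_equal(tr$times, 0)
})

test_that("passive rods without overlaps never move, even while tumbling", {
  set.seed(8)
  rod <- rod_params(alpha = 0.1)
  cfg <- sim_config(L = 15, phi = 0.15, n_steps = 300L, save_every = 50L,
                    rod = rod)
  pat <- speed_pattern(0, 0, 0, type = "uniform")  # v = 0 everywhere
  tr <- simulate_run(cfg, rod, NULL, pat, seed = 12)
  expect_identical(tr$positions[, , 1], tr$positions[, , tr$n_frames])
})

test_that("with interactions off and uniform speed every rod moves at v exactly", {
  rod <- rod_params(alpha = 0)
  cfg <- sim_config(L = 15, phi = 0.3, n_steps = 50L, save_every = 1L,
                    interactions_on = FALSE, rod = rod)
  pat <- speed_pattern(0, 0, v_zero = 0.8, type = "uniform")
  tr <- simulate_run(cfg, rod, NULL, pat, seed = 2)
  d <- tr$positions[, , 2] - tr$positions[, , 1]
  d <- d - 15 * round(d / 15)  # min image
  speeds <- sqrt(rowSums(d^2)) / (cfg$dt * cfg$save_every)
  expect_equal(speeds, rep(0.8, cfg$N), tolerance = 1e-12)
})

test_that("interactions off keeps the bead impenetrable to rods", {
  set.seed(31)
  geo <- reference_geometry()
  cfg <- sim_config(L = 20, phi = 0.25, n_steps = 4000L, save_every = 200L,
                    interactions_on = FALSE)
  bead <- bead_spec(a = 2, mobile = FALSE)
  pat <- speed_pattern(0.4, 1.2, 1, R = 8)
  tr <- simulate_run(cfg, rod_params(), bead, pat, seed = 17)
  # no rod centre ends up closer than a (bead surface minus cap radius
  # would be a + sigma/2 at contact; deep penetration would be < a)
  for (f in seq_len(tr$n_frames)) {
    dx <- tr$positions[, 1, f] - tr$bead[1, f]
    dy <- tr$positions[, 2, f] - tr$bead[2, f]
    dx <- dx - 20 * round(dx / 20); dy <- dy - 20 * round(dy / 20)
    expect_gt(min(sqrt(dx^2 + dy^2)), tr$bead_spec$a)
  }
})

test_that("the stability guard aborts runs with excessive displacement", {
  rod <- rod_params(alpha = 0, k_rep = 1e5)  # absurdly stiff contacts
  cfg <- sim_config(L = 10, N = 30, dt = 2e-3, n_steps = 2000L, rod = rod)
  pat <- speed_pattern(0, 0, 1, type = "uniform")
  expect_error(
    simulate_run(cfg, rod, NULL, pat, seed = 5, contact_scale = 0.5),
    "unstable")
})

test_that("internal rod-rod forces sum to zero over a crowded frame", {
  set.seed(19)
  rod <- rod_params()
  cfg <- sim_config(L = 12, phi = 0.35, rod = rod)
  st <- initialize_rods(cfg, rod, contact_scale = 0.7)
  n <- nrow(st$positions)
  tot <- c(0, 0)
  any_contact <- FALSE
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    pf <- pair_force(st$positions[i, ], st$angles[i],
                     st$positions[j, ], st$angles[j], rod, 12,
                     idx = c(i - 1L, j - 1L))
    tot <- tot + pf$f_i + pf$f_j
    any_contact <- any_contact || pf$contact
  }
  expect_true(any_contact)
  expect_equal(tot, c(0, 0))
})
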