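test_that("velocity-Verlet: free flight is exact, oscillator energy is bounded, trajectory reverses", {
  # zero forces: straight-line motion
  sys <- particle_system(matrix(2, 2, 3), c(1, 1), c(10, 10, 10), masses = 1)
  sys$velocities <- matrix(c(0.3, -0.1, 0.2, 0.05, 0, -0.4), 2, 3)
  zero <- function(s) list(forces = matrix(0, 2, 3))
  st <- list(system = sys, forces = NULL)
  for (i in 1:100) st <- velocity_verlet_step(st$system, zero, 0.05,
                                              forces = st$forces)
  expect_lt(max(periodic_dist(st$system$positions,
                              wrap_positions(sys$positions +
                                               5 * sys$velocities, sys$box),
                              sys$box)), 1e-10)
  # 1-d harmonic oscillator at omega dt = 0.01: bounded error, no drift
  osc <- particle_system(matrix(5, 1, 3), 1L, c(10, 10, 10), masses = 1)
  osc$velocities[1, 1] <- 0.3
  k <- 100
  prov <- function(s) list(forces = matrix(c(-k * (s$positions[1, 1] - 5), 0, 0),
                                           1, 3))
  efun <- function(s) 0.5 * sum(s$velocities^2) +
    0.5 * k * (s$positions[1, 1] - 5)^2
  e0 <- efun(osc)
  st <- list(system = osc, forces = NULL)
  errs <- numeric(0)
  for (i in 1:50000) {
    st <- velocity_verlet_step(st$system, prov, 0.001, forces = st$forces)
    if (i %% 500 == 0) errs <- c(errs, abs(efun(st$system) - e0) / e0)
  }
  expect_lt(max(errs), 1e-4)                     # bounded, O((w dt)^2)
  expect_lt(abs(mean(tail(errs, 10)) - mean(head(errs, 10))), 5e-5)  # no drift
  # reversibility
  back <- st$system
  back$velocities <- -back$velocities
  stb <- list(system = back, forces = NULL)
  for (i in 1:50000) stb <- velocity_verlet_step(stb$system, prov, 0.001,
                                                 forces = stb$forces)
  expect_lt(abs(stb$system$positions[1, 1] - osc$positions[1, 1]), 1e-9)
  # non-finite forces abort with a diagnostic
  bad <- function(s) list(forces = matrix(NaN, 1, 3))
  expect_error(velocity_verlet_step(osc, bad, 0.001), "non-finite")
})

test_that("CSVR thermostat: NVE limit, canonical mean, determinism", {
  set.seed(20)
  n <- 50
  sys <- particle_system(matrix(runif(3 * n), n, 3), rep(1, n), c(3, 3, 3),
                         masses = 72)
  sys <- maxwell_velocities(sys, 300)
  # tau -> infinity: rescale factor -> 1
  s2 <- csvr_thermostat_step(sys, 323, tau = 1e12, dt = 0.1)
  expect_equal(attr(s2, "alpha"), 1, tolerance = 1e-5)
  # preserves zero net momentum
  expect_equal(max(abs(net_momentum(s2))), 0, tolerance = 1e-9)
  # deterministic given the RNG state
  set.seed(99)
  a <- csvr_thermostat_step(sys, 323, 0.1, 0.1)
  set.seed(99)
  b <- csvr_thermostat_step(sys, 323, 0.1, 0.1)
  expect_identical(a$velocities, b$velocities)
  expect_error(csvr_thermostat_step(sys, 323, tau = -1, dt = 0.1), "tau")
})

test_that("run configuration enforces its invariants", {
  cfg <- run_config(inner_dt = 0.01, field_update_time = 0.2, n_outer = 10)
  expect_identical(cfg$n_inner, 20L)
  expect_equal(cfg$field_update_time, 0.2)
  expect_error(run_config(inner_dt = 0.01, field_update_time = 0.015),
               "integer multiple")
  expect_error(run_config(n_inner = 0, n_outer = 1), "n_inner")
  expect_error(run_config(n_inner = 1, ensemble = "nvt", tau = 0),
               "tau")
  expect_error(run_config(n_inner = 1,
                          sigma_schedule = data.frame(time = c(2, 1),
                                                      sigma = c(1, 2))),
               "non-decreasing")
})

test_that("runs are deterministic: identical seeds give bitwise-identical trajectories", {
  fx <- build_homopolymer_melt(n_chains = 8, chain_length = 10, box = 2.5,
                               seed = 3)
  m <- interaction_model(matrix(0, 1, 1), kappa_inv = 2.4, sigma = 0.4,
                         phi0 = compute_phi0(fx$system), species = "HP")
  msh <- mesh(rep(12, 3), fx$system$box)
  cfg <- run_config(inner_dt = 0.01, n_inner = 5, n_outer = 20,
                    ensemble = "nvt", target_T = 323, seed = 77)
  r1 <- run_hhpf(fx$system, fx$topology, m, msh, cfg)
  r2 <- run_hhpf(fx$system, fx$topology, m, msh, cfg)
  expect_identical(r1$system$positions, r2$system$positions)
  expect_identical(r1$system$velocities, r2$system$velocities)
  expect_identical(r1$ledger$total, r2$ledger$total)
  cfg2 <- cfg
  cfg2$seed <- 78L
  r3 <- run_hhpf(fx$system, fx$topology, m, msh, cfg2)
  expect_false(identical(r1$system$positions, r3$system$positions))
})

test_that("the energy ledger is consistent and the run object prints", {
  fx <- build_homopolymer_melt(n_chains = 8, chain_length = 10, box = 2.5,
                               seed = 3)
  m <- interaction_model(matrix(0, 1, 1), kappa_inv = 2.4, sigma = 0.4,
                         phi0 = compute_phi0(fx$system), species = "HP")
  msh <- mesh(rep(12, 3), fx$system$box)
  run <- run_hhpf(fx$system, fx$topology, m, msh,
                  run_config(n_inner = 5, n_outer = 10, seed = 1,
                             store_trajectory = 5))
  l <- run$ledger
  expect_equal(l$total,
               l$kinetic + l$field + l$electrostatic + l$bonded,
               tolerance = 1e-12)
  expect_equal(nrow(l), 11)
  expect_length(run$trajectory, 3)
  expect_output(print(run), "hhpf_run")
  expect_output(print(summary(run)), "total energy")
})

test_that("on-the-fly filter-width schedules interpolate linearly", {
  fx <- build_homopolymer_melt(n_chains = 8, chain_length = 10, box = 2.5,
                               seed = 3)
  m <- interaction_model(matrix(0, 1, 1), kappa_inv = 2.4, sigma = 0.8,
                         phi0 = compute_phi0(fx$system), species = "HP")
  msh <- mesh(rep(12, 3), fx$system$box)
  sched <- data.frame(time = c(0, 0.5), sigma = c(0.8, 0.4))
  run <- run_hhpf(fx$system, fx$topology, m, msh,
                  run_config(n_inner = 5, n_outer = 10, seed = 1,
                             sigma_schedule = sched))
  expect_equal(run$final_sigma, 0.4, tolerance = 1e-10)
  # midpoint of the ramp
  run2 <- run_hhpf(fx$system, fx$topology, m, msh,
                   run_config(n_inner = 5, n_outer = 6, seed = 1,
                              sigma_schedule = sched))
  expect_equal(run2$final_sigma, 0.8 + (0.4 - 0.8) * 0.3 / 0.5,
               tolerance = 1e-10)
})

test_that("single-precision mode degrades but does not destroy conservation", {
  fx <- build_homopolymer_melt(n_chains = 10, chain_length = 10, box = 2.5,
                               seed = 4)
  m <- interaction_model(matrix(0, 1, 1), kappa_inv = 2.4, sigma = 0.4,
                         phi0 = compute_phi0(fx$system), species = "HP")
  msh <- mesh(rep(12, 3), fx$system$box)
  rs <- run_hhpf(fx$system, fx$topology, m, msh,
                 run_config(n_inner = 5, n_outer = 50, seed = 2,
                            precision = "single"))
  # positions really are float32-representable
  p <- rs$system$positions
  expect_identical(p, hhpfmd:::.to_single(p))
  expect_true(all(is.finite(rs$ledger$total)))
})
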