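test_that("system state validates dimensions and masses", {
  expect_error(new_system_state(1:3, velocities = 1:2), "dimensions")
  expect_error(new_system_state(1, masses = 0), "positive")
  st <- new_system_state(rep(0, 6), masses = c(10, 14))
  expect_equal(st$masses, rep(c(10, 14), each = 3))
})

test_that("zero-friction BAOAB conserves energy (NVE) and is deterministic", {
  h <- make_harmonic(k_spring = 1)
  st <- new_system_state(0.5, masses = 12)
  tr <- run_cmd(h, st, n_steps = 10000, save_interval = 10, dt = 0.001,
                friction = 0, temperature = 0, seed = 1,
                record_velocities = TRUE)
  Etot <- tr$V_total +
    0.5 * 12 * tr$velocities[, 1]^2 / gamdtk:::KCAL_PER_MOL_TO_AKMA
  E0 <- h$energy(0.5)
  expect_lt(max(abs(Etot - E0)), 1e-4)

  tr2 <- run_cmd(h, st, n_steps = 500, save_interval = 10, dt = 0.002,
                 friction = 2, temperature = 310, seed = 42)
  tr3 <- run_cmd(h, st, n_steps = 500, save_interval = 10, dt = 0.002,
                 friction = 2, temperature = 310, seed = 42)
  expect_identical(tr2$coords, tr3$coords)
  expect_identical(tr2$V_total, tr3$V_total)
})

test_that("Langevin thermostat reproduces equipartition and the Boltzmann density", {
  # 5 independent harmonic modes: velocity variance kBT/m within 2%
  pot <- make_separable_harmonic(k_spring = 1, dof = 5)
  st <- new_system_state(rep(0, 5), masses = 1)
  tr <- run_cmd(pot, st, n_steps = 2e5, save_interval = 50, dt = 0.002,
                friction = 10, temperature = 310, seed = 7,
                record_velocities = TRUE)
  v2 <- mean(tr$velocities^2)
  expect_equal(v2, kBT(310) * gamdtk:::KCAL_PER_MOL_TO_AKMA / 1,
               tolerance = 0.02)

  # positions: Kolmogorov-Smirnov against the exact Gaussian density
  x <- as.numeric(tr$coords[seq(1, nrow(tr$coords), by = 4), ])
  ks <- suppressWarnings(
    ks.test(x, "pnorm", sd = sqrt(kBT(310) / 1)))
  expect_gt(ks$p.value, 0.01)
})

test_that("minimizer: convergence, fixed point, no barrier crossing", {
  h <- make_harmonic(k_spring = 3, center = 0.7)
  st <- new_system_state(-4, masses = 12)
  out <- minimize(h, st, steepest_steps = 200, conj_grad_steps = 200)
  expect_lt(abs(out$coords - 0.7), 1e-4)

  out2 <- minimize(h, out, steepest_steps = 50, conj_grad_steps = 50)
  expect_lt(abs(attr(out2, "energy") - attr(out, "energy")), 1e-8)

  # start left of the barrier: gradient descent cannot cross it
  dw <- make_double_well(6, 2, 0)
  m <- minimize(dw, new_system_state(-0.25, masses = 12), 500, 500)
  # gradient-flow oracle from the same start (small fixed steps)
  x <- -0.25
  for (i in 1:20000) x <- x - 1e-3 * dw$gradient(x)
  expect_equal(m$coords, x, tolerance = 1e-3)
  expect_lt(m$coords, 0)
})

test_that("minimizer on the bead chain reaches a stationary point", {
  bc <- make_bead_chain(6)
  pot <- bead_chain_potential(bc)
  set.seed(2)
  x0 <- bead_chain_extended(bc) + rnorm(18, sd = 0.15)
  st <- new_system_state(x0, masses = rep(12, 18))
  out <- minimize(pot, st, 500, 2000, grad_tol = 1e-6)
  expect_lt(attr(out, "energy"), pot$energy(x0))
  expect_lt(attr(out, "grad_norm"), 1e-3)
})

test_that("run_cmd bookkeeping: frame counts, zero boost, statistics", {
  h <- make_harmonic()
  st <- new_system_state(0, masses = 12)
  tr <- run_cmd(h, st, n_steps = 100, save_interval = 100, seed = 1)
  expect_identical(n_frames(tr), 1L)
  tr2 <- run_cmd(h, st, n_steps = 100, save_interval = 100, seed = 1,
                 record_initial = TRUE)
  expect_identical(n_frames(tr2), 2L)
  expect_true(all(boost_series(tr2) == 0))
  expect_error(run_cmd(h, st, n_steps = 10, save_interval = 100), ">=")

  st3 <- maxwell_velocities({set.seed(5); new_system_state(0, masses = 12)}, 310)
  tr3 <- run_cmd(h, st3, n_steps = 20000, save_interval = 10, seed = 5)
  es <- tr3$metadata$energy_stats
  # streaming statistics agree with a two-pass recomputation over the
  # same per-step energies (recompute from a rerun with save_interval 1)
  tr4 <- run_cmd(h, st3, n_steps = 20000, save_interval = 1, seed = 5)
  expect_equal(es$V_max, max(tr4$V_total), tolerance = 1e-12)
  expect_equal(es$V_min, min(tr4$V_total), tolerance = 1e-12)
  expect_equal(es$V_avg, mean(tr4$V_total), tolerance = 1e-10)
  expect_equal(es$sigma_V, sqrt(mean((tr4$V_total - mean(tr4$V_total))^2)),
               tolerance = 1e-8)
})

test_that("harmonic positional restraints give the closed-form displacement variance", {
  flat <- make_flat_potential(dof = 3)
  ref <- c(0, 0, 0)
  st <- new_system_state(ref, masses = 12)
  tr <- run_cmd(flat, st, n_steps = 2e5, save_interval = 100, dt = 0.002,
                friction = 2, temperature = 310,
                restraints = list(k = 1, ref = ref), seed = 9)
  msd <- mean(tr$coords^2)
  expect_equal(msd, kBT(310) / 2, tolerance = 0.1)
})

test_that("double-well cMD at 310 K stays in the starting well over a short run", {
  dw <- make_double_well(6, 2, 2)
  set.seed(3)
  st <- maxwell_velocities(new_system_state(-1, masses = 12), 310)
  tr <- run_cmd(dw, st, n_steps = 20000, save_interval = 10,
                temperature = 310, seed = 3)
  expect_gt(mean(tr$coords[, 1] < 0), 0.95)
})

test_that("heat ramp: degenerate ramp equals constant-T cMD; target reached; restraint bound", {
  h <- make_separable_harmonic(1, 3)
  st <- new_system_state(c(0.2, -0.1, 0.4), masses = 12)
  s1 <- heat_ramp(h, st, 310, 310, n_steps = 2000, seed = 11)
  tr <- run_cmd(h, st, n_steps = 2000, save_interval = 100, seed = 11)
  s2 <- tr$metadata$final_state
  expect_identical(s1$coords, s2$coords)
  expect_identical(s1$velocities, s2$velocities)

  bc <- make_bead_chain(6)
  pot <- bead_chain_potential(bc)
  x0 <- bead_chain_extended(bc)
  st0 <- new_system_state(x0, masses = rep(12, 18))
  restr <- list(k = 1, ref = x0)
  sf <- heat_ramp(pot, st0, 0, 310, n_steps = 10000, restraints = restr,
                  seed = 13)
  # kinetic temperature averaged over a short post-ramp window
  trw <- run_cmd(pot, sf, n_steps = 5000, save_interval = 10,
                 temperature = 310, restraints = restr, seed = 14,
                 record_velocities = TRUE)
  Tkin <- mean(trw$velocities^2 * rep(12, 18)[col(trw$velocities)]) /
    (kB * gamdtk:::KCAL_PER_MOL_TO_AKMA)
  expect_equal(Tkin, 310, tolerance = 0.15)
  # Gaussian tail bound on restrained displacement
  disp <- abs(sweep(trw$coords, 2, x0))
  expect_lt(max(disp), 5 * sqrt(kBT(310) / 1))
})

test_that("trajectory tables round-trip at the declared precision", {
  h <- make_harmonic()
  st <- maxwell_velocities({set.seed(1); new_system_state(0.3, masses = 12)}, 310)
  tr <- run_cmd(h, st, n_steps = 2000, save_interval = 100, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_trajectory_table(tr, path)
  tr2 <- read_trajectory_table(path)
  expect_equal(unname(tr2$coords), unname(tr$coords), tolerance = 1e-10)
  expect_equal(tr2$V_total, tr$V_total, tolerance = 1e-10)
  expect_equal(tr2$time, tr$time, tolerance = 1e-10)
  expect_equal(tr2$metadata$temperature, 310)
})

test_that("trajectory invariants are enforced", {
  expect_error(new_trajectory(c(1, 1), matrix(0, 2, 1)), "increasing")
  expect_error(new_trajectory(1:2, matrix(0, 2, 1),
                              dV_total = c(-1, 0)), "non-negative")
})
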