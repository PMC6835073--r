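test_that("energy statistics stream correctly and match two-pass moments", {
  s <- update_stats(new_energy_stats(), c(1, 2, 3))
  expect_equal(s$V_max, 3); expect_equal(s$V_min, 1)
  expect_equal(s$V_avg, 2)
  expect_equal(s$sigma_V, sqrt(2 / 3))  # population convention
  expect_equal(s$n_samples, 3)

  s1 <- update_stats(new_energy_stats(), 5)
  expect_equal(s1$sigma_V, 0)
  expect_error(update_stats(new_energy_stats(), NaN), "non-finite")

  set.seed(1)
  v <- rnorm(1e6, mean = -250, sd = 4)
  ss <- update_stats(new_energy_stats(), v)
  expect_equal(ss$V_avg, mean(v), tolerance = 1e-10)
  expect_equal(ss$sigma_V, sqrt(mean((v - mean(v))^2)), tolerance = 1e-10)
  expect_identical(ss$V_max, max(v))
  expect_identical(ss$V_min, min(v))
})

test_that("boost parameter selection follows the sigma-0 criterion", {
  # hand-evaluated lower-bound case
  st <- new_energy_stats(V_max = 100, V_min = 0, V_avg = 80, sigma_V = 5,
                         n_samples = 1000)
  p <- compute_params(st, sigma_0 = 10, bound_mode = "lower")
  expect_equal(p$k0, 1)
  expect_equal(p$k, 0.01)
  expect_equal(p$E, 100)

  # large sigma_0 limit: maximum acceleration
  p2 <- compute_params(st, sigma_0 = 1e9, bound_mode = "lower")
  expect_equal(p2$k0, 1)

  # k0 < 1 when sigma_V is large relative to sigma_0
  st3 <- new_energy_stats(100, 0, 50, sigma_V = 40, n_samples = 1000)
  p3 <- compute_params(st3, sigma_0 = 6, bound_mode = "lower")
  expect_equal(p3$k0, (6 / 40) * (100 - 0) / (100 - 50))
  expect_lt(p3$k0, 1)

  # degenerate V_avg == V_max: capped at 1
  st4 <- new_energy_stats(100, 0, 100, sigma_V = 5, n_samples = 10)
  expect_equal(compute_params(st4, 6, "lower")$k0, 1)

  # errors: flat energy, zero fluctuation
  expect_error(compute_params(new_energy_stats(5, 5, 5, 0, 10), 6),
               "flat energy")
  expect_error(compute_params(new_energy_stats(10, 0, 5, 0, 10), 6),
               "zero energy fluctuation")
})

test_that("upper-bound threshold satisfies E = V_min + 1/k, with fallback", {
  # sigma_0 < sigma_V makes the upper-bound relation attainable
  st <- new_energy_stats(V_max = 100, V_min = 0, V_avg = 80, sigma_V = 10,
                         n_samples = 1000)
  p <- compute_params(st, sigma_0 = 2, bound_mode = "upper")
  expect_equal(p$bound_mode, "upper")
  expect_equal(p$E, p$stats$V_min + 1 / p$k)
  expect_equal(p$k0, (1 - 2 / 10) * (100 - 0) / (80 - 0))
  # sigma_0 >= sigma_V: upper bound unattainable, falls back to lower
  p2 <- compute_params(st, sigma_0 = 20, bound_mode = "upper")
  expect_equal(p2$bound_mode, "lower")
  expect_equal(p2$E, 100)
})

test_that("boost energy and force factor obey the harmonic-boost algebra", {
  st <- new_energy_stats(100, 0, 80, 5, 1000)
  p <- compute_params(st, 10, "lower")  # E = 100, k = 0.01
  expect_equal(boost_energy(p, 100), 0)
  expect_equal(boost_energy(p, 99), 0.005)
  expect_equal(boost_energy(p, 150), 0)
  expect_equal(boost_force_factor(p, 150), 1)
  expect_equal(boost_force_factor(p, p$stats$V_min), 1 - p$k0)

  # modified potential non-decreasing over [V_min, V_max]
  V <- seq(0, 100, length.out = 2000)
  Vstar <- V + boost_energy(p, V)
  expect_true(all(diff(Vstar) >= 0))
  # dV = 0 iff V >= E
  dV <- boost_energy(p, V)
  expect_true(all((dV == 0) == (V >= p$E)))
})

test_that("force factor equals the derivative of the boosted energy", {
  set.seed(21)
  for (i in 1:20) {
    vmin <- runif(1, -100, 0)
    vmax <- vmin + runif(1, 1, 100)
    vavg <- runif(1, vmin, vmax)
    sv <- runif(1, 0.1, 10)
    p <- compute_params(new_energy_stats(vmax, vmin, vavg, sv, 100),
                        sigma_0 = runif(1, 0.5, 12),
                        bound_mode = sample(c("lower", "upper"), 1))
    V <- runif(20, vmin, vmax)
    h <- 1e-6
    fd <- ((V + h + boost_energy(p, V + h)) -
             (V - h + boost_energy(p, V - h))) / (2 * h)
    expect_equal(boost_force_factor(p, V), fd, tolerance = 1e-6)
  }
})

test_that("boosted forces on the bead chain equal factor times plain forces", {
  bc <- make_bead_chain(5)
  pot <- bead_chain_potential(bc)
  set.seed(6)
  x <- bead_chain_extended(bc) + rnorm(15, sd = 0.2)
  V <- pot$energy(x)
  st <- update_stats(new_energy_stats(),
                     V + c(-0.5, 0.3, 2.5, 4, -1.2))
  p <- compute_params(st, sigma_0 = 6, bound_mode = "lower")
  fac <- boost_force_factor(p, V)
  # numerical gradient of V(x) + dV(V(x)) vs factor * analytic gradient
  gb <- num_grad(function(y) {
    vy <- pot$energy(y); vy + boost_energy(p, vy)
  }, x)
  expect_equal(gb, fac * pot$gradient(x), tolerance = 1e-5)
})

test_that("near-zero boost is statistically indistinguishable from cMD", {
  h <- make_harmonic(1)
  p <- structure(list(bound_mode = "lower", component = "total",
                      E = 100, k = 1e-12, k0 = 1e-10, sigma_0 = 6,
                      stats = new_energy_stats(100, 0, 50, 5, 100)),
                 class = "gamd_params")
  set.seed(31)
  st <- maxwell_velocities(new_system_state(0, masses = 12), 310)
  # sampling thinned to ~2 correlation times so KS is valid
  trb <- run_gamd(h, st, params = list(class = "total", total = p),
                  n_steps = 4e5, save_interval = 1000, friction = 2,
                  boost_class = "total", seed = 101)
  trc <- run_cmd(h, st, n_steps = 4e5, save_interval = 1000, friction = 2,
                 seed = 202)
  ks <- suppressWarnings(ks.test(trb$V_total, trc$V_total))
  expect_gt(ks$p.value, 0.01)
  expect_lt(max(boost_series(trb)), 1e-8)
})

test_that("boost accelerates barrier crossing and respects the sigma-0 cap", {
  dw <- make_double_well(6, 2, 2)
  st0 <- new_system_state(-1, masses = 12)
  proto <- run_protocol(dw, st0, schedule = list(
    min_sd = 100, min_cg = 100, heat_steps = 1000, eq_steps = 1000,
    cmd_stats_steps = 3000, gamd_eq_steps = 60000, n_production = 1,
    prod_steps = 60000), boost_class = "total", seed = 3)
  gx <- count_crossings(proto$production[[1]])
  set.seed(77)
  stc <- maxwell_velocities(proto$state0, 310)
  cx <- count_crossings(run_cmd(dw, stc, 60000, 100, seed = 77))
  expect_gte(gx, cx)
  sdv <- sd(boost_series(proto$production[[1]]))
  expect_lte(sdv, 1.2 * 6)
})

test_that("dual boost on the bead chain records additive non-negative components", {
  bc <- make_bead_chain(5)
  pot <- bead_chain_potential(bc)
  st0 <- new_system_state(bead_chain_extended(bc), masses = rep(12, 15))
  proto <- run_protocol(pot, st0, schedule = list(
    min_sd = 100, min_cg = 200, heat_steps = 500, eq_steps = 500,
    cmd_stats_steps = 2000, gamd_eq_steps = 3000, n_production = 2,
    prod_steps = 2000), boost_class = "dual", seed = 5)
  expect_identical(proto$params$class, "dual")
  tr <- proto$production[[1]]
  expect_true(all(tr$dV_total >= 0))
  expect_true(all(tr$dV_dihedral >= 0))
  expect_gt(mean(tr$dV_dihedral), 0)
  expect_gt(mean(tr$dV_total), 0)
  # recorded components reproduce the frozen-parameter formulas
  expect_equal(tr$dV_total,
               boost_energy(proto$params$total, tr$V_total),
               tolerance = 1e-10)
  expect_equal(tr$dV_dihedral,
               boost_energy(proto$params$dihedral, tr$V_dihedral),
               tolerance = 1e-10)
})

test_that("staged protocol: run count, seed determinism, pass-through params", {
  dw <- make_double_well(5, 2, 1)
  st0 <- new_system_state(-1, masses = 12)
  sched <- list(min_sd = 50, min_cg = 50, heat_steps = 500, eq_steps = 500,
                cmd_stats_steps = 2000, gamd_eq_steps = 2000,
                n_production = 4, prod_steps = 2000)
  proto <- run_protocol(dw, st0, schedule = sched, boost_class = "total",
                        seed = 9)
  expect_length(proto$production, 4)
  seeds <- vapply(proto$production, function(tr) tr$metadata$seed, 0)
  expect_length(unique(seeds), 4)

  proto2 <- run_protocol(dw, st0, schedule = sched, boost_class = "total",
                         seed = 9)
  for (i in 1:4) {
    expect_identical(proto$production[[i]]$coords,
                     proto2$production[[i]]$coords)
  }

  # gamd_eq_steps = 0: production uses the cMD-statistics params verbatim
  sched0 <- sched; sched0$gamd_eq_steps <- 0
  proto3 <- run_protocol(dw, st0, schedule = sched0, boost_class = "total",
                         seed = 9)
  cmd_stats <- proto3$cmd$metadata$energy_stats
  expect_equal(proto3$params$total$E, cmd_stats$V_max)
  expect_equal(proto3$params$total$k0,
               compute_params(cmd_stats, 6, "lower")$k0)

  expect_error(run_protocol(dw, st0, schedule = sched[-1],
                            boost_class = "total", seed = 1), "min_sd")
})

test_that("gamd run requires parameters or adaptive statistics", {
  h <- make_harmonic()
  st <- new_system_state(0, masses = 12)
  expect_error(run_gamd(h, st, params = NULL, n_steps = 100,
                        adaptive = FALSE, boost_class = "total"),
               "adaptive")
})
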