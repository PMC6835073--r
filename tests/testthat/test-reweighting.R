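make_traj <- function(x, dV, temp = 310, label = "run1") {
  new_trajectory(time = seq_along(x), coords = matrix(x, ncol = 1),
                 dV_total = dV,
                 metadata = list(temperature = temp, label = label))
}

test_that("combine_runs pools frames, keeps provenance, validates temperature", {
  trs <- lapply(1:4, function(i) {
    make_traj(rnorm(50), rep(0.1, 50), label = sprintf("p%d", i))
  })
  s <- combine_runs(trs)
  expect_length(s$dV, 200)
  expect_identical(as.character(sort(unique(s$run))), sprintf("p%d", 1:4))

  expect_warning(
    s2 <- combine_runs(list(trs[[1]],
                            make_traj(numeric(0), numeric(0), label = "e"))),
    "no frames")
  expect_length(s2$dV, 50)

  trs[[2]]$metadata$temperature <- 350
  expect_error(combine_runs(trs), "temperature mismatch")

  # permuting run order leaves the PMF unchanged
  set.seed(2)
  trs3 <- lapply(1:3, function(i) make_traj(rnorm(300), runif(300),
                                            label = sprintf("r%d", i)))
  e <- seq(-3, 3, 0.5)
  p1 <- pmf_exponential(combine_runs(trs3), e)
  p2 <- pmf_exponential(combine_runs(trs3[c(3, 1, 2)]), e)
  expect_equal(p1$values, p2$values, tolerance = 1e-12)
})

test_that("unweighted PMF: degenerate bin, Gaussian curvature, count invariance", {
  s1 <- new_weighted_samples(rep(0.25, 100), rep(0, 100), 310)
  p <- pmf_unweighted(s1, seq(0, 1, 0.5))
  expect_equal(as.numeric(p$values[1]), 0)
  expect_true(is.na(p$values[2]))

  set.seed(8)
  x <- rnorm(2e5, sd = 0.5)
  s <- new_weighted_samples(x, rep(0, 2e5), 310)
  edges <- seq(-1, 1, by = 0.05)
  pm <- pmf_unweighted(s, edges)
  mids <- pmf_midpoints(pm)[[1]]
  fit <- lm(as.numeric(pm$values) ~ I(mids^2))
  curv <- 2 * coef(fit)[[2]]
  expect_equal(curv, kBT(310) / 0.25, tolerance = 0.05)

  # doubling all counts: identical PMF (density normalization)
  s2 <- new_weighted_samples(c(x, x), rep(0, 4e5), 310)
  pm2 <- pmf_unweighted(s2, edges)
  expect_equal(pm2$values, pm$values, tolerance = 1e-12)
})

test_that("exponential reweighting equals brute-force importance weighting", {
  # hand-checkable two-bin case
  x <- c(0.2, 0.3, 0.7, 0.8, 0.9)
  dV <- c(1, 2, 0.5, 0, 1.5)
  s <- new_weighted_samples(x, dV, 310)
  p <- pmf_exponential(s, c(0, 0.5, 1))
  b <- s$beta
  w1 <- sum(exp(b * dV[1:2])); w2 <- sum(exp(b * dV[3:5]))
  expected <- -log(c(w1, w2) / 0.5) / b
  expected <- expected - min(expected)
  expect_equal(as.numeric(p$values), expected, tolerance = 1e-12)

  # property: equality to brute force on random inputs, incl. huge dV
  set.seed(5)
  for (rep in 1:10) {
    n <- 500
    x <- runif(n, 0, 4)
    dV <- rexp(n, rate = 1 / 20)  # large boosts: stresses log-sum-exp
    s <- new_weighted_samples(x, dV, 310)
    edges <- seq(0, 4, 0.5)
    p <- pmf_exponential(s, edges)
    w <- exp(s$beta * (dV - max(dV)))
    bins <- findInterval(x, edges, rightmost.closed = TRUE)
    brute <- -log(vapply(seq_len(8), function(b) sum(w[bins == b]), 0) /
                    0.5) / s$beta
    brute[!is.finite(brute)] <- NA
    brute <- brute - min(brute, na.rm = TRUE)
    expect_equal(as.numeric(p$values), brute, tolerance = 1e-10)
  }

  # null boost: identical to the unweighted PMF
  s0 <- new_weighted_samples(runif(200), rep(0, 200), 310)
  e <- seq(0, 1, 0.25)
  expect_equal(pmf_exponential(s0, e)$values, pmf_unweighted(s0, e)$values,
               tolerance = 1e-12)
})

test_that("cumulant expansion: Gaussian closed form, constant shift, vanishing C3", {
  set.seed(12)
  n <- 1e5
  # two bins; bin A Gaussian boost, bin B zero boost
  x <- c(rep(0.25, n), rep(0.75, n))
  mu <- 3; sg <- 0.6
  dV <- c(pmax(rnorm(n, mu, sg), 0), rep(0, n))  # truncation mass ~ 0
  s <- new_weighted_samples(x, dV, 310)
  edges <- c(0, 0.5, 1)
  b <- s$beta
  p2 <- pmf_cumulant(s, edges, order = 2)
  # exact Gaussian factor: ln<e^{b dV}> = b mu + b^2 s^2 / 2
  closed <- (b * mu + b^2 * sg^2 / 2) / b  # kcal/mol shift of bin A
  diffA <- as.numeric(p2$values[2] - p2$values[1])
  expect_equal(diffA, closed, tolerance = 0.02)
  pe <- pmf_exponential(s, edges)
  expect_equal(as.numeric(pe$values[2] - pe$values[1]), closed,
               tolerance = 0.03)

  # order 1 on constant dV: pure shift, shape unchanged
  set.seed(3)
  xs <- rnorm(5000)
  sc <- new_weighted_samples(xs, rep(3, 5000), 310)
  e2 <- seq(-3, 3, 0.5)
  expect_equal(pmf_cumulant(sc, e2, order = 1)$values,
               pmf_unweighted(sc, e2, min_count = 10)$values,
               tolerance = 1e-10)
  expect_equal(pmf_cumulant(sc, e2, order = 1)$values,
               pmf_cumulant(sc, e2, order = 2)$values, tolerance = 1e-10)

  # order 3 reduces to order 2 when the third central moment vanishes
  xb <- rep(c(0.25, 0.75), each = 1000)
  dVs <- rep(c(1.5, 2.5), 500)  # symmetric two-point distribution, C3 = 0
  sb <- new_weighted_samples(xb, c(dVs, rep(0, 1000)), 310)
  expect_equal(pmf_cumulant(sb, edges, order = 3)$values,
               pmf_cumulant(sb, edges, order = 2)$values,
               tolerance = 1e-10)

  expect_error(pmf_cumulant(s, edges, order = 4), "order")
})

test_that("under-populated bins are masked, never reported as zero", {
  x <- c(rep(0.25, 100), 0.75)
  s <- new_weighted_samples(x, rep(0, 101), 310)
  p <- pmf_cumulant(s, c(0, 0.5, 1), order = 2, min_count = 10)
  expect_true(is.na(p$values[2]))
  expect_identical(as.numeric(p$counts), c(100, 1))
  # the masked bin does not participate in the min-shift
  expect_equal(as.numeric(p$values[1]), 0)
})

test_that("anharmonicity gamma: Gaussian zero, exponential positive, translation invariant", {
  set.seed(4)
  g <- rnorm(1e5, mean = 5, sd = 2)
  expect_lt(anharmonicity(g), 0.01)

  ex <- rexp(1e5, rate = 0.5)
  # closed form: S_gauss - S_exp = ln(sqrt(2*pi*e)) - 1 ~ 0.419; the
  # histogram estimator is biased slightly low at the density's edge
  expect_gt(anharmonicity(ex), 0.3)
  expect_lt(abs(anharmonicity(ex) - (log(sqrt(2 * pi * exp(1))) - 1)), 0.07)

  expect_equal(anharmonicity(ex), anharmonicity(ex + 123), tolerance = 1e-10)
  expect_error(anharmonicity(rnorm(50)), "100")
  expect_warning(g0 <- anharmonicity(rep(1, 200)), "zero-variance")
  expect_equal(g0, 0)
})

test_that("boost distribution is near-Gaussian on the many-dof bead chain", {
  bc <- make_bead_chain(6)
  pot <- bead_chain_potential(bc)
  st0 <- new_system_state(bead_chain_extended(bc), masses = rep(12, 18))
  proto <- run_protocol(pot, st0, schedule = list(
    min_sd = 100, min_cg = 200, heat_steps = 500, eq_steps = 500,
    cmd_stats_steps = 2000, gamd_eq_steps = 5000, n_production = 1,
    prod_steps = 20000), save_interval = 20, boost_class = "dual",
    seed = 17)
  dv <- boost_series(proto$production[[1]])
  expect_lt(anharmonicity(dv), 0.15)
})
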