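# The GaMD method proper: potential-energy statistics, boost-parameter
# selection under the sigma-0 criterion, the harmonic boost
# dV = 1/2 k (E - V)^2 applied below the threshold E, and the staged
# cMD -> GaMD-equilibration -> production protocol.

#' Potential-energy statistics
#'
#' Running maximum, minimum, mean and (population) standard deviation of
#' a potential-energy component — the inputs to GaMD boost-parameter
#' selection.
#'
#' @param V_max,V_min,V_avg,sigma_V kcal/mol
#' @param n_samples sample count
#' @return object of class `energy_stats`
#' @export
new_energy_stats <- function(V_max = -Inf, V_min = Inf, V_avg = 0,
                             sigma_V = 0, n_samples = 0) {
  if (n_samples > 0 && !(V_min <= V_avg && V_avg <= V_max)) {
    stop("require V_min <= V_avg <= V_max")
  }
  if (sigma_V < 0) stop("sigma_V must be non-negative")
  structure(list(V_max = V_max, V_min = V_min, V_avg = V_avg,
                 sigma_V = sigma_V, n_samples = as.numeric(n_samples)),
            class = "energy_stats")
}

#' @export
print.energy_stats <- function(x, ...) {
  cat(sprintf(
    "<energy_stats> n = %g: min %.4f, avg %.4f, max %.4f, sigma %.4f kcal/mol\n",
    x$n_samples, x$V_min, x$V_avg, x$V_max, x$sigma_V))
  invisible(x)
}

#' Stream potential-energy samples into running statistics
#'
#' Numerically stable Welford update; `V` may be a vector, in which case
#' samples are folded in one at a time in order. Max/min are
#' order-independent and mean/std match a two-pass computation to
#' near machine precision.
#'
#' @param stats an `energy_stats`
#' @param V potential-energy sample(s), kcal/mol
#' @return updated `energy_stats` (population sigma convention)
#' @export
update_stats <- function(stats, V) {
  if (!all(is.finite(V))) stop("non-finite potential-energy sample")
  n <- stats$n_samples
  mu <- if (n == 0) 0 else stats$V_avg
  M2 <- stats$sigma_V^2 * n
  vmin <- stats$V_min; vmax <- stats$V_max
  for (v in V) {
    n <- n + 1
    d <- v - mu
    mu <- mu + d / n
    M2 <- M2 + d * (v - mu)
    if (v < vmin) vmin <- v
    if (v > vmax) vmax <- v
  }
  new_energy_stats(V_max = vmax, V_min = vmin, V_avg = mu,
                   sigma_V = sqrt(max(0, M2 / n)), n_samples = n)
}

#' GaMD boost parameters for one energy component
#'
#' Selects the threshold energy E and force constant k from collected
#' potential statistics under the sigma-0 criterion, which caps the
#' standard deviation of the boost at `sigma_0` so that reweighting
#' stays accurate. Lower bound: \eqn{E = V_{max}},
#' \eqn{k_0 = \min(1, (\sigma_0/\sigma_V) (V_{max}-V_{min})/(V_{max}-V_{avg}))}.
#' Upper bound: \eqn{E = V_{min} + 1/k} with
#' \eqn{k_0'' = (1 - \sigma_0/\sigma_V)(V_{max}-V_{min})/(V_{avg}-V_{min})},
#' falling back to the lower-bound formula when \eqn{k_0''} leaves
#' (0, 1]. In both modes \eqn{k = k_0 / (V_{max}-V_{min})}.
#'
#' @param stats an `energy_stats` with at least 2 samples
#' @param sigma_0 upper limit on the boost-energy std, kcal/mol
#' @param bound_mode "lower" (E = V_max) or "upper" (E = V_min + 1/k)
#' @param component which energy class these statistics describe
#'   ("total" or "dihedral"); recorded, does not change the algebra
#' @return object of class `gamd_params` with fields bound_mode,
#'   component, E, k, k0, sigma_0 and the input statistics
#' @export
compute_params <- function(stats, sigma_0 = 6, bound_mode = c("lower", "upper"),
                           component = "total") {
  bound_mode <- match.arg(bound_mode)
  if (stats$n_samples < 2) stop("need at least 2 energy samples")
  if (sigma_0 <= 0) stop("sigma_0 must be positive")
  dV_range <- stats$V_max - stats$V_min
  if (dV_range <= 0) stop("flat energy (V_max == V_min): no boost possible")
  if (stats$sigma_V == 0) stop("zero energy fluctuation: no boost possible")
  k0_lower <- function() {
    denom <- stats$V_max - stats$V_avg
    if (denom <= 0) return(1)  # degenerate V_avg == V_max: cap
    min(1, (sigma_0 / stats$sigma_V) * dV_range / denom)
  }
  mode_used <- bound_mode
  if (bound_mode == "lower") {
    k0 <- k0_lower()
    k <- k0 / dV_range
    E <- stats$V_max
  } else {
    denom <- stats$V_avg - stats$V_min
    k0dd <- if (denom <= 0) NA_real_ else
      (1 - sigma_0 / stats$sigma_V) * dV_range / denom
    if (is.finite(k0dd) && k0dd > 0 && k0dd <= 1) {
      k0 <- k0dd
      k <- k0 / dV_range
      E <- stats$V_min + 1 / k
    } else {
      # upper-bound relation unsatisfiable; standard fallback
      k0 <- k0_lower()
      k <- k0 / dV_range
      E <- stats$V_max
      mode_used <- "lower"
    }
  }
  if (!(k0 > 0 && k0 <= 1)) stop("invalid k0 outside (0, 1]")
  structure(list(bound_mode = mode_used, requested_bound = bound_mode,
                 component = component, E = E, k = k, k0 = k0,
                 sigma_0 = sigma_0, stats = stats),
            class = "gamd_params")
}

#' @export
print.gamd_params <- function(x, ...) {
  cat(sprintf(
    "<gamd_params> %s boost, %s bound: E = %.4f, k0 = %.4f, k = %.6g 1/(kcal/mol)\n",
    x$component, x$bound_mode, x$E, x$k0, x$k))
  invisible(x)
}

#' Harmonic boost energy
#'
#' \eqn{\Delta V = k/2 (E - V)^2} when \eqn{V < E}, else 0. Non-negative,
#' continuous and once-differentiable at the threshold.
#'
#' @param params a `gamd_params`
#' @param V potential energy (scalar or vector), kcal/mol
#' @return boost energy, kcal/mol
#' @export
boost_energy <- function(params, V) {
  ifelse(V < params$E, 0.5 * params$k * (params$E - V)^2, 0)
}

#' Boost force-scaling factor
#'
#' Forces on the boosted surface equal the unboosted forces times
#' \eqn{1 - k (E - V)} for \eqn{V < E} (1 otherwise). For any valid
#' parameter set the factor lies in [0, 1]; a negative value indicates
#' parameters invalid for the supplied energy and is an error.
#'
#' @param params a `gamd_params`
#' @param V potential energy (scalar or vector), kcal/mol
#' @return dimensionless factor in [0, 1]
#' @export
boost_force_factor <- function(params, V) {
  fac <- ifelse(V < params$E, 1 - params$k * (params$E - V), 1)
  # k0 = 1 puts the factor at exactly 0 at V_min; forgive roundoff there
  fac[fac < 0 & fac > -1e-9] <- 0
  if (any(fac < 0)) {
    stop(sprintf(
      "negative force factor (%.4g) at V = %.4f: parameters invalid below V = %.4f",
      min(fac), V[which.min(fac)], params$E - 1 / params$k))
  }
  fac
}

#' Boost parameter set for a boost class
#'
#' Bundles per-component `gamd_params` into the requested boost class.
#' For potentials without a dihedral energy class, a requested dual
#' boost degrades to a total boost with a warning.
#'
#' @param stats_total `energy_stats` of the total potential
#' @param stats_dihedral `energy_stats` of the dihedral component, or
#'   NULL
#' @param sigma_0 kcal/mol (applied to both classes)
#' @param bound_mode "lower" or "upper"
#' @param boost_class "total", "dihedral" or "dual"
#' @return list with elements `class`, `total` and/or `dihedral`
#' @export
gamd_boost_set <- function(stats_total, stats_dihedral = NULL, sigma_0 = 6,
                           bound_mode = "lower",
                           boost_class = c("dual", "total", "dihedral")) {
  boost_class <- match.arg(boost_class)
  if (boost_class %in% c("dual", "dihedral") && is.null(stats_dihedral)) {
    if (boost_class == "dihedral") {
      stop("no dihedral energy component available")
    }
    warning("no dihedral energy component: dual boost degraded to total boost")
    boost_class <- "total"
  }
  out <- list(class = boost_class)
  if (boost_class %in% c("dual", "total")) {
    out$total <- compute_params(stats_total, sigma_0, bound_mode, "total")
  }
  if (boost_class %in% c("dual", "dihedral")) {
    out$dihedral <- compute_params(stats_dihedral, sigma_0, bound_mode,
                                   "dihedral")
    if (boost_class == "dihedral") {
      # engine applies the total slot; a dihedral-only boost is a
      # zero total boost plus the dihedral one
      out$total <- NULL
    }
  }
  out
}

#' GaMD run (equilibration or production)
#'
#' Boosted Langevin dynamics. In adaptive (equilibration) mode the
#' energy statistics accumulate every step — continuing from any prior
#' cMD statistics — and the boost parameters refresh on the save-interval
#' schedule; in production mode the supplied parameters stay frozen and
#' runs differ only by their velocity seed. Every saved frame carries
#' the applied boost energy.
#'
#' @param potential a `gamd_potential`
#' @param state a `system_state`
#' @param params boost parameter set from [gamd_boost_set()] (or NULL
#'   with `adaptive = TRUE` and prior stats)
#' @param n_steps,save_interval,dt,friction,temperature,seed as
#'   [run_cmd()]
#' @param adaptive refresh parameters from cumulative statistics
#' @param prior_stats optional `list(total=, dihedral=)` of
#'   `energy_stats` carried over from the cMD stage
#' @param sigma_0,bound_mode used when refreshing parameters
#' @param boost_class "total", "dihedral" or "dual"
#' @return a `gamd_trajectory`; metadata carries `params` (final),
#'   `energy_stats`, and `final_state`
#' @export
run_gamd <- function(potential, state, params = NULL, n_steps,
                     save_interval = 100, dt = 0.002, friction = 1,
                     temperature = 310, adaptive = FALSE,
                     prior_stats = NULL, sigma_0 = 6,
                     bound_mode = "lower", boost_class = "dual",
                     seed = NULL) {
  if (is.null(params) && !adaptive) {
    stop("need boost parameters, or adaptive = TRUE with prior statistics")
  }
  if (boost_class == "dual" && is.null(potential$dihedral_energy)) {
    warning("no dihedral energy component: dual boost degraded to total boost")
    boost_class <- "total"
  }
  if (!is.null(seed)) set.seed(seed)
  boost <- list(class = boost_class, params = params, adaptive = adaptive,
                sigma0 = sigma_0, bound_mode = bound_mode,
                stats_dihedral = prior_stats$dihedral)
  res <- .integrate(potential, state, n_steps, dt, friction,
                    temp_schedule = temperature,
                    save_interval = save_interval, boost = boost,
                    stats0 = prior_stats$total, label = "gamd")
  traj <- res$trajectory
  traj$metadata$seed <- seed
  traj$metadata$params <- res$params
  traj$metadata$energy_stats <- res$stats_total
  traj$metadata$energy_stats_dihedral <- res$stats_dihedral
  traj$metadata$final_state <- res$state
  traj$metadata$sigma_0 <- sigma_0
  traj
}

#' Staged simulation protocol
#'
#' Executes the full preparation-and-production sequence at toy scale:
#' minimize (steepest descent + conjugate gradient), heat under
#' restraints, a second restrained NVT equilibration, unrestrained cMD
#' collecting potential statistics, adaptive GaMD equilibration, then
#' `n_production` independent production runs that share the frozen
#' boost parameters and differ only by randomized initial velocities.
#'
#' @param potential a `gamd_potential`
#' @param state starting `system_state`
#' @param schedule list with stage lengths in steps: `min_sd`, `min_cg`,
#'   `heat_steps`, `eq_steps`, `cmd_stats_steps`, `gamd_eq_steps`,
#'   `n_production`, `prod_steps`
#' @param temperature production/thermostat temperature, K
#' @param dt,friction,save_interval integrator settings
#' @param restraint_k restraint constant for heat/equilibration stages,
#'   kcal/mol/A^2
#' @param sigma_0,bound_mode,boost_class GaMD settings
#' @param seed base integer seed; per-stage and per-run seeds are
#'   derived from it and recorded in metadata
#' @return list with `production` (list of trajectories), `params`
#'   (frozen boost set), `cmd` (statistics trajectory), `gamd_eq`,
#'   `stats`, `state0` (post-equilibration state) and `seeds`
#' @export
run_protocol <- function(potential, state,
                         schedule = list(min_sd = 200, min_cg = 200,
                                         heat_steps = 2500, eq_steps = 2500,
                                         cmd_stats_steps = 5000,
                                         gamd_eq_steps = 250000,
                                         n_production = 4,
                                         prod_steps = 600000),
                         temperature = 310, dt = 0.002, friction = 1,
                         save_interval = 100, restraint_k = 1,
                         sigma_0 = 6, bound_mode = "lower",
                         boost_class = "dual", seed = 1) {
  sc <- schedule
  stages <- c("min_sd", "min_cg", "heat_steps", "eq_steps",
              "cmd_stats_steps", "gamd_eq_steps", "prod_steps")
  for (s in stages) if (is.null(sc[[s]]) || sc[[s]] < 0) {
    stop(sprintf("schedule stage '%s' missing or negative", s))
  }
  if (is.null(sc$n_production) || sc$n_production < 1) {
    stop("n_production must be >= 1")
  }
  if (boost_class == "dual" && is.null(potential$dihedral_energy)) {
    warning("no dihedral energy component: dual boost degraded to total boost")
    boost_class <- "total"
  }
  seeds <- list(heat = seed * 11L + 1L, eq = seed * 11L + 2L,
                cmd = seed * 11L + 3L, gamd_eq = seed * 11L + 4L,
                production = seed * 11L + 4L + seq_len(sc$n_production))
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("protocol stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  st <- run_stage("minimize", function() {
    minimize(potential, state, sc$min_sd, sc$min_cg)
  })
  restr <- list(k = restraint_k, ref = st$coords)
  if (sc$heat_steps > 0) {
    st <- run_stage("heat", function() {
      set.seed(seeds$heat)
      st <- maxwell_velocities(st, 1e-6)
      heat_ramp(potential, st, 0, temperature, sc$heat_steps,
                restraints = restr, dt = dt, friction = friction,
                save_interval = save_interval)
    })
  }
  if (sc$eq_steps > 0) {
    st <- run_stage("equilibrate", function() {
      tr <- run_cmd(potential, st, sc$eq_steps, save_interval, dt, friction,
                    temperature, restraints = restr, seed = seeds$eq)
      tr$metadata$final_state
    })
  }
  cmd_traj <- NULL
  stats <- list(total = NULL, dihedral = NULL)
  if (sc$cmd_stats_steps > 0) {
    cmd_traj <- run_stage("cmd_statistics", function() {
      run_cmd(potential, st, sc$cmd_stats_steps, save_interval, dt, friction,
              temperature, seed = seeds$cmd)
    })
    st <- cmd_traj$metadata$final_state
    stats$total <- cmd_traj$metadata$energy_stats
    if (!is.null(potential$dihedral_energy)) {
      # dihedral statistics from the saved cMD frames
      vd <- cmd_traj$V_dihedral
      stats$dihedral <- update_stats(new_energy_stats(), vd)
    }
  }
  gamd_eq_traj <- NULL
  params <- NULL
  if (sc$gamd_eq_steps > 0) {
    gamd_eq_traj <- run_stage("gamd_equilibration", function() {
      run_gamd(potential, st, params = NULL, n_steps = sc$gamd_eq_steps,
               save_interval = save_interval, dt = dt, friction = friction,
               temperature = temperature, adaptive = TRUE,
               prior_stats = stats, sigma_0 = sigma_0,
               bound_mode = bound_mode, boost_class = boost_class,
               seed = seeds$gamd_eq)
    })
    st <- gamd_eq_traj$metadata$final_state
    params <- gamd_eq_traj$metadata$params
    stats <- list(total = gamd_eq_traj$metadata$energy_stats,
                  dihedral = gamd_eq_traj$metadata$energy_stats_dihedral)
  } else {
    # adaptive off: production uses the cMD-statistics params verbatim
    if (is.null(stats$total)) stop("no statistics available for boost")
    params <- gamd_boost_set(stats$total, stats$dihedral, sigma_0,
                             bound_mode, boost_class)
  }
  production <- vector("list", sc$n_production)
  for (i in seq_len(sc$n_production)) {
    production[[i]] <- run_stage(sprintf("production_%d", i), function() {
      set.seed(seeds$production[i])
      sti <- maxwell_velocities(st, temperature)
      tr <- run_gamd(potential, sti, params = params,
                     n_steps = sc$prod_steps,
                     save_interval = save_interval, dt = dt,
                     friction = friction, temperature = temperature,
                     adaptive = FALSE, boost_class = params$class)
      tr$metadata$seed <- seeds$production[i]
      tr$metadata$label <- sprintf("production_%d", i)
      tr
    })
  }
  list(production = production, params = params, cmd = cmd_traj,
       gamd_eq = gamd_eq_traj, stats = stats, state0 = st,
       seeds = seeds, schedule = sc,
       settings = list(temperature = temperature, dt = dt,
                       friction = friction, save_interval = save_interval,
                       sigma_0 = sigma_0, bound_mode = bound_mode,
                       boost_class = boost_class, seed = seed))
}
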