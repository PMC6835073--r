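# Minimal Langevin/NVT engine with energy-component bookkeeping.
# Integrator is BAOAB splitting: with friction = 0 it reduces to
# velocity Verlet (NVE), and at finite friction it gives high
# configurational accuracy at large time steps.

#' Construct a dynamical system state
#'
#' @param coords coordinate vector, Angstrom
#' @param velocities velocity vector, A/ps (default zero)
#' @param masses amu; scalar, per-dof vector, or per-particle vector for
#'   3D systems (expanded to per dof)
#' @param time current time, ps
#' @return object of class `system_state`
#' @export
new_system_state <- function(coords, velocities = NULL, masses = 12,
                             time = 0) {
  coords <- as.numeric(coords)
  n <- length(coords)
  if (is.null(velocities)) velocities <- numeric(n)
  if (length(velocities) != n) {
    stop("coordinate and velocity dimensions must match")
  }
  if (length(masses) * 3L == n) masses <- rep(masses, each = 3L)
  masses <- rep(masses, length.out = n)
  if (any(masses <= 0)) stop("masses must be strictly positive")
  structure(list(coords = coords, velocities = as.numeric(velocities),
                 masses = masses, time = as.numeric(time)),
            class = "system_state")
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param state a `system_state`
#' @param temperature K
#' @return the state with velocities resampled from the Maxwell
#'   distribution at `temperature` (uses the current RNG stream)
#' @export
maxwell_velocities <- function(state, temperature) {
  sd <- sqrt(kBT(temperature) * KCAL_PER_MOL_TO_AKMA / state$masses)
  state$velocities <- stats::rnorm(length(state$coords), sd = sd)
  state
}

#' Instantaneous kinetic temperature
#' @param state a `system_state`
#' @return temperature in K from equipartition over all dof
#' @export
kinetic_temperature <- function(state) {
  ke <- 0.5 * sum(state$masses * state$velocities^2) / KCAL_PER_MOL_TO_AKMA
  2 * ke / (length(state$coords) * kB)
}

# restraints: list(k = kcal/mol/A^2, ref = coords, sel = dof indices or NULL)
.restraint_energy <- function(restraints, x) {
  if (is.null(restraints)) return(0)
  sel <- if (is.null(restraints$sel)) seq_along(x) else restraints$sel
  restraints$k * sum((x[sel] - restraints$ref[sel])^2)
}

.restraint_force <- function(restraints, x) {
  f <- numeric(length(x))
  if (is.null(restraints)) return(f)
  sel <- if (is.null(restraints$sel)) seq_along(x) else restraints$sel
  f[sel] <- -2 * restraints$k * (x[sel] - restraints$ref[sel])
  f
}

# Unified BAOAB integration loop shared by run_cmd, heat_ramp and
# run_gamd. `boost` is NULL (cMD) or a list(class=, params=, adaptive=,
# sigma0=, bound_mode=, update_interval=). Returns frames, final state,
# streaming energy statistics and (for GaMD) the final parameter set.
.integrate <- function(potential, state, n_steps, dt, friction,
                       temp_schedule, save_interval, restraints = NULL,
                       boost = NULL, record_initial = FALSE,
                       stats0 = NULL, label = "run",
                       record_velocities = FALSE) {
  if (dt <= 0) stop("dt must be positive")
  if (friction < 0) stop("friction must be non-negative")
  if (n_steps < save_interval) stop("n_steps must be >= save_interval")
  x <- state$coords; v <- state$velocities; m <- state$masses
  dof <- length(x)
  temp_schedule <- rep(temp_schedule, length.out = n_steps)
  if (any(temp_schedule < 0)) stop("temperature must be non-negative")
  has_dih <- !is.null(potential$dihedral_energy)
  dual <- !is.null(boost) && identical(boost$class, "dual") && has_dih
  # streaming moments (population convention), seeded from prior stats
  st <- if (is.null(stats0)) list(n = 0, mean = 0, M2 = 0, vmin = Inf, vmax = -Inf)
        else list(n = stats0$n_samples, mean = stats0$V_avg,
                  M2 = stats0$sigma_V^2 * stats0$n_samples,
                  vmin = stats0$V_min, vmax = stats0$V_max)
  std <- if (is.null(boost$stats_dihedral)) {
    list(n = 0, mean = 0, M2 = 0, vmin = Inf, vmax = -Inf)
  } else {
    s <- boost$stats_dihedral
    list(n = s$n_samples, mean = s$V_avg, M2 = s$sigma_V^2 * s$n_samples,
         vmin = s$V_min, vmax = s$V_max)
  }
  upd <- function(s, V) {
    s$n <- s$n + 1
    d <- V - s$mean
    s$mean <- s$mean + d / s$n
    s$M2 <- s$M2 + d * (V - s$mean)
    if (V < s$vmin) s$vmin <- V
    if (V > s$vmax) s$vmax <- V
    s
  }
  pack <- function(s) {
    if (s$n == 0) return(NULL)
    new_energy_stats(V_max = s$vmax, V_min = s$vmin, V_avg = s$mean,
                     sigma_V = sqrt(max(0, s$M2 / s$n)), n_samples = s$n)
  }
  params <- boost$params
  refresh_params <- function() {
    tot <- pack(st)
    if (is.null(tot) || tot$V_max <= tot$V_min || tot$sigma_V == 0) {
      return(params)
    }
    if (boost$class %in% c("dual", "dihedral") && has_dih) {
      dih <- pack(std)
      if (is.null(dih) || dih$V_max <= dih$V_min || dih$sigma_V == 0) {
        return(params)
      }
      gamd_boost_set(tot, dih, sigma_0 = boost$sigma0,
                     bound_mode = boost$bound_mode, boost_class = boost$class)
    } else {
      gamd_boost_set(tot, NULL, sigma_0 = boost$sigma0,
                     bound_mode = boost$bound_mode, boost_class = "total")
    }
  }
  n_clamped <- 0L
  eval_point <- function(x) {
    Vd <- if (has_dih) potential$dihedral_energy(x) else 0
    V <- potential$energy(x)
    g <- potential$gradient(x)
    dV <- 0; dVd <- 0
    if (!is.null(boost) && !is.null(params)) {
      # grad of V* = V + dV_P(V) + dV_D(V_dih):
      #   fact * grad(V) + (facd - 1) * grad(V_dih)
      pt <- params$total
      if (!is.null(pt)) {
        fact <- 1 - pt$k * max(0, pt$E - V)
        if (fact < 0) { fact <- 0; n_clamped <<- n_clamped + 1L }
        dV <- boost_energy(pt, V)
        g <- fact * g
      }
      if (dual || (!is.null(params$dihedral) && has_dih)) {
        pd <- params$dihedral
        facd <- 1 - pd$k * max(0, pd$E - Vd)
        if (facd < 0) { facd <- 0; n_clamped <<- n_clamped + 1L }
        dVd <- boost_energy(pd, Vd)
        g <- g + (facd - 1) * potential$dihedral_gradient(x)
      }
    }
    f <- -g + .restraint_force(restraints, x)
    list(V = V, Vd = Vd, dV = dV, dVd = dVd, f = f)
  }
  ep <- eval_point(x)
  if (!all(is.finite(ep$f))) stop("non-finite forces at start")
  n_save <- n_steps %/% save_interval
  sv_time <- numeric(n_save + record_initial)
  sv_coords <- matrix(0, n_save + record_initial, dof)
  sv_V <- numeric(n_save + record_initial)
  sv_Vd <- numeric(n_save + record_initial)
  sv_dV <- numeric(n_save + record_initial)
  sv_dVd <- numeric(n_save + record_initial)
  sv_vel <- if (record_velocities) matrix(0, n_save + record_initial, dof)
  irow <- 0L
  push <- function(t) {
    irow <<- irow + 1L
    sv_time[irow] <<- t
    sv_coords[irow, ] <<- x
    sv_V[irow] <<- ep$V; sv_Vd[irow] <<- ep$Vd
    sv_dV[irow] <<- ep$dV; sv_dVd[irow] <<- ep$dVd
    if (record_velocities) sv_vel[irow, ] <<- v
  }
  if (record_initial) push(state$time)
  akma <- KCAL_PER_MOL_TO_AKMA
  chunk <- 1024L
  noise <- NULL; noise_i <- chunk
  t_now <- state$time
  adaptive <- isTRUE(boost$adaptive)
  upd_int <- if (is.null(boost$update_interval)) save_interval else boost$update_interval
  for (step in seq_len(n_steps)) {
    Tk <- temp_schedule[step]
    v <- v + 0.5 * dt * ep$f / m * akma
    x <- x + 0.5 * dt * v
    if (friction > 0 && Tk > 0) {
      if (noise_i >= chunk) {
        noise <- matrix(stats::rnorm(chunk * dof), chunk, dof)
        noise_i <- 0L
      }
      noise_i <- noise_i + 1L
      c1 <- exp(-friction * dt)
      v <- c1 * v + sqrt((1 - c1^2) * kB * Tk * akma / m) * noise[noise_i, ]
    } else if (friction > 0) {
      v <- exp(-friction * dt) * v
    }
    x <- x + 0.5 * dt * v
    ep <- eval_point(x)
    if (!all(is.finite(ep$f)) || !is.finite(ep$V)) {
      stop(sprintf("unstable integration at step %d (non-finite energy/force)",
                   step))
    }
    if (abs(ep$V) > 1e8) {
      stop(sprintf("unstable integration at step %d (energy explosion)", step))
    }
    v <- v + 0.5 * dt * ep$f / m * akma
    t_now <- t_now + dt
    st <- upd(st, ep$V)
    if (has_dih) std <- upd(std, ep$Vd)
    if (adaptive && step %% upd_int == 0L) params <- refresh_params()
    if (step %% save_interval == 0L) push(t_now)
  }
  final <- new_system_state(x, v, m, t_now)
  list(
    trajectory = new_trajectory(
      time = sv_time[seq_len(irow)], coords = sv_coords[seq_len(irow), , drop = FALSE],
      V_total = sv_V[seq_len(irow)], V_dihedral = sv_Vd[seq_len(irow)],
      dV_total = sv_dV[seq_len(irow)], dV_dihedral = sv_dVd[seq_len(irow)],
      metadata = list(label = label, dt = dt, friction = friction,
                      temperature = temp_schedule[n_steps],
                      save_interval = save_interval,
                      boost_class = if (is.null(boost)) "none" else boost$class,
                      n_factor_clamped = n_clamped)),
    velocities = if (record_velocities) sv_vel[seq_len(irow), , drop = FALSE],
    state = final,
    stats_total = pack(st),
    stats_dihedral = if (has_dih) pack(std) else NULL,
    params = params
  )
}

#' Energy minimization: steepest descent then conjugate gradient
#'
#' Step-count based stage switch (steepest descent for
#' `steepest_steps`, then Polak-Ribiere conjugate gradient for
#' `conj_grad_steps`), with backtracking line search and an optional
#' early-exit gradient tolerance.
#'
#' @param potential a `gamd_potential`
#' @param state a `system_state`
#' @param steepest_steps steepest-descent iterations (>= 0)
#' @param conj_grad_steps conjugate-gradient iterations (>= 0)
#' @param grad_tol early exit when the gradient max-norm falls below
#'   this (kcal/mol/A)
#' @return the minimized `system_state`; attributes `energy` (kcal/mol)
#'   and `grad_norm` report the final point
#' @export
minimize <- function(potential, state, steepest_steps = 200,
                     conj_grad_steps = 200, grad_tol = 1e-8) {
  if (steepest_steps < 0 || conj_grad_steps < 0) {
    stop("step counts must be non-negative")
  }
  x <- state$coords
  E0 <- potential$energy(x)
  E <- E0
  g <- potential$gradient(x)
  alpha <- 0.1 / max(1, max(abs(g)))
  dir_prev <- NULL; g_prev <- NULL
  total <- steepest_steps + conj_grad_steps
  for (it in seq_len(total)) {
    if (max(abs(g)) < grad_tol) break
    if (it <= steepest_steps || is.null(g_prev)) {
      dir <- -g
    } else {
      beta <- max(0, sum(g * (g - g_prev)) / sum(g_prev^2))
      dir <- -g + beta * dir_prev
      if (sum(dir * g) >= 0) dir <- -g  # restart on non-descent
    }
    accepted <- FALSE
    for (tries in 1:30) {
      xn <- x + alpha * dir
      En <- potential$energy(xn)
      if (is.finite(En) && En <= E) { accepted <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!accepted) break
    g_prev <- g; dir_prev <- dir
    x <- xn; E <- En
    g <- potential$gradient(x)
    alpha <- alpha * 1.25
  }
  if (E > E0 + 1e-8) {
    stop(sprintf("minimization diverged: energy rose from %.6g to %.6g", E0, E))
  }
  out <- new_system_state(x, state$velocities, state$masses, state$time)
  attr(out, "energy") <- E
  attr(out, "grad_norm") <- max(abs(g))
  out
}

#' Single BAOAB Langevin step
#'
#' One symplectic-stochastic update; with `friction = 0` this is a
#' velocity Verlet (NVE) step. Deterministic given the RNG state.
#'
#' @param potential a `gamd_potential`
#' @param state a `system_state`
#' @param dt time step, ps
#' @param friction Langevin friction, 1/ps
#' @param temperature thermostat target, K
#' @return the advanced `system_state`
#' @export
langevin_step <- function(potential, state, dt, friction = 1,
                          temperature = 310) {
  res <- .integrate(potential, state, n_steps = 1L, dt = dt,
                    friction = friction, temp_schedule = temperature,
                    save_interval = 1L)
  res$state
}

#' Conventional MD run (NVT Langevin)
#'
#' Runs unboosted dynamics, saving a frame every `save_interval` steps
#' and streaming potential-energy statistics (max, min, mean, std) over
#' every step. The statistics and final state are carried in the
#' trajectory metadata.
#'
#' @param potential a `gamd_potential`
#' @param state a `system_state`
#' @param n_steps number of steps (>= save_interval)
#' @param save_interval steps between saved frames
#' @param dt ps
#' @param friction 1/ps
#' @param temperature K
#' @param restraints optional `list(k=, ref=, sel=)` harmonic positional
#'   restraint (kcal/mol/A^2; AMBER convention k*(dx)^2)
#' @param seed integer seed (RNG reset if non-NULL)
#' @param record_initial also save the initial frame
#' @return a `gamd_trajectory` with `dV = 0` everywhere; metadata fields
#'   `energy_stats` (an `energy_stats`) and `final_state`
#' @export
run_cmd <- function(potential, state, n_steps, save_interval = 100,
                    dt = 0.002, friction = 1, temperature = 310,
                    restraints = NULL, seed = NULL,
                    record_initial = FALSE, record_velocities = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  res <- .integrate(potential, state, n_steps, dt, friction,
                    temp_schedule = temperature,
                    save_interval = save_interval, restraints = restraints,
                    record_initial = record_initial, label = "cmd",
                    record_velocities = record_velocities)
  traj <- res$trajectory
  if (record_velocities) traj$velocities <- res$velocities
  traj$metadata$seed <- seed
  traj$metadata$energy_stats <- res$stats_total
  traj$metadata$final_state <- res$state
  traj
}

#' Linear heating ramp under positional restraints
#'
#' Thermostat target interpolated linearly from `t_start` to `t_end`
#' over the run; mirrors the heat-and-restrain preparation stage.
#'
#' @inheritParams run_cmd
#' @param t_start,t_end K
#' @return final `system_state`
#' @export
heat_ramp <- function(potential, state, t_start = 0, t_end = 310,
                      n_steps = 1000, restraints = NULL, seed = NULL,
                      dt = 0.002, friction = 1, save_interval = 100) {
  if (t_start < 0 || t_end < 0) stop("temperatures must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  sched <- if (n_steps == 1L) t_end else
    seq(t_start, t_end, length.out = n_steps)
  res <- .integrate(potential, state, n_steps, dt, friction,
                    temp_schedule = sched, save_interval = save_interval,
                    restraints = restraints, label = "heat")
  res$state
}
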