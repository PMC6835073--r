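# Coarse-grained bead-chain "peptide": bonds, angles, dihedrals and a
# soft nonbonded repulsion. Its only job is to provide a molecular
# system whose total potential decomposes exactly into a dihedral
# component plus remainder, so the dual-boost machinery (independent
# dihedral and total boosts) can be exercised and tested.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build a bead-chain molecular model
#'
#' Linear chain of `n_beads` beads with harmonic bonds
#' \eqn{k_b (r - r_0)^2}, harmonic angles \eqn{k_a (\theta - \theta_0)^2}
#' (AMBER-style, no 1/2), cosine dihedrals
#' \eqn{A (1 + \cos(n\phi - \delta))} and a purely repulsive
#' \eqn{\epsilon(\sigma/r)^{12}} term between beads three or more bonds
#' apart.
#'
#' @param n_beads number of beads (>= 4 when dihedral terms are used)
#' @param masses amu, scalar or per bead
#' @param bond_r0,bond_kb equilibrium length (A) and force constant
#'   (kcal/mol/A^2)
#' @param angle_theta0,angle_ka equilibrium angle (rad) and force
#'   constant (kcal/mol/rad^2)
#' @param dihedral_amp,dihedral_n,dihedral_phase cosine-series
#'   amplitude (kcal/mol), periodicity and phase (rad)
#' @param rep_eps,rep_sigma repulsion strength (kcal/mol) and diameter (A)
#' @param dihedrals include dihedral terms (default TRUE)
#' @return object of class `bead_chain`
#' @export
make_bead_chain <- function(n_beads = 6, masses = 12,
                            bond_r0 = 1.5, bond_kb = 100,
                            angle_theta0 = 1.911, angle_ka = 40,
                            dihedral_amp = 1.5, dihedral_n = 3,
                            dihedral_phase = 0,
                            rep_eps = 0.05, rep_sigma = 2.0,
                            dihedrals = TRUE) {
  n_beads <- as.integer(n_beads)
  if (dihedrals && n_beads < 4) {
    stop("dihedral terms require n_beads >= 4")
  }
  if (!dihedrals && n_beads < 2) stop("need at least 2 beads")
  structure(list(
    n_beads = n_beads,
    masses = rep(masses, length.out = n_beads),
    bond_r0 = bond_r0, bond_kb = bond_kb,
    angle_theta0 = angle_theta0, angle_ka = angle_ka,
    dihedral_amp = dihedral_amp, dihedral_n = dihedral_n,
    dihedral_phase = dihedral_phase,
    rep_eps = rep_eps, rep_sigma = rep_sigma,
    dihedrals = dihedrals
  ), class = "bead_chain")
}

#' @export
print.bead_chain <- function(x, ...) {
  cat(sprintf("<bead_chain> %d beads, %d bonds, %d angles, %d dihedrals\n",
              x$n_beads, x$n_beads - 1L, max(0L, x$n_beads - 2L),
              if (x$dihedrals) max(0L, x$n_beads - 3L) else 0L))
  invisible(x)
}

# energy and gradient of one cosine dihedral; returns list(phi, E, g4x3)
.dihedral_term <- function(r1, r2, r3, r4, amp, per, phase) {
  b1 <- r2 - r1; b2 <- r3 - r2; b3 <- r4 - r3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  m1 <- .cross3(n1, b2 / nb2)
  phi <- atan2(sum(m1 * n2), sum(n1 * n2))
  E <- amp * (1 + cos(per * phi - phase))
  dEdphi <- -amp * per * sin(per * phi - phase)
  s1 <- sum(n1^2); s2 <- sum(n2^2)
  dphi1 <- nb2 / s1 * n1
  dphi4 <- -nb2 / s2 * n2
  c12 <- sum(b1 * b2) / nb2^2
  c32 <- sum(b3 * b2) / nb2^2
  dphi2 <- -(1 + c12) * dphi1 + c32 * dphi4
  dphi3 <- -(1 + c32) * dphi4 + c12 * dphi1
  list(phi = phi, E = E,
       g = dEdphi * rbind(dphi1, dphi2, dphi3, dphi4))
}

# full energy/gradient decomposition; x is a flat length-3n vector
.bead_chain_eval <- function(model, x, gradient = TRUE) {
  n <- model$n_beads
  r <- matrix(x, ncol = 3, byrow = TRUE)
  g <- if (gradient) matrix(0, n, 3) else NULL
  gd <- if (gradient) matrix(0, n, 3) else NULL
  E_bond <- 0; E_angle <- 0; E_dih <- 0; E_rep <- 0
  for (i in seq_len(n - 1)) {
    d <- r[i, ] - r[i + 1, ]
    rr <- sqrt(sum(d^2))
    E_bond <- E_bond + model$bond_kb * (rr - model$bond_r0)^2
    if (gradient) {
      f <- 2 * model$bond_kb * (rr - model$bond_r0) * d / rr
      g[i, ] <- g[i, ] + f
      g[i + 1, ] <- g[i + 1, ] - f
    }
  }
  if (n >= 3) {
    for (j in 2:(n - 1)) {
      u <- r[j - 1, ] - r[j, ]; v <- r[j + 1, ] - r[j, ]
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      ct <- sum(u * v) / (nu * nv)
      ct <- max(-1, min(1, ct))
      th <- acos(ct)
      E_angle <- E_angle + model$angle_ka * (th - model$angle_theta0)^2
      if (gradient) {
        st <- sqrt(max(1e-12, 1 - ct^2))
        dth_du <- -(v / (nu * nv) - ct * u / nu^2) / st
        dth_dv <- -(u / (nu * nv) - ct * v / nv^2) / st
        pre <- 2 * model$angle_ka * (th - model$angle_theta0)
        g[j - 1, ] <- g[j - 1, ] + pre * dth_du
        g[j + 1, ] <- g[j + 1, ] + pre * dth_dv
        g[j, ] <- g[j, ] - pre * (dth_du + dth_dv)
      }
    }
  }
  if (model$dihedrals && n >= 4) {
    for (i in seq_len(n - 3)) {
      dt <- .dihedral_term(r[i, ], r[i + 1, ], r[i + 2, ], r[i + 3, ],
                           model$dihedral_amp, model$dihedral_n,
                           model$dihedral_phase)
      E_dih <- E_dih + dt$E
      if (gradient) {
        idx <- i:(i + 3)
        gd[idx, ] <- gd[idx, ] + dt$g
      }
    }
  }
  if (n >= 4 && model$rep_eps > 0) {
    for (i in seq_len(n - 3)) for (j in (i + 3):n) {
      d <- r[i, ] - r[j, ]
      rr <- sqrt(sum(d^2))
      e <- model$rep_eps * (model$rep_sigma / rr)^12
      E_rep <- E_rep + e
      if (gradient) {
        f <- -12 * e / rr^2 * d
        g[i, ] <- g[i, ] + f
        g[j, ] <- g[j, ] - f
      }
    }
  }
  list(E_total = E_bond + E_angle + E_dih + E_rep,
       E_dihedral = E_dih,
       E_bond = E_bond, E_angle = E_angle, E_rep = E_rep,
       grad_total = if (gradient) as.numeric(t(g + gd)) else NULL,
       grad_dihedral = if (gradient) as.numeric(t(gd)) else NULL)
}

#' Bead-chain model as a `gamd_potential`
#'
#' Exposes total energy/gradient plus the exact dihedral component and
#' its gradient, the decomposition required for dual-boost GaMD.
#'
#' @param model a `bead_chain`
#' @return a `gamd_potential` with `dimension = 3 * n_beads`
#' @export
bead_chain_potential <- function(model) {
  stopifnot(inherits(model, "bead_chain"))
  new_potential(
    name = sprintf("bead_chain_%d", model$n_beads),
    dimension = 3L * model$n_beads,
    energy = function(x) .bead_chain_eval(model, x, gradient = FALSE)$E_total,
    gradient = function(x) .bead_chain_eval(model, x)$grad_total,
    parameters = c(list(type = "bead_chain"), unclass(model)),
    dihedral_energy = function(x) {
      .bead_chain_eval(model, x, gradient = FALSE)$E_dihedral
    },
    dihedral_gradient = function(x) .bead_chain_eval(model, x)$grad_dihedral
  )
}

#' Extended (all-trans) starting configuration of a bead chain
#'
#' Planar zig-zag with every bond at `bond_r0` and every angle at
#' `angle_theta0`, so the bond and angle energies are exactly zero and
#' all dihedrals sit at 180 degrees.
#'
#' @param model a `bead_chain`
#' @return flat coordinate vector of length `3 * n_beads` (Angstrom)
#' @export
bead_chain_extended <- function(model) {
  n <- model$n_beads
  alpha <- (pi - model$angle_theta0) / 2
  r <- matrix(0, n, 3)
  dirs <- cbind(cos(alpha * rep_len(c(1, -1), n - 1)),
                sin(alpha * rep_len(c(1, -1), n - 1)), 0)
  for (i in 2:n) r[i, ] <- r[i - 1, ] + model$bond_r0 * dirs[i - 1, ]
  as.numeric(t(r))
}

#' Number of dihedral terms in a bead chain
#' @param model a `bead_chain`
#' @return integer count
#' @export
n_dihedrals <- function(model) {
  if (!model$dihedrals) 0L else max(0L, model$n_beads - 3L)
}

#' Energy decomposition of a bead-chain configuration
#'
#' @param model a `bead_chain`
#' @param x flat coordinate vector
#' @return named list with total, dihedral, bond, angle and repulsion
#'   energies (kcal/mol)
#' @export
bead_chain_energy_components <- function(model, x) {
  ev <- .bead_chain_eval(model, x, gradient = FALSE)
  list(total = ev$E_total, dihedral = ev$E_dihedral, bond = ev$E_bond,
       angle = ev$E_angle, repulsion = ev$E_rep)
}
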