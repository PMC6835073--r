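# Analytic model potentials with exactly known Boltzmann statistics.
# These stand in for the all-atom potential V(r): every downstream stage
# (dynamics, boost, reweighting, clustering) can be validated against
# quadrature of exp(-V/kBT) instead of GPU-scale simulation.

#' Construct an analytic potential
#'
#' Low-level constructor for the `gamd_potential` interface shared by the
#' analytic model systems and the bead-chain model. `energy` and
#' `gradient` operate on a bare numeric coordinate vector of length
#' `dimension`.
#'
#' @param name label for the potential
#' @param dimension number of degrees of freedom
#' @param energy function(x) -> kcal/mol
#' @param gradient function(x) -> length-`dimension` gradient, kcal/mol/A
#' @param parameters named list of defining parameters (serialized to
#'   config files)
#' @param dihedral_energy optional function(x) giving the dihedral energy
#'   component (bead chain); NULL for potentials without one
#' @param dihedral_gradient optional gradient of the dihedral component
#' @return object of class `gamd_potential`
#' @export
new_potential <- function(name, dimension, energy, gradient,
                          parameters = list(),
                          dihedral_energy = NULL, dihedral_gradient = NULL) {
  structure(list(
    name = name, dimension = as.integer(dimension),
    energy = energy, gradient = gradient, parameters = parameters,
    dihedral_energy = dihedral_energy, dihedral_gradient = dihedral_gradient
  ), class = "gamd_potential")
}

#' @export
print.gamd_potential <- function(x, ...) {
  cat(sprintf("<gamd_potential> %s (%d dof)%s\n", x$name, x$dimension,
              if (is.null(x$dihedral_energy)) "" else ", with dihedral component"))
  invisible(x)
}

#' One-dimensional harmonic well
#'
#' \eqn{V(x) = k/2 (x - x0)^2}. Mostly used as a validation system: its
#' Boltzmann density, PMF and equipartition statistics are closed-form.
#'
#' @param k_spring force constant, kcal/mol/A^2
#' @param center minimum position x0, Angstrom
#' @return a `gamd_potential`
#' @export
make_harmonic <- function(k_spring = 1, center = 0) {
  if (k_spring <= 0) stop("k_spring must be positive")
  new_potential(
    name = "harmonic", dimension = 1L,
    energy = function(x) 0.5 * k_spring * (x - center)^2,
    gradient = function(x) k_spring * (x - center),
    parameters = list(type = "harmonic", k_spring = k_spring, center = center)
  )
}

#' One-dimensional double-well potential
#'
#' Quartic double well
#' \deqn{V(x) = h ((x/a)^2 - 1)^2 + (c/2)(x/a),}
#' with \eqn{a} half the well separation, \eqn{h} the barrier height of
#' the symmetric part and \eqn{c} a linear tilt. With `asymmetry = 0`
#' the two minima are exactly degenerate; for small `asymmetry` relative
#' to the barrier the energy difference between the wells approaches
#' `asymmetry` (left well deeper for positive values).
#'
#' @param barrier_height h, kcal/mol (barrier of the symmetric part)
#' @param well_separation distance between the two minima of the
#'   symmetric part, Angstrom
#' @param asymmetry c, kcal/mol; energy tilt between the wells
#' @return a `gamd_potential`
#' @export
make_double_well <- function(barrier_height = 6, well_separation = 2,
                             asymmetry = 0) {
  if (barrier_height <= 0) stop("barrier_height must be positive")
  if (well_separation <= 0) stop("well_separation must be positive")
  a <- well_separation / 2
  h <- barrier_height
  c0 <- asymmetry
  new_potential(
    name = "double_well", dimension = 1L,
    energy = function(x) {
      u <- x / a
      h * (u^2 - 1)^2 + (c0 / 2) * u
    },
    gradient = function(x) {
      u <- x / a
      (4 * h * u * (u^2 - 1) + c0 / 2) / a
    },
    parameters = list(type = "double_well", barrier_height = h,
                      well_separation = well_separation, asymmetry = c0)
  )
}

#' Two-dimensional four-well Gaussian landscape
#'
#' Sum of four Gaussian wells on a flat background,
#' \eqn{V(r) = \sum_i d_i \exp(-|r - c_i|^2 / (2 w^2))} with negative
#' depths \eqn{d_i}. Mirrors the two-coordinate free-energy landscapes
#' used to analyse peptide binding, with the deepest well identifiable
#' analytically.
#'
#' @param depths length-4 numeric, well depths in kcal/mol (negative for
#'   attractive wells)
#' @param centers 4 x 2 matrix of well centers (Angstrom)
#' @param widths Gaussian width w, Angstrom (scalar or length 4)
#' @return a `gamd_potential` with `dimension = 2`
#' @export
make_four_well_2d <- function(depths = c(-5, -3, -3, -1),
                              centers = rbind(c(-1, -1), c(1, -1),
                                              c(-1, 1), c(1, 1)),
                              widths = 0.4) {
  centers <- as.matrix(centers)
  if (length(depths) != 4 || nrow(centers) != 4 || ncol(centers) != 2) {
    stop("need 4 depths and a 4 x 2 matrix of centers")
  }
  if (any(stats::dist(centers) < 1e-9)) stop("well centers must be distinct")
  w <- rep(widths, length.out = 4)
  if (any(w <= 0)) stop("widths must be positive")
  new_potential(
    name = "four_well_2d", dimension = 2L,
    energy = function(x) {
      dx <- sweep(centers, 2, x)
      sum(depths * exp(-rowSums(dx^2) / (2 * w^2)))
    },
    gradient = function(x) {
      dx <- sweep(centers, 2, x)           # centers - x
      g <- depths * exp(-rowSums(dx^2) / (2 * w^2)) / w^2
      colSums(g * dx)                      # d/dx of -|x-c|^2/2w^2 term
    },
    parameters = list(type = "four_well_2d", depths = depths,
                      centers = centers, widths = w)
  )
}

#' Reference PMF by direct Boltzmann quadrature
#'
#' Computes the exact potential of mean force along a projection of an
#' analytic potential by trapezoidal integration of
#' \eqn{\exp(-V/k_B T)}, on a quadrature grid `refine` times finer than
#' the requested bins. This is the ground truth that reweighted PMFs
#' from boosted sampling must recover.
#'
#' @param potential a `gamd_potential` (dimension 1 or 2)
#' @param coordinate projection: "x", "y" (2D only), or "xy" for the
#'   full 2D surface
#' @param grid bin edges: numeric vector (1D projection) or list of two
#'   edge vectors ("xy")
#' @param temperature K
#' @param domain range over which any integrated-out coordinate is
#'   quadratured, default the grid range of the kept coordinate
#' @param refine starting quadrature refinement factor per bin (>= 4);
#'   doubled automatically until the PMF changes by < `tol`
#' @param tol convergence tolerance on the PMF values, kcal/mol
#' @param max_refine refinement ceiling; non-convergence at this level
#'   is an error, never silently truncated
#' @return a `pmf_grid` (values in kcal/mol, min over bins = 0)
#' @export
boltzmann_pmf_oracle <- function(potential, coordinate = "x", grid,
                                 temperature = 310, domain = NULL,
                                 refine = 8, tol = 0.01, max_refine = 1024) {
  if (temperature <= 0) stop("temperature must be positive")
  if (refine < 4) stop("quadrature must be at least 4x finer than the bins")
  beta <- 1 / kBT(temperature)
  pmf_prev <- .masses_to_pmf(
    .oracle_masses(potential, coordinate, grid, beta, domain, refine),
    temperature)
  while (refine < max_refine) {
    refine <- 2L * refine
    pmf_next <- .masses_to_pmf(
      .oracle_masses(potential, coordinate, grid, beta, domain, refine),
      temperature)
    dev <- suppressWarnings(
      max(abs(pmf_next$values - pmf_prev$values), na.rm = TRUE))
    pmf_prev <- pmf_next
    if (is.finite(dev) && dev < tol) return(pmf_prev)
  }
  stop(sprintf(
    "quadrature not converged at refinement %d (last change %.3g kcal/mol)",
    refine, dev))
}

# bin masses integral of exp(-beta V) per requested bin. Each bin is
# integrated on its own local trapezoid grid (refine sub-intervals), so
# per-bin masses converge at second order.
.oracle_fine <- function(edges, refine) {
  nb <- length(edges) - 1L
  x <- numeric(0); w <- numeric(0); bin <- integer(0)
  for (i in seq_len(nb)) {
    xs <- seq(edges[i], edges[i + 1], length.out = refine + 1)
    h <- xs[2] - xs[1]
    ws <- rep(h, refine + 1); ws[c(1, refine + 1)] <- h / 2
    x <- c(x, xs); w <- c(w, ws); bin <- c(bin, rep(i, refine + 1))
  }
  list(x = x, w = w, bin = bin)
}

.oracle_masses <- function(potential, coordinate, grid, beta, domain, refine) {
  if (identical(coordinate, "xy")) {
    if (!is.list(grid) || length(grid) != 2) {
      stop("2D PMF needs a list of two edge vectors")
    }
    fx <- .oracle_fine(grid[[1]], refine)
    fy <- .oracle_fine(grid[[2]], refine)
    dens <- vapply(seq_along(fy$x), function(j) {
      vapply(seq_along(fx$x), function(i) {
        exp(-beta * potential$energy(c(fx$x[i], fy$x[j])))
      }, 0)
    }, numeric(length(fx$x)))
    m1 <- rowsum(dens * fx$w, fx$bin)            # integrate x per x-bin
    mass <- t(rowsum(t(m1) * fy$w, fy$bin))      # then y per y-bin
    widths <- outer(diff(grid[[1]]), diff(grid[[2]]))
    return(list(edges = grid, mass = mass, widths = widths))
  }
  keep <- match(coordinate, c("x", "y"))
  if (is.na(keep)) stop("coordinate must be 'x', 'y' or 'xy'")
  if (!is.numeric(grid)) stop("1D projection needs a numeric edge vector")
  fx <- .oracle_fine(grid, refine)
  if (potential$dimension == 1L) {
    if (keep != 1L) stop("1D potential has only coordinate 'x'")
    dens <- vapply(fx$x, function(x) exp(-beta * potential$energy(x)), 0)
    mass <- as.numeric(rowsum(dens * fx$w, fx$bin))
    return(list(edges = list(grid), mass = mass, widths = diff(grid)))
  }
  # 2D potential projected to one coordinate: integrate the other out
  if (is.null(domain)) domain <- range(grid)
  fo <- .oracle_fine(seq(domain[1], domain[2],
                         length.out = length(grid)), refine)
  inner <- vapply(fx$x, function(xi) {
    e <- vapply(fo$x, function(o) {
      pt <- if (keep == 1L) c(xi, o) else c(o, xi)
      exp(-beta * potential$energy(pt))
    }, 0)
    sum(fo$w * e)
  }, 0)
  mass <- as.numeric(rowsum(inner * fx$w, fx$bin))
  list(edges = list(grid), mass = mass, widths = diff(grid))
}

.masses_to_pmf <- function(m, temperature) {
  dens <- m$mass / (sum(m$mass) * m$widths)
  vals <- -kBT(temperature) * log(dens)
  occ <- is.finite(vals)
  vals <- vals - min(vals[occ])
  new_pmf_grid(edges = m$edges, values = vals, counts = NULL, mask = occ,
               metadata = list(source = "boltzmann_quadrature",
                               temperature = temperature))
}

#' Synthetic pose ensemble with planted clusters
#'
#' Draws coordinate frames around perturbed copies of a reference
#' structure: each cluster is a fixed random per-atom displacement of
#' the reference with the requested unfitted-RMSD magnitude, plus
#' isotropic Gaussian noise of the requested spread per frame. The
#' generating cluster labels are stored with the ensemble, so clustering
#' recovery can be scored against ground truth without circularity.
#'
#' @param reference a `pdb_structure` or an n_atoms x 3 coordinate matrix
#' @param n_frames number of frames to draw
#' @param cluster_spec list of specs, each `list(offset=, spread=,
#'   weight=)`: offset is the cluster centre's RMSD to the reference
#'   (Angstrom, unfitted), spread the per-coordinate sd (Angstrom),
#'   weights must sum to 1
#' @param seed integer RNG seed (identical seeds give bit-identical
#'   ensembles)
#' @return a `gamd_trajectory` with `labels` set to the generating
#'   cluster of each frame
#' @export
make_pose_ensemble <- function(reference, n_frames, cluster_spec, seed = 1) {
  xyz <- if (inherits(reference, "pdb_structure")) {
    structure_coords(reference)
  } else {
    as.matrix(reference)
  }
  if (ncol(xyz) != 3) stop("reference coordinates must be n_atoms x 3")
  if (length(cluster_spec) == 0) stop("cluster_spec must not be empty")
  w <- vapply(cluster_spec, function(s) s$weight, 0)
  sp <- vapply(cluster_spec, function(s) s$spread, 0)
  off <- vapply(cluster_spec, function(s) s$offset, 0)
  if (abs(sum(w) - 1) > 1e-8) stop("cluster weights must sum to 1")
  if (any(sp < 0)) stop("spreads must be non-negative")
  n_at <- nrow(xyz)
  dof <- 3L * n_at
  ref <- as.numeric(t(xyz))
  set.seed(seed)
  # fixed per-cluster displacement, scaled to unfitted RMSD = offset
  disp <- lapply(seq_along(cluster_spec), function(i) {
    if (off[i] == 0) return(numeric(dof))
    u <- stats::rnorm(dof)
    u * off[i] / sqrt(sum(u^2) / n_at)
  })
  labels <- sample.int(length(cluster_spec), n_frames, replace = TRUE, prob = w)
  coords <- matrix(0, n_frames, dof)
  for (f in seq_len(n_frames)) {
    k <- labels[f]
    coords[f, ] <- ref + disp[[k]] +
      if (sp[k] > 0) stats::rnorm(dof, sd = sp[k]) else 0
  }
  new_trajectory(
    time = seq_len(n_frames), coords = coords,
    metadata = list(seed = seed, kind = "synthetic_pose_ensemble",
                    n_atoms = n_at, cluster_spec = cluster_spec),
    labels = labels
  )
}
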