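# Independent oracles used across the suite. These deliberately avoid
# the package's own implementation paths.

# central-difference gradient
num_grad <- function(fn, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h; xm[i] <- x[i] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, 0)
}

.quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# brute-force optimal superposition RMSD: quaternion grid search plus
# local simplex refinement; independent of the SVD route
quaternion_rmsd_oracle <- function(mobile, reference, n_grid = 4000) {
  A <- scale(mobile, scale = FALSE)
  B <- scale(reference, scale = FALSE)
  obj_q <- function(q) sqrt(mean(rowSums((A %*% t(.quat_to_rot(q)) - B)^2)))
  qs <- matrix(stats::rnorm(4 * n_grid), ncol = 4)
  vals <- apply(qs, 1, obj_q)
  best <- qs[which.min(vals), ]
  opt <- stats::optim(best, obj_q, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# O(n^3) textbook average-linkage agglomeration halted at the cutoff
naive_average_linkage <- function(dmat, cutoff) {
  n <- nrow(dmat)
  groups <- as.list(seq_len(n))
  repeat {
    m <- length(groups)
    if (m == 1) break
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      d <- mean(dmat[groups[[i]], groups[[j]]])
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    if (bestd > cutoff) break
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (g in seq_along(groups)) lab[groups[[g]]] <- g
  lab
}

# long 1D Metropolis chain at temperature T (K)
metropolis_chain <- function(potential, n, temperature, x0 = 0,
                             step = 0.3, seed = 1) {
  set.seed(seed)
  beta <- 1 / kBT(temperature)
  x <- numeric(n)
  cur <- x0
  ecur <- potential$energy(cur)
  prop <- stats::rnorm(n, sd = step)
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    cand <- cur + prop[i]
    ecand <- potential$energy(cand)
    if (u[i] < exp(-beta * (ecand - ecur))) {
      cur <- cand; ecur <- ecand
    }
    x[i] <- cur
  }
  x
}

# partition agreement ignoring label permutation
adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# separable harmonic potential with `dof` identical 1D modes
make_separable_harmonic <- function(k_spring = 1, dof = 5) {
  new_potential(
    name = "separable_harmonic", dimension = as.integer(dof),
    energy = function(x) 0.5 * k_spring * sum(x^2),
    gradient = function(x) k_spring * x,
    parameters = list(k_spring = k_spring))
}

# zero potential (free particle under restraints)
make_flat_potential <- function(dof = 3) {
  new_potential(
    name = "flat", dimension = as.integer(dof),
    energy = function(x) 0,
    gradient = function(x) numeric(length(x)))
}

# synthetic peptide-like structure built in code (no external data):
# per residue N, CA, C, O (+ CB except GLY) along a loose helix
build_synthetic_peptide <- function(n_res = 6, chain = "A", seed = 11,
                                    resno_start = 1) {
  set.seed(seed)
  resnames <- rep(c("ALA", "GLY", "SER", "LEU"), length.out = n_res)
  atoms <- NULL
  xyz <- NULL
  serial <- 0
  for (r in seq_len(n_res)) {
    base <- c(2.2 * cos(r * 1.7), 2.2 * sin(r * 1.7), 1.5 * r)
    names_r <- c("N", "CA", "C", "O")
    offs <- rbind(c(0, 0, 0), c(1.2, 0.4, 0.3), c(2.1, -0.4, 0.9),
                  c(2.4, -1.5, 0.8))
    if (resnames[r] != "GLY") {
      names_r <- c(names_r, "CB")
      offs <- rbind(offs, c(1.4, 1.6, 1.0))
    }
    for (a in seq_along(names_r)) {
      serial <- serial + 1
      atoms <- rbind(atoms, data.frame(
        serial = serial, name = names_r[a], resname = resnames[r],
        chain = chain, resno = as.integer(resno_start + r - 1), insert = "",
        element = substr(names_r[a], 1, 1), occupancy = 1, b = 0,
        stringsAsFactors = FALSE))
      xyz <- rbind(xyz, base + offs[a, ] + stats::rnorm(3, sd = 0.05))
    }
  }
  structure(list(atoms = atoms, xyz = list(unname(xyz))),
            class = "pdb_structure")
}
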