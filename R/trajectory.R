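#' Trajectory container
#'
#' A `gamd_trajectory` stores time-ordered coordinate frames together with
#' per-frame potential-energy components and the applied boost energy
#' \eqn{\Delta V} (zero everywhere for conventional MD). It is the unit of
#' exchange between the dynamics engine and the analysis modules.
#'
#' @param time numeric vector of frame times (ps), strictly increasing
#' @param coords numeric matrix, one row per frame (coordinates in Angstrom)
#' @param V_total per-frame total potential energy (kcal/mol)
#' @param V_dihedral per-frame dihedral-component energy (kcal/mol); 0 for
#'   analytic potentials without a dihedral class
#' @param dV_total per-frame applied total boost energy (kcal/mol)
#' @param dV_dihedral per-frame applied dihedral boost energy (kcal/mol)
#' @param metadata list of run metadata (seed, temperature, dt, friction,
#'   boost class, run label, save interval)
#' @param labels optional integer ground-truth cluster labels (synthetic
#'   ensembles only)
#' @return object of class `gamd_trajectory`
#' @export
new_trajectory <- function(time, coords, V_total = NULL, V_dihedral = NULL,
                           dV_total = NULL, dV_dihedral = NULL,
                           metadata = list(), labels = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(time) == n)
  if (n > 1 && any(diff(time) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  zero <- rep(0, n)
  traj <- structure(list(
    time = as.numeric(time),
    coords = coords,
    V_total = if (is.null(V_total)) zero else as.numeric(V_total),
    V_dihedral = if (is.null(V_dihedral)) zero else as.numeric(V_dihedral),
    dV_total = if (is.null(dV_total)) zero else as.numeric(dV_total),
    dV_dihedral = if (is.null(dV_dihedral)) zero else as.numeric(dV_dihedral),
    metadata = metadata,
    labels = labels
  ), class = "gamd_trajectory")
  if (any(traj$dV_total < 0) || any(traj$dV_dihedral < 0)) {
    stop("boost energies must be non-negative")
  }
  if (!all(is.finite(traj$V_total))) stop("non-finite potential energies")
  traj
}

#' Number of frames in a trajectory
#' @param traj a `gamd_trajectory`
#' @return integer frame count
#' @export
n_frames <- function(traj) nrow(traj$coords)

#' Total recorded boost energy per frame
#' @param traj a `gamd_trajectory`
#' @return numeric vector, `dV_total + dV_dihedral`
#' @export
boost_series <- function(traj) traj$dV_total + traj$dV_dihedral

#' @export
print.gamd_trajectory <- function(x, ...) {
  cat(sprintf("<gamd_trajectory> %d frames, %d dof, t = [%g, %g] ps\n",
              n_frames(x), ncol(x$coords), x$time[1], x$time[n_frames(x)]))
  if (!is.null(x$metadata$boost_class)) {
    cat(sprintf("  boost class: %s; mean dV = %.4f kcal/mol\n",
                x$metadata$boost_class, mean(boost_series(x))))
  }
  invisible(x)
}
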