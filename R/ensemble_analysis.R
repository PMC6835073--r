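# Conformational clustering and pose ranking: pairwise-RMSD matrices,
# CPPTRAJ-style hierarchical agglomerative clustering with a distance
# cutoff (3.5 A backbone RMSD by convention), ClusPro-style greedy
# radius clustering (0.5 A), and ranking by size or by reweighted free
# energy.

# frames: gamd_trajectory (rows reshaped to n x 3), list of n x 3
# matrices, or a numeric matrix of flat frames
.frames_as_list <- function(frames, selection = NULL) {
  if (inherits(frames, "gamd_trajectory")) frames <- frames$coords
  if (is.matrix(frames)) {
    frames <- lapply(seq_len(nrow(frames)), function(i) {
      matrix(frames[i, ], ncol = 3, byrow = TRUE)
    })
  }
  if (!is.null(selection)) {
    frames <- lapply(frames, function(m) m[selection, , drop = FALSE])
  }
  frames
}

#' Pairwise RMSD matrix over trajectory frames
#'
#' @param frames a `gamd_trajectory` (3D coordinates), list of n x 3
#'   matrices, or matrix of flattened frames
#' @param selection optional `atom_selection` applied to every frame
#' @param fit "pairwise" (Kabsch superposition per pair) or "none"
#'   (frames already share a common reference frame)
#' @return symmetric matrix with zero diagonal, Angstrom
#' @export
pairwise_rmsd_matrix <- function(frames, selection = NULL,
                                 fit = c("pairwise", "none")) {
  fit <- match.arg(fit)
  fl <- .frames_as_list(frames, selection)
  n <- length(fl)
  if (n < 2) stop("need at least 2 frames")
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- tryCatch(rmsd_fit(fl[[i]], fl[[j]], fit = fit == "pairwise"),
                    error = function(e) {
                      stop(sprintf("frames %d/%d: %s", i, j,
                                   conditionMessage(e)), call. = FALSE)
                    })
      M[i, j] <- r; M[j, i] <- r
    }
  }
  M
}

.check_dmat <- function(dmat) {
  dmat <- as.matrix(dmat)
  if (nrow(dmat) != ncol(dmat) || max(abs(dmat - t(dmat))) > 1e-8) {
    stop("distance matrix must be symmetric")
  }
  if (any(dmat < 0)) stop("distance matrix has negative entries")
  dmat
}

.mk_cluster <- function(members, dmat) {
  if (length(members) == 1) {
    rep <- members
  } else {
    sub <- dmat[members, members, drop = FALSE]
    rep <- members[which.min(rowMeans(sub))]  # medoid
  }
  list(members = members, representative = rep, size = length(members),
       rmsd_ref = NA_real_, free_energy = NA_real_)
}

#' Hierarchical agglomerative clustering with a distance cutoff
#'
#' Bottom-up agglomeration (average linkage by default, as in CPPTRAJ)
#' halted when the minimum inter-cluster linkage exceeds the cutoff;
#' every frame is assigned. Representatives are medoids (member with
#' minimal mean distance to co-members).
#'
#' @param dmat symmetric pairwise distance matrix, Angstrom
#' @param cutoff linkage cutoff, Angstrom (3.5 A is the conventional
#'   backbone-RMSD choice for pose clustering)
#' @param linkage "average", "single" or "complete"
#' @return list of cluster results, largest first
#' @export
hier_agglom_cluster <- function(dmat, cutoff = 3.5,
                                linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  dmat <- .check_dmat(dmat)
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- nrow(dmat)
  if (n == 1) return(list(.mk_cluster(1L, dmat)))
  hc <- stats::hclust(stats::as.dist(dmat), method = linkage)
  lab <- stats::cutree(hc, h = cutoff)
  cl <- unname(lapply(split(seq_len(n), lab), .mk_cluster, dmat = dmat))
  cl[order(-vapply(cl, `[[`, 0L, "size"))]
}

#' Greedy radius clustering
#'
#' The ClusPro-style greedy algorithm: repeatedly pick the unassigned
#' item with the most unassigned neighbors within `radius` (lowest
#' index on ties) as a centroid, assign it and those neighbors to a new
#' cluster, remove them, and repeat. Every member lies within `radius`
#' of its centroid.
#'
#' @param dmat symmetric pairwise distance matrix
#' @param radius cluster radius (0.5 A is the conventional
#'   fragment-clustering choice)
#' @return list of cluster results in creation order (first cluster is
#'   membership-maximal); the representative is the centroid item
#' @export
greedy_cluster <- function(dmat, radius = 0.5) {
  dmat <- .check_dmat(dmat)
  if (radius <= 0) stop("radius must be positive")
  n <- nrow(dmat)
  remaining <- rep(TRUE, n)
  out <- list()
  while (any(remaining)) {
    idx <- which(remaining)
    counts <- vapply(idx, function(i) {
      sum(dmat[i, idx] <= radius)
    }, 0L)
    centroid <- idx[which.max(counts)]  # lowest index on ties
    members <- idx[dmat[centroid, idx] <= radius]
    cl <- .mk_cluster(members, dmat)
    cl$representative <- centroid
    out[[length(out) + 1]] <- cl
    remaining[members] <- FALSE
  }
  out
}

#' Rank clusters by size or reweighted free energy
#'
#' Free-energy mode computes each cluster's reweighted population
#' \eqn{p_c = \sum_{i \in c} e^{\beta \Delta V_i} / \sum_i e^{\beta
#' \Delta V_i}} and reports \eqn{-k_B T \ln p_c}, shifted so the
#' rank-1 cluster reads exactly 0.00 (log-sum-exp internally). With
#' \eqn{\Delta V \equiv 0} this reduces exactly to population ranking.
#' Size mode sorts by member count, descending. Ties break by the other
#' criterion, then by lowest representative index.
#'
#' @param clusters list of cluster results (from the clustering
#'   operations)
#' @param mode "size" or "free_energy"
#' @param samples a `weighted_samples` whose frames the cluster member
#'   indices refer to (required for free-energy mode: supplies per-frame
#'   boost and beta)
#' @return object of class `cluster_report`: ranked clusters plus the
#'   ranking criterion
#' @export
rank_clusters <- function(clusters, mode = c("size", "free_energy"),
                          samples = NULL) {
  mode <- match.arg(mode)
  if (!length(clusters)) stop("empty cluster list")
  if (mode == "free_energy") {
    if (is.null(samples)) stop("free-energy ranking needs weighted samples")
    beta <- samples$beta
    ldV <- beta * samples$dV
    ltot <- .logsumexp(ldV)
    fe <- unname(vapply(clusters, function(cl) {
      -(.logsumexp(ldV[cl$members]) - ltot) / beta
    }, 0))
    for (i in seq_along(clusters)) clusters[[i]]$free_energy <- fe[i]
    ord <- order(fe, -vapply(clusters, `[[`, 0L, "size"),
                 vapply(clusters, `[[`, 0L, "representative"))
    clusters <- clusters[ord]
    f0 <- clusters[[1]]$free_energy
    for (i in seq_along(clusters)) {
      clusters[[i]]$free_energy <- clusters[[i]]$free_energy - f0
    }
  } else {
    sizes <- vapply(clusters, `[[`, 0L, "size")
    fe <- vapply(clusters, `[[`, 0, "free_energy")
    fe[is.na(fe)] <- Inf
    ord <- order(-sizes, fe, vapply(clusters, `[[`, 0L, "representative"))
    clusters <- clusters[ord]
  }
  structure(list(clusters = clusters, criterion = mode,
                 n_frames = sum(vapply(clusters, `[[`, 0L, "size"))),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %d clusters over %d frames, ranked by %s\n",
              length(x$clusters), x$n_frames, x$criterion))
  invisible(x)
}

#' Top-ranked cluster table
#'
#' The per-system comparison table: one row per top-ranked cluster with
#' its size, representative RMSD to the reference and free energy
#' (rank 1 is 0.00 by the shift convention). When fewer than `n`
#' clusters exist the table has fewer rows and carries an explicit
#' annotation (attribute `note`).
#'
#' @param report a `cluster_report`
#' @param rmsd_to_ref optional per-frame RMSD to the reference
#'   structure, Angstrom (indexed like the clustered frames);
#'   representative values are reported
#' @param n number of clusters to report (default 10)
#' @return data frame with columns rank, cluster size, representative
#'   frame, RMSD (A) and PMF (kcal/mol); attribute `note` explains
#'   missing rows
#' @export
report_top_clusters <- function(report, rmsd_to_ref = NULL, n = 10) {
  k <- min(n, length(report$clusters))
  cl <- report$clusters[seq_len(k)]
  df <- data.frame(
    rank = seq_len(k),
    size = vapply(cl, `[[`, 0L, "size"),
    representative = vapply(cl, `[[`, 0L, "representative"),
    rmsd_A = vapply(cl, function(c) {
      if (!is.null(rmsd_to_ref)) rmsd_to_ref[c$representative]
      else c$rmsd_ref
    }, 0),
    pmf_kcal_mol = vapply(cl, `[[`, 0, "free_energy"))
  if (k < n) {
    attr(df, "note") <- sprintf(
      "only %d clusters were obtained; no values for clusters %d-%d",
      k, k + 1, n)
  }
  df
}
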