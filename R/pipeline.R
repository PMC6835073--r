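# Orchestration of the full refinement workflow on toy systems:
# simulate (staged protocol), reweight (PMF recovery) and refine
# (cluster + rank + report), with seeded reproducibility and
# machine-readable manifests.

#' Default run configuration
#'
#' The default toy system is the asymmetric double well under the
#' production study conditions (6 kcal/mol barrier, 2 kcal/mol tilt,
#' 310 K). The staged protocol keeps the reference stage ordering
#' (statistics, then adaptive boost equilibration, then four
#' independent production runs); stage lengths are sized so the
#' adaptive statistics converge at desk scale — the boost equilibration
#' must be long enough to visit the barrier region, otherwise the
#' frozen threshold E underestimates the sampled energy range.
#'
#' @param system "double_well", "four_well_2d" or "bead_chain"
#' @param seed base integer seed
#' @return nested configuration list (serializable with
#'   [write_run_config()])
#' @export
default_config <- function(system = "double_well", seed = 1) {
  list(
    system = switch(system,
      double_well = list(type = "double_well", barrier_height = 6,
                         well_separation = 2, asymmetry = 2, mass = 12,
                         start = -1),
      four_well_2d = list(type = "four_well_2d",
                          depths = c(-5, -3, -3, -1), widths = 0.4,
                          mass = 12, start = c(-1, -1)),
      bead_chain = list(type = "bead_chain", n_beads = 6, mass = 12),
      stop(sprintf("unknown system '%s'", system))),
    protocol = list(min_sd = 200, min_cg = 200, heat_steps = 2500,
                    eq_steps = 2500, cmd_stats_steps = 5000,
                    gamd_eq_steps = 250000, n_production = 4,
                    prod_steps = 600000),
    md = list(dt = 0.002, friction = 1, temperature = 310,
              save_interval = 100, restraint_k = 1),
    gamd = list(sigma_0 = 6, bound_mode = "lower", boost_class = "dual"),
    analysis = list(bin_width = 0.1, rmsd_bin_width = 0.5,
                    cluster_cutoff = 3.5, greedy_radius = 0.5,
                    cumulant_order = 2, min_bin_count = 10,
                    linkage = "average", n_top = 10),
    seed = seed
  )
}

#' Instantiate the system described by a configuration
#'
#' @param config configuration list (see [default_config()])
#' @return list with `potential` (a `gamd_potential`) and `state`
#'   (starting `system_state`)
#' @export
build_system <- function(config) {
  sys <- config$system
  if (sys$type == "double_well") {
    pot <- make_double_well(sys$barrier_height, sys$well_separation,
                            sys$asymmetry %||% 0)
    x0 <- sys$start %||% (-sys$well_separation / 2)
  } else if (sys$type == "four_well_2d") {
    pot <- make_four_well_2d(depths = sys$depths %||% c(-5, -3, -3, -1),
                             widths = sys$widths %||% 0.4)
    x0 <- sys$start %||% c(-1, -1)
  } else if (sys$type == "bead_chain") {
    model <- make_bead_chain(n_beads = sys$n_beads %||% 6,
                             masses = sys$mass %||% 12)
    pot <- bead_chain_potential(model)
    x0 <- bead_chain_extended(model)
  } else {
    stop(sprintf("unknown system type '%s'", sys$type))
  }
  list(potential = pot,
       state = new_system_state(x0, masses = sys$mass %||% 12))
}

.write_manifest <- function(outdir, config, extra = list()) {
  files <- setdiff(list.files(outdir, recursive = TRUE), "manifest.json")
  sums <- tools::md5sum(file.path(outdir, files))
  names(sums) <- files
  manifest <- c(list(
    generator = sprintf("gamdtk %s",
                        as.character(utils::packageVersion("gamdtk"))),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config,
    checksums = as.list(sums)
  ), extra)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

.prepare_outdir <- function(outdir, force) {
  if (is.null(outdir)) return(invisible(NULL))
  if (file.exists(file.path(outdir, "manifest.json")) && !force) {
    stop(sprintf(
      "output directory '%s' already holds a run; use force = TRUE to overwrite",
      outdir))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
}

#' Run the staged simulation protocol from a configuration
#'
#' Executes minimize, restrained heating, equilibration, cMD statistics
#' collection, adaptive GaMD equilibration and the independent
#' production runs, then (optionally) writes the per-run artifacts:
#' `gamd_production_<i>.log`, `trajectory_<i>.tsv`, the frozen boost
#' parameters, the configuration and a checksummed manifest.
#'
#' @param config configuration list (see [default_config()])
#' @param outdir output directory, or NULL to skip writing
#' @param force overwrite an existing run directory
#' @return (invisibly) the [run_protocol()] result, with `manifest`
#'   attached when artifacts were written
#' @export
cmd_simulate <- function(config = default_config(), outdir = NULL,
                         force = FALSE) {
  .prepare_outdir(outdir, force)
  sys <- build_system(config)
  res <- run_protocol(
    sys$potential, sys$state,
    schedule = config$protocol,
    temperature = config$md$temperature, dt = config$md$dt,
    friction = config$md$friction,
    save_interval = config$md$save_interval,
    restraint_k = config$md$restraint_k,
    sigma_0 = config$gamd$sigma_0, bound_mode = config$gamd$bound_mode,
    boost_class = config$gamd$boost_class, seed = config$seed)
  if (!is.null(outdir)) {
    for (i in seq_along(res$production)) {
      write_gamd_log(res$production[[i]],
                     file.path(outdir, sprintf("gamd_production_%d.log", i)))
      write_trajectory_table(res$production[[i]],
                             file.path(outdir, sprintf("trajectory_%d.tsv", i)))
    }
    yaml::write_yaml(params_to_list(res$params),
                     file.path(outdir, "gamd_params.yaml"))
    write_run_config(config, file.path(outdir, "config.yaml"))
    res$manifest <- .write_manifest(outdir, config,
                                    extra = list(seeds = res$seeds))
  }
  invisible(res)
}

#' Reweight trajectories to PMF surfaces
#'
#' Builds pooled weighted samples from production runs (or gamd.log +
#' coordinate files) and returns the unweighted, exponential and
#' cumulant PMFs together with the boost-distribution diagnostics.
#'
#' @param trajectories list of `gamd_trajectory`, or character paths to
#'   trajectory tables
#' @param config configuration list
#' @param coord_fn function(trajectory) -> reaction coordinate(s); the
#'   default uses the first coordinate column
#' @param bins bin edges (numeric vector or list of two); default built
#'   from the sampled range at `config$analysis$bin_width`
#' @param outdir optional output directory for PMF tables
#' @param force overwrite existing outputs
#' @return list with `samples`, `pmf_unweighted`, `pmf_exponential`,
#'   `pmf_cumulant`, `anharmonicity` and the per-run frame counts
#' @export
cmd_reweight <- function(trajectories, config = default_config(),
                         coord_fn = function(tr) tr$coords[, 1],
                         bins = NULL, outdir = NULL, force = FALSE) {
  .prepare_outdir(outdir, force)
  if (is.character(trajectories)) {
    trajectories <- lapply(trajectories, read_trajectory_table)
  }
  samples <- combine_runs(trajectories, coord_fn = coord_fn)
  if (is.null(bins)) {
    bw <- config$analysis$bin_width
    d <- ncol(samples$coords)
    mk <- function(v) {
      r <- range(v)
      seq(floor(r[1] / bw) * bw, ceiling(r[2] / bw) * bw, by = bw)
    }
    bins <- if (d == 1) mk(samples$coords[, 1])
            else list(mk(samples$coords[, 1]), mk(samples$coords[, 2]))
  }
  order <- config$analysis$cumulant_order
  min_ct <- config$analysis$min_bin_count
  out <- list(
    samples = samples,
    pmf_unweighted = pmf_unweighted(samples, bins),
    pmf_exponential = pmf_exponential(samples, bins),
    pmf_cumulant = pmf_cumulant(samples, bins, order = order,
                                min_count = min_ct),
    anharmonicity = if (length(samples$dV) >= 100) {
      anharmonicity(samples$dV)
    } else {
      NA_real_  # diagnostic needs >= 100 frames
    },
    frames_per_run = table(samples$run))
  if (!is.null(outdir)) {
    write_pmf_table(out$pmf_unweighted, file.path(outdir, "pmf_unweighted.tsv"))
    write_pmf_table(out$pmf_cumulant,
                    file.path(outdir, sprintf("pmf_cumulant%d.tsv", order)))
    write_pmf_table(out$pmf_exponential,
                    file.path(outdir, "pmf_exponential.tsv"))
    yaml::write_yaml(list(anharmonicity = out$anharmonicity,
                          n_frames = length(samples$dV)),
                     file.path(outdir, "diagnostics.yaml"))
    .write_manifest(outdir, config)
  }
  out
}

#' Cluster, rank and report refined poses
#'
#' The end-of-pipeline analysis: pairwise-RMSD clustering of pooled
#' frames, reweighted free-energy ranking, the top-N cluster table
#' (rank-1 free energy 0.00 by convention; fewer-than-N clusters are
#' annotated) and a 1D PMF over the reference-RMSD coordinate. Frames
#' without boost data are analysed unweighted with a prominent warning.
#'
#' @param frames a `gamd_trajectory` of 3D coordinate frames, or a list
#'   of such trajectories (pooled)
#' @param reference reference structure: `pdb_structure` or n x 3
#'   coordinate matrix
#' @param config configuration list
#' @param selection optional `atom_selection` for the RMSD computations
#' @param fit "none" for pre-aligned ensembles (default) or "pairwise"
#' @param n_top rows in the report (default from config)
#' @param outdir optional output directory
#' @param force overwrite existing outputs
#' @return list with `report` (a `cluster_report`), `table` (top-N data
#'   frame), `rmsd_to_ref`, `pmf` (over the RMSD coordinate) and
#'   `samples`
#' @export
cmd_refine <- function(frames, reference, config = default_config(),
                       selection = NULL, fit = "none", n_top = NULL,
                       outdir = NULL, force = FALSE) {
  .prepare_outdir(outdir, force)
  if (inherits(frames, "gamd_trajectory")) frames <- list(frames)
  pooled <- do.call(rbind, lapply(frames, `[[`, "coords"))
  dV <- unlist(lapply(frames, boost_series))
  temp <- frames[[1]]$metadata$temperature %||% 310
  if (all(dV == 0)) {
    warning("no boost data in input frames: falling back to unweighted ",
            "(population) analysis", immediate. = TRUE)
  }
  ref_xyz <- if (inherits(reference, "pdb_structure")) {
    structure_coords(reference)
  } else {
    as.matrix(reference)
  }
  if (!is.null(selection)) ref_xyz <- ref_xyz[selection, , drop = FALSE]
  fl <- .frames_as_list(pooled, selection)
  rmsd_ref <- vapply(fl, function(m) {
    rmsd_fit(m, ref_xyz, fit = fit == "pairwise")
  }, 0)
  dmat <- pairwise_rmsd_matrix(fl, fit = fit)
  clusters <- hier_agglom_cluster(dmat,
                                  cutoff = config$analysis$cluster_cutoff,
                                  linkage = config$analysis$linkage)
  samples <- new_weighted_samples(coords = rmsd_ref, dV = dV,
                                  temperature = temp)
  report <- rank_clusters(clusters, mode = "free_energy", samples = samples)
  n_top <- n_top %||% config$analysis$n_top
  tab <- report_top_clusters(report, rmsd_to_ref = rmsd_ref, n = n_top)
  bw <- config$analysis$rmsd_bin_width
  edges <- seq(0, ceiling(max(rmsd_ref) / bw) * bw + bw, by = bw)
  pmf <- pmf_cumulant(samples, edges, order = config$analysis$cumulant_order,
                      min_count = min(config$analysis$min_bin_count,
                                      length(rmsd_ref)))
  out <- list(report = report, table = tab, rmsd_to_ref = rmsd_ref,
              pmf = pmf, samples = samples, dmat = dmat)
  if (!is.null(outdir)) {
    tf <- file.path(outdir, "top_clusters.tsv")
    utils::write.table(format(tab, digits = 4), tf, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (!is.null(attr(tab, "note"))) {
      cat(sprintf("# %s\n", attr(tab, "note")), file = tf, append = TRUE)
    }
    write_pmf_table(pmf, file.path(outdir, "pmf_rmsd.tsv"))
    if (inherits(reference, "pdb_structure") && is.null(selection)) {
      reps <- vapply(report$clusters, `[[`, 0L, "representative")
      rep_struct <- reference
      rep_struct$xyz <- lapply(reps, function(r) {
        matrix(pooled[r, ], ncol = 3, byrow = TRUE)
      })
      write_pdb(rep_struct, file.path(outdir, "representatives.pdb"))
    }
    .write_manifest(outdir, config)
  }
  out
}

#' Count barrier crossings of a 1D trajectory
#'
#' Hysteresis counter for double-well transitions: a crossing is
#' recorded each time the coordinate passes from below `-margin` to
#' above `+margin` around the dividing point, or back.
#'
#' @param traj a `gamd_trajectory` (first coordinate used) or numeric
#'   series
#' @param barrier dividing point (default 0)
#' @param margin hysteresis half-width, Angstrom
#' @return integer number of well-to-well transitions
#' @export
count_crossings <- function(traj, barrier = 0, margin = 0.5) {
  x <- if (inherits(traj, "gamd_trajectory")) traj$coords[, 1] else as.numeric(traj)
  side <- ifelse(x < barrier - margin, -1L, ifelse(x > barrier + margin, 1L, 0L))
  side <- side[side != 0L]
  if (!length(side)) return(0L)
  sum(diff(side) != 0L)
}
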