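# On-disk formats, all plain text and versioned:
#   gamd.log        per-frame energy/boost record (reweighting input)
#   trajectory .tsv per-frame time, energy components and coordinates
#   run config      YAML (sectioned key-value)

.GAMD_LOG_HEADER <- "# gamdtk gamd.log v1"
.TRAJ_TABLE_HEADER <- "# gamdtk trajectory v1"

#' Write a per-frame energy/boost log
#'
#' Tab-separated columns: time_ps, V_total, V_dihedral, dV_total,
#' dV_dihedral (kcal/mol). This file is the reweighting input.
#'
#' @param traj a `gamd_trajectory`
#' @param path output file
#' @return the path, invisibly
#' @export
write_gamd_log <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(.GAMD_LOG_HEADER,
               sprintf("# temperature_K: %.4f",
                       traj$metadata$temperature %||% NA),
               sprintf("# label: %s", traj$metadata$label %||% "run")), con)
  df <- data.frame(time_ps = traj$time, V_total = traj$V_total,
                   V_dihedral = traj$V_dihedral, dV_total = traj$dV_total,
                   dV_dihedral = traj$dV_dihedral)
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a gamd.log energy/boost record
#'
#' @param path file written by [write_gamd_log()] (or any table with
#'   the same columns)
#' @return data frame with attribute `temperature`
#' @export
read_gamd_log <- function(path) {
  lines <- readLines(path, n = 5)
  temp <- NA_real_
  m <- grep("^# temperature_K:", lines, value = TRUE)
  if (length(m)) temp <- as.numeric(sub("^# temperature_K:", "", m[1]))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("time_ps", "V_total", "V_dihedral", "dV_total", "dV_dihedral")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s' is not a gamd.log (missing columns: %s)", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  }
  attr(df, "temperature") <- temp
  df
}

#' Write a trajectory as a plain-text table
#'
#' One row per frame: time, energy components, boost energies and the
#' flat coordinate vector at 12 significant digits (the declared
#' round-trip precision).
#'
#' @param traj a `gamd_trajectory`
#' @param path output file
#' @return the path, invisibly
#' @export
write_trajectory_table <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  md <- traj$metadata
  writeLines(c(.TRAJ_TABLE_HEADER,
               sprintf("# dof: %d", ncol(traj$coords)),
               sprintf("# temperature_K: %.4f", md$temperature %||% NA),
               sprintf("# dt_ps: %s", md$dt %||% NA),
               sprintf("# friction_per_ps: %s", md$friction %||% NA),
               sprintf("# boost_class: %s", md$boost_class %||% "none"),
               sprintf("# label: %s", md$label %||% "run"),
               sprintf("# seed: %s", md$seed %||% NA)), con)
  df <- data.frame(time_ps = traj$time, V_total = traj$V_total,
                   V_dihedral = traj$V_dihedral, dV_total = traj$dV_total,
                   dV_dihedral = traj$dV_dihedral)
  cm <- traj$coords
  colnames(cm) <- sprintf("x%d", seq_len(ncol(cm)))
  out <- cbind(df, as.data.frame(cm))
  utils::write.table(format(out, digits = 12, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory table
#'
#' @param path file written by [write_trajectory_table()]
#' @return a `gamd_trajectory`
#' @export
read_trajectory_table <- function(path) {
  hdr <- readLines(path, n = 10)
  get <- function(key) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(m)) trimws(sub(sprintf("^# %s:", key), "", m[1])) else NA
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  xc <- grep("^x[0-9]+$", names(df))
  new_trajectory(
    time = df$time_ps, coords = as.matrix(df[, xc, drop = FALSE]),
    V_total = df$V_total, V_dihedral = df$V_dihedral,
    dV_total = df$dV_total, dV_dihedral = df$dV_dihedral,
    metadata = list(temperature = as.numeric(get("temperature_K")),
                    dt = as.numeric(get("dt_ps")),
                    friction = as.numeric(get("friction_per_ps")),
                    boost_class = get("boost_class"),
                    label = get("label"),
                    seed = suppressWarnings(as.integer(get("seed")))))
}

#' Serialize GaMD boost parameters
#'
#' @param params a boost parameter set from [gamd_boost_set()]
#' @return plain list suitable for YAML/JSON
#' @export
params_to_list <- function(params) {
  one <- function(p) {
    if (is.null(p)) return(NULL)
    list(bound_mode = p$bound_mode, component = p$component, E = p$E,
         k = p$k, k0 = p$k0, sigma_0 = p$sigma_0,
         stats = list(V_max = p$stats$V_max, V_min = p$stats$V_min,
                      V_avg = p$stats$V_avg, sigma_V = p$stats$sigma_V,
                      n_samples = p$stats$n_samples))
  }
  list(class = params$class, total = one(params$total),
       dihedral = one(params$dihedral))
}

#' Write/read a run configuration (YAML)
#'
#' @param config nested configuration list
#' @param path file path
#' @return `write_run_config` the path; `read_run_config` the list
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
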