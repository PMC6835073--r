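#' Binned free-energy surface
#'
#' Container for a 1D or 2D potential-of-mean-force estimate: bin edges,
#' PMF values in kcal/mol, raw occupancy counts and an occupancy mask.
#' By convention the minimum over occupied bins is 0; bins below the
#' occupancy cutoff are masked (`NA` in `values`), never reported as 0.
#'
#' @param edges list of numeric bin-edge vectors (length 1 or 2)
#' @param values numeric vector (1D) or matrix (2D) of PMF values,
#'   kcal/mol
#' @param counts raw sample counts per bin (NULL for quadrature oracles)
#' @param mask logical occupancy mask, same shape as `values`
#' @param metadata list (temperature, estimator, cumulant order, ...)
#' @return object of class `pmf_grid`
#' @export
new_pmf_grid <- function(edges, values, counts = NULL, mask = NULL,
                         metadata = list()) {
  if (!is.list(edges)) edges <- list(edges)
  dim_n <- length(edges)
  stopifnot(dim_n %in% c(1L, 2L))
  if (is.null(mask)) mask <- is.finite(values)
  if (!any(mask)) stop("PMF grid has no occupied bins")
  values[!mask] <- NA_real_
  # shift convention: minimum over occupied bins is 0
  values <- values - min(values[mask])
  structure(list(edges = edges, values = values, counts = counts,
                 mask = mask, dimension = dim_n, metadata = metadata),
            class = "pmf_grid")
}

#' Bin midpoints of a PMF grid
#' @param pmf a `pmf_grid`
#' @return list of midpoint vectors, one per dimension
#' @export
pmf_midpoints <- function(pmf) {
  lapply(pmf$edges, function(e) (e[-1] + e[-length(e)]) / 2)
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat(sprintf("<pmf_grid> %dD, %s bins (%d occupied), range [0, %.3f] kcal/mol\n",
              x$dimension,
              paste(vapply(x$edges, function(e) length(e) - 1L, 1L),
                    collapse = " x "),
              sum(x$mask), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Write a PMF grid as a plain-text table
#'
#' One row per occupied bin: bin midpoints (Angstrom), PMF (kcal/mol)
#' and raw count. Masked bins are written with `NA` PMF so downstream
#' consumers can distinguish "unsampled" from "zero".
#'
#' @param pmf a `pmf_grid`
#' @param path output file
#' @return the path, invisibly
#' @export
write_pmf_table <- function(pmf, path) {
  mids <- pmf_midpoints(pmf)
  if (pmf$dimension == 1L) {
    df <- data.frame(coord1_A = mids[[1]], pmf_kcal_mol = as.numeric(pmf$values),
                     count = if (is.null(pmf$counts)) NA else as.numeric(pmf$counts))
  } else {
    g <- expand.grid(coord1_A = mids[[1]], coord2_A = mids[[2]])
    df <- data.frame(g, pmf_kcal_mol = as.numeric(pmf$values),
                     count = if (is.null(pmf$counts)) NA else as.numeric(pmf$counts))
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
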