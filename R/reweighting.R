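# Energetic reweighting: recover unbiased PMF profiles from boosted
# trajectories. The biased histogram density in each reaction-coordinate
# bin is corrected by the bin-conditional average of exp(beta*dV),
# either exactly (exponential average, computed with log-sum-exp) or by
# a truncated cumulant expansion
#   ln<exp(beta dV)> ~ beta*C1 + beta^2/2 C2 + beta^3/6 C3,
# which is the numerically stable default because dV is near-Gaussian
# by construction of the boost.

#' Pooled weighted samples for reweighting
#'
#' @param coords matrix of per-frame reaction-coordinate values (1 or 2
#'   columns), or a numeric vector for one coordinate
#' @param dV per-frame total boost energy, kcal/mol (>= 0)
#' @param temperature K
#' @param run labels identifying the source run of each frame
#' @return object of class `weighted_samples` with `beta` in mol/kcal
#' @export
new_weighted_samples <- function(coords, dV, temperature = 310,
                                 run = NULL) {
  coords <- as.matrix(coords)
  if (length(dV) != nrow(coords)) {
    stop("coordinate and dV lengths differ")
  }
  if (any(dV < 0)) stop("boost energies must be non-negative")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(coords = coords, dV = as.numeric(dV),
                 beta = 1 / kBT(temperature), temperature = temperature,
                 run = if (is.null(run)) rep("run1", length(dV)) else run),
            class = "weighted_samples")
}

#' Combine independent runs into one pooled sample set
#'
#' Frames from all runs are pooled with equal weight; provenance labels
#' are retained. Run temperatures must agree to 0.1 K.
#'
#' @param trajectories list of `gamd_trajectory` objects
#' @param coord_fn function(trajectory) -> per-frame reaction
#'   coordinate(s) (vector or matrix); default uses the first
#'   coordinate column
#' @param temperature K; defaults to the metadata temperature of the
#'   first run
#' @return a `weighted_samples`
#' @export
combine_runs <- function(trajectories,
                         coord_fn = function(tr) tr$coords[, 1],
                         temperature = NULL) {
  stopifnot(length(trajectories) >= 1)
  temps <- vapply(trajectories, function(tr) {
    tt <- tr$metadata$temperature
    if (is.null(tt)) NA_real_ else tt
  }, 0)
  if (is.null(temperature)) {
    temperature <- temps[which(!is.na(temps))[1]]
    if (is.na(temperature)) temperature <- 310
  }
  bad <- which(!is.na(temps) & abs(temps - temperature) > 0.1)
  if (length(bad)) {
    stop(sprintf("temperature mismatch in run(s) %s (> 0.1 K)",
                 paste(bad, collapse = ", ")))
  }
  parts <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    if (n_frames(tr) == 0) {
      warning(sprintf("run %d contributes no frames", i))
      return(NULL)
    }
    lab <- tr$metadata$label
    if (is.null(lab)) lab <- sprintf("run%d", i)
    list(coords = as.matrix(coord_fn(tr)), dV = boost_series(tr),
         run = rep(lab, n_frames(tr)))
  })
  parts <- Filter(Negate(is.null), parts)
  if (!length(parts)) stop("no frames in any run")
  new_weighted_samples(
    coords = do.call(rbind, lapply(parts, `[[`, "coords")),
    dV = unlist(lapply(parts, `[[`, "dV")),
    temperature = temperature,
    run = unlist(lapply(parts, `[[`, "run")))
}

# assign samples to bins; returns list(idx (flat bin id or NA), nbin,
# widths vector/matrix per flat bin)
.bin_samples <- function(coords, bins) {
  if (!is.list(bins)) bins <- list(bins)
  d <- length(bins)
  stopifnot(ncol(coords) == d)
  nb <- vapply(bins, function(e) length(e) - 1L, 1L)
  ix <- findInterval(coords[, 1], bins[[1]], rightmost.closed = TRUE)
  ix[ix < 1 | ix > nb[1]] <- NA
  if (d == 2) {
    iy <- findInterval(coords[, 2], bins[[2]], rightmost.closed = TRUE)
    iy[iy < 1 | iy > nb[2]] <- NA
    flat <- ix + (iy - 1L) * nb[1]
    widths <- as.numeric(outer(diff(bins[[1]]), diff(bins[[2]])))
  } else {
    flat <- ix
    widths <- diff(bins[[1]])
  }
  list(flat = flat, nbin = prod(nb), dims = nb, widths = widths,
       edges = bins)
}

.shape <- function(v, dims) if (length(dims) == 2) matrix(v, dims[1], dims[2]) else v

#' Unweighted (biased) PMF from sample histograms
#'
#' \eqn{-k_B T \ln} of the histogram density, shifted so the occupied
#' minimum is 0. For boosted data this is the biased baseline that
#' reweighting corrects.
#'
#' @param samples a `weighted_samples`
#' @param bins bin edges: numeric vector (1D) or list of two edge
#'   vectors (2D)
#' @param min_count bins with fewer samples are masked
#' @return a `pmf_grid`
#' @export
pmf_unweighted <- function(samples, bins, min_count = 1) {
  b <- .bin_samples(samples$coords, bins)
  counts <- tabulate(b$flat[!is.na(b$flat)], nbins = b$nbin)
  if (!any(counts > 0)) stop("no samples fall inside the grid")
  n_tot <- sum(counts)
  dens <- counts / (n_tot * b$widths)
  pmf <- -log(dens) / samples$beta
  mask <- counts >= max(1, min_count)
  if (!any(mask)) stop("no bin reaches the minimum count")
  new_pmf_grid(edges = b$edges, values = .shape(pmf, b$dims),
               counts = .shape(counts, b$dims), mask = .shape(mask, b$dims),
               metadata = list(estimator = "unweighted",
                               temperature = samples$temperature))
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Exponential-average reweighted PMF
#'
#' Exact Boltzmann reweighting: each bin's density is multiplied by the
#' bin-conditional mean of \eqn{e^{\beta \Delta V}}, i.e. each frame
#' carries weight \eqn{e^{\beta \Delta V_i}}. Computed in log space
#' (log-sum-exp), so large boosts never overflow.
#'
#' @inheritParams pmf_unweighted
#' @return a `pmf_grid`
#' @export
pmf_exponential <- function(samples, bins, min_count = 1) {
  b <- .bin_samples(samples$coords, bins)
  ok <- !is.na(b$flat)
  if (!any(ok)) stop("no samples fall inside the grid")
  counts <- tabulate(b$flat[ok], nbins = b$nbin)
  ldV <- samples$beta * samples$dV[ok]
  flat <- b$flat[ok]
  logw <- rep(-Inf, b$nbin)
  sp <- split(ldV, flat)
  for (nm in names(sp)) logw[as.integer(nm)] <- .logsumexp(sp[[nm]])
  # log reweighted density (unnormalized); normalization drops in shift
  logp <- logw - log(b$widths)
  pmf <- -logp / samples$beta
  mask <- counts >= max(1, min_count)
  if (!any(mask)) stop("no bin reaches the minimum count")
  new_pmf_grid(edges = b$edges, values = .shape(pmf, b$dims),
               counts = .shape(counts, b$dims), mask = .shape(mask, b$dims),
               metadata = list(estimator = "exponential",
                               temperature = samples$temperature))
}

#' Cumulant-expansion reweighted PMF
#'
#' Per-bin truncated cumulant expansion of the reweighting factor:
#' \eqn{\ln\langle e^{\beta \Delta V}\rangle \approx \sum_{j=1}^{order}
#' \beta^j C_j / j!} with \eqn{C_1} the mean, \eqn{C_2} the (population)
#' variance and \eqn{C_3} the third central moment of \eqn{\Delta V} in
#' the bin. Order 2 is exact for Gaussian boost distributions and is
#' the recommended default.
#'
#' @inheritParams pmf_unweighted
#' @param order cumulant truncation order, 1, 2 or 3
#' @param min_count minimum samples per reported bin (default 10;
#'   third-moment estimates are unstable below that)
#' @return a `pmf_grid` with the order recorded in metadata
#' @export
pmf_cumulant <- function(samples, bins, order = 2, min_count = 10) {
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  b <- .bin_samples(samples$coords, bins)
  ok <- !is.na(b$flat)
  if (!any(ok)) stop("no samples fall inside the grid")
  counts <- tabulate(b$flat[ok], nbins = b$nbin)
  flat <- b$flat[ok]
  dV <- samples$dV[ok]
  beta <- samples$beta
  lnfac <- numeric(b$nbin)
  sp <- split(dV, flat)
  for (nm in names(sp)) {
    v <- sp[[nm]]
    c1 <- mean(v)
    lf <- beta * c1
    if (order >= 2) {
      c2 <- mean((v - c1)^2)
      lf <- lf + beta^2 * c2 / 2
    }
    if (order >= 3) {
      c3 <- mean((v - c1)^3)
      lf <- lf + beta^3 * c3 / 6
    }
    lnfac[as.integer(nm)] <- lf
  }
  n_tot <- sum(counts)
  logp <- log(counts / (n_tot * b$widths)) + lnfac
  pmf <- -logp / beta
  mask <- counts >= max(1, min_count)
  if (!any(mask)) stop("no bin reaches the minimum count")
  new_pmf_grid(edges = b$edges, values = .shape(pmf, b$dims),
               counts = .shape(counts, b$dims), mask = .shape(mask, b$dims),
               metadata = list(estimator = "cumulant", order = order,
                               temperature = samples$temperature))
}

#' Anharmonicity of the boost-energy distribution
#'
#' Entropy deficit of the \eqn{\Delta V} distribution relative to a
#' Gaussian of equal variance,
#' \eqn{\gamma = S_{Gauss}(\sigma) - S_{data} \ge 0}: the Gaussian
#' maximizes differential entropy at fixed variance, so gamma is 0 iff
#' the boost is exactly Gaussian. Small gamma certifies that low-order
#' cumulant reweighting is accurate. The empirical entropy uses a
#' histogram estimate with Scott's bin width.
#'
#' @param dV boost-energy samples, kcal/mol (>= 100 samples)
#' @return gamma, dimensionless, >= 0 (clamped at 0 against estimator
#'   noise); 0 with a warning for zero-variance input
#' @export
anharmonicity <- function(dV) {
  if (length(dV) < 100) stop("need at least 100 samples")
  s <- stats::sd(dV)
  if (s == 0) {
    warning("zero-variance boost distribution; gamma = 0")
    return(0)
  }
  h <- 3.49 * s * length(dV)^(-1 / 3)
  edges <- seq(min(dV) - h / 2, max(dV) + h, by = h)
  p <- tabulate(findInterval(dV, edges), nbins = length(edges) - 1)
  p <- p / sum(p)
  nz <- p > 0
  S_data <- -sum(p[nz] * log(p[nz])) + log(h)
  # population sigma for the matching Gaussian
  sp <- sqrt(mean((dV - mean(dV))^2))
  S_gauss <- 0.5 * log(2 * pi * exp(1) * sp^2)
  max(0, S_gauss - S_data)
}
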