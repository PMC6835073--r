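# PDB reading/writing (via bio3d), atom selection, Kabsch superposition
# and the RMSD conventions used to evaluate peptide poses: direct
# backbone RMSD and CAPRI-style ligand RMSD (fit on the receptor
# backbone, measure the peptide backbone without refitting).

#' Read a PDB file
#'
#' Parses ATOM/HETATM records (fixed-column PDB format, MODEL/ENDMDL
#' honored) through bio3d. Alternate locations are reduced to a single
#' conformer per atom: highest occupancy, first altloc on ties.
#'
#' @param path PDB file
#' @param hetero keep HETATM records (default FALSE)
#' @return object of class `pdb_structure`: `atoms` data frame (serial,
#'   name, resname, chain, resno, insert, element, occupancy, b) and
#'   `xyz`, a list of n_atoms x 3 coordinate matrices, one per model
#' @export
read_pdb <- function(path, hetero = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop(sprintf("malformed PDB '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  at <- pdb$atom
  keep <- if (hetero) rep(TRUE, nrow(at)) else at$type == "ATOM"
  if (!any(keep)) {
    stop(sprintf("no atoms selected from '%s' (only HETATM records?)", path))
  }
  idx <- which(keep)
  at <- at[idx, , drop = FALSE]
  # altloc policy: highest occupancy, first altloc on ties
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  if (anyDuplicated(key)) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(key, -occ, ifelse(is.na(at$alt), "", at$alt))
    first <- !duplicated(key[ord])
    sel <- sort(ord[first])
  } else {
    sel <- seq_len(nrow(at))
  }
  at <- at[sel, , drop = FALSE]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  col_idx <- as.vector(rbind(3 * idx[sel] - 2, 3 * idx[sel] - 1, 3 * idx[sel]))
  models <- lapply(seq_len(nrow(xyz)), function(m) {
    matrix(xyz[m, col_idx], ncol = 3, byrow = TRUE)
  })
  if (any(!vapply(models, function(m) all(is.finite(m)), TRUE))) {
    stop(sprintf("non-finite coordinates in '%s'", path))
  }
  atoms <- data.frame(
    serial = at$eleno, name = at$elety, resname = at$resid,
    chain = ifelse(is.na(at$chain), " ", at$chain), resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    element = ifelse(is.na(at$elesy), "", at$elesy),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE)
  structure(list(atoms = atoms, xyz = models), class = "pdb_structure")
}

#' Number of models in a structure
#' @param structure a `pdb_structure`
#' @return integer
#' @export
n_models <- function(structure) length(structure$xyz)

#' Coordinates of one model
#' @param structure a `pdb_structure`
#' @param model model index (default 1)
#' @return n_atoms x 3 matrix, Angstrom
#' @export
structure_coords <- function(structure, model = 1) structure$xyz[[model]]

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("<pdb_structure> %d atoms, %d model(s), chains: %s\n",
              nrow(x$atoms), n_models(x),
              paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

#' Write a structure (or coordinate stack) as PDB
#'
#' Fixed-column PDB output at the standard 3-decimal coordinate
#' precision; multiple models are wrapped in MODEL/ENDMDL records.
#'
#' @param structure a `pdb_structure`
#' @param path output file
#' @param models which models to write (default all)
#' @return the path, invisibly
#' @export
write_pdb <- function(structure, path, models = seq_len(n_models(structure))) {
  at <- structure$atoms
  lines <- character(0)
  multi <- length(models) > 1
  for (m in models) {
    xyz <- structure$xyz[[m]]
    recs <- sprintf(
      "ATOM  %5d %s%-3s %-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$serial %% 100000,
      ifelse(nchar(at$name) >= 4, "", " "),
      at$name, at$resname, substr(paste0(at$chain, " "), 1, 1),
      at$resno, substr(paste0(at$insert, " "), 1, 1),
      xyz[, 1], xyz[, 2], xyz[, 3], at$occupancy, at$b, at$element)
    if (multi) {
      lines <- c(lines, sprintf("MODEL %8d", m), recs, "ENDMDL")
    } else {
      lines <- c(lines, recs)
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Select atoms by chain, residue range and atom names
#'
#' Deterministic, document-ordered selection.
#'
#' @param structure a `pdb_structure`
#' @param chain chain id(s), or NULL for all
#' @param resno residue numbers (e.g. `67:74`), or NULL for all
#' @param names atom-name set, or NULL for all
#' @return integer atom indices (class `atom_selection`)
#' @export
select_atoms <- function(structure, chain = NULL, resno = NULL,
                         names = NULL) {
  at <- structure$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(names)) keep <- keep & at$name %in% names
  structure(which(keep), class = "atom_selection",
            spec = list(chain = chain, resno = resno, names = names))
}

#' Select backbone atoms
#'
#' Backbone convention: N, CA, C (carbonyl O excluded), the common
#' CPPTRAJ/CAPRI choice; pass `atoms = c("N","CA","C","O")` to include
#' the carbonyl oxygen. Residues in scope that are missing any backbone
#' atom are an error, not silently skipped.
#'
#' @param structure a `pdb_structure`
#' @param chain chain id(s) or NULL
#' @param resno residue-number scope or NULL
#' @param atoms backbone atom-name set
#' @return integer `atom_selection`, ordered as in the file
#' @export
select_backbone <- function(structure, chain = NULL, resno = NULL,
                            atoms = c("N", "CA", "C")) {
  sel_scope <- select_atoms(structure, chain = chain, resno = resno)
  if (!length(sel_scope)) stop("selection scope is empty")
  at <- structure$atoms[sel_scope, , drop = FALSE]
  res_key <- unique(paste(at$chain, at$resno, at$insert, sep = "|"))
  have <- split(at$name, paste(at$chain, at$resno, at$insert, sep = "|"))
  missing <- vapply(res_key, function(k) {
    !all(atoms %in% have[[k]])
  }, TRUE)
  if (any(missing)) {
    stop(sprintf("residues missing backbone atoms: %s",
                 paste(res_key[missing], collapse = ", ")))
  }
  sel <- sel_scope[at$name %in% atoms]
  structure(sel, class = "atom_selection",
            spec = list(chain = chain, resno = resno, names = atoms))
}

#' Kabsch least-squares superposition
#'
#' Optimal rigid-body superposition of paired point sets by the Kabsch
#' algorithm (SVD of the weighted covariance with the standard sign
#' correction, so the rotation is always proper, det = +1).
#'
#' @param mobile,reference n x 3 coordinate matrices with paired rows
#'   (n >= 3, non-degenerate spread)
#' @param weights optional non-negative per-atom weights
#' @return list with `rotation` (3 x 3, applied as `x %*% rotation`),
#'   `translation` (length 3), `rmsd` (Angstrom) and `apply`, a
#'   function transforming arbitrary coordinates into the reference
#'   frame
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    stop("mobile and reference must be equal-size n x 3 matrices")
  }
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 atoms for superposition")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) == 0) stop("invalid weights")
  w <- w / sum(w)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- t(A * w) %*% B
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)) {
    stop("degenerate (collinear) atom set: superposition undefined")
  }
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  rmsd <- sqrt(sum(w * rowSums((A %*% R - B)^2)))
  tvec <- cr - as.numeric(cm %*% R)
  list(rotation = R, translation = tvec, rmsd = rmsd,
       apply = function(x) sweep(as.matrix(x) %*% R, 2, tvec, `+`))
}

#' Plain (fitted) RMSD between paired coordinate sets
#' @param a,b n x 3 matrices
#' @param fit superpose first (default TRUE); FALSE computes the direct
#'   coordinate RMSD
#' @return RMSD in Angstrom
#' @export
rmsd_fit <- function(a, b, fit = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (fit) {
    kabsch_superpose(a, b)$rmsd
  } else {
    sqrt(mean(rowSums((a - b)^2)))
  }
}

# correspondence check by residue number + atom name
.check_correspondence <- function(at_a, at_b, what = "selection") {
  key_a <- paste(at_a$chain, at_a$resno, at_a$name)
  key_b <- paste(at_b$chain, at_b$resno, at_b$name)
  if (length(key_a) != length(key_b) || any(key_a != key_b)) {
    only_a <- setdiff(key_a, key_b); only_b <- setdiff(key_b, key_a)
    stop(sprintf(
      "atom correspondence mismatch in %s:\n  only in first: %s\n  only in second: %s",
      what,
      paste(utils::head(only_a, 5), collapse = "; "),
      paste(utils::head(only_b, 5), collapse = "; ")))
  }
}

#' CAPRI-style ligand RMSD
#'
#' Superposes the frame onto the reference using the fit selection
#' (receptor backbone), then measures the RMSD over the measure
#' selection (peptide backbone) without refitting. Atom correspondence
#' is by residue number and atom name and must match exactly.
#'
#' @param frame,reference `pdb_structure` objects (model 1 used), or
#'   n x 3 coordinate matrices with identical atom ordering
#' @param fit_sel `atom_selection` (or indices) for the superposition,
#'   typically the receptor backbone
#' @param measure_sel `atom_selection` (or indices) to measure,
#'   typically the peptide backbone
#' @param frame_model,reference_model model indices when structures are
#'   multi-model
#' @return RMSD in Angstrom
#' @export
ligand_rmsd <- function(frame, reference, fit_sel, measure_sel,
                        frame_model = 1, reference_model = 1) {
  get_xyz <- function(s, model) {
    if (inherits(s, "pdb_structure")) structure_coords(s, model)
    else as.matrix(s)
  }
  xf <- get_xyz(frame, frame_model)
  xr <- get_xyz(reference, reference_model)
  if (inherits(frame, "pdb_structure") && inherits(reference, "pdb_structure")) {
    .check_correspondence(frame$atoms[fit_sel, ], reference$atoms[fit_sel, ],
                          "fit selection")
    .check_correspondence(frame$atoms[measure_sel, ],
                          reference$atoms[measure_sel, ], "measure selection")
  }
  fit <- kabsch_superpose(xf[fit_sel, , drop = FALSE],
                          xr[fit_sel, , drop = FALSE])
  moved <- fit$apply(xf[measure_sel, , drop = FALSE])
  sqrt(mean(rowSums((moved - xr[measure_sel, , drop = FALSE])^2)))
}
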