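#' Read an atomic model from a PDB file
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}), infers the element of each
#' atom from the element column when present and from the first letter of
#' the atom name otherwise, and drops atoms whose element has no tabulated
#' scattering-factor parameters (with a warning listing them).  Waters are
#' excluded by default.  Occupancies and B-factors are ignored.
#'
#' @param path Path to a PDB file.
#' @param exclude_water Drop HOH/WAT/DOD residues (default TRUE).
#' @param label Model label; defaults to the file name.
#' @return An `atomic_model`.
#' @export
read_pdb <- function(path, exclude_water = TRUE, label = basename(path)) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (exclude_water)
    at <- at[!toupper(at$resid) %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  if (nrow(at) == 0L) stop("no usable atoms in PDB file: ", path)
  el <- .norm_element(at$elesy)
  miss <- is.na(el) | el == ""
  # atom-name fallback: first alphabetic character of the (blank-stripped) name
  guess <- toupper(substr(gsub("[^A-Za-z].*$", "",
                               gsub("^[0-9 ]+", "", at$elety)), 1L, 1L))
  el[miss] <- guess[miss]
  ok <- el %in% known_elements()
  if (any(!ok)) {
    warning("dropping ", sum(!ok), " atom(s) with unrecognized element(s): ",
            paste(unique(el[!ok]), collapse = ", "))
    at <- at[ok, , drop = FALSE]
    el <- el[ok]
  }
  if (nrow(at) == 0L) stop("no atoms with recognized elements in: ", path)
  atomic_model(el, cbind(at$x, at$y, at$z), label = label)
}

#' Write an atomic model (or complex) to a PDB file
#'
#' A `complex_model` is written with the fixed subunit as chain A and the
#' mobile subunit as chain B, preserving the fixed-then-mobile atom order
#' used by the RMSD convention.  Coordinates are written at standard PDB
#' precision (3 decimals, i.e. 1e-3 Angstrom).
#'
#' @param model An `atomic_model` or `complex_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(model, path) {
  if (inherits(model, "complex_model")) {
    chain <- rep(c("A", "B"), c(n_atoms(model$fixed), n_atoms(model$mobile)))
    model <- merge_subunits(model)
  } else {
    stopifnot(inherits(model, "atomic_model"))
    chain <- rep("A", n_atoms(model))
  }
  n <- n_atoms(model)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(model$coords)),
                   type = rep("ATOM", n),
                   resno = seq_len(n), resid = rep("GLY", n),
                   chain = chain,
                   elety = model$elements, elesy = model$elements)
  invisible(path)
}

#' Read a two-chain PDB file as a complex model
#'
#' The first chain (by order of appearance) becomes the fixed subunit and
#' the remaining atoms the mobile subunit.
#'
#' @param path Path to a PDB file with at least two chains.
#' @inheritParams read_pdb
#' @return A `complex_model`.
#' @export
read_complex_pdb <- function(path, exclude_water = TRUE,
                             label = basename(path)) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (exclude_water)
    at <- at[!toupper(at$resid) %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  chains <- unique(at$chain)
  if (length(chains) < 2L)
    stop("complex PDB must contain at least two chains: ", path)
  tmp_model <- function(rows, lab) {
    f <- tempfile(fileext = ".pdb")
    on.exit(unlink(f), add = TRUE)
    bio3d::write.pdb(file = f, xyz = as.numeric(t(cbind(rows$x, rows$y, rows$z))),
                     type = rows$type, resno = rows$resno, resid = rows$resid,
                     chain = rows$chain, elety = rows$elety, elesy = rows$elesy)
    read_pdb(f, exclude_water = exclude_water, label = lab)
  }
  fixed <- tmp_model(at[at$chain == chains[1L], , drop = FALSE], "fixed")
  mobile <- tmp_model(at[at$chain != chains[1L], , drop = FALSE], "mobile")
  complex_model(fixed, mobile, label = label)
}
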