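#' Full-atom no-fit RMSD between a decoy and the native complex
#'
#' Root-mean-square deviation over all atoms (fixed and mobile subunits) in
#' the frame defined by the fixed subunit, i.e. without re-superposition:
#' in the docking convention the fixed subunit anchors the laboratory frame,
#' so superposing would hide genuine displacement of the mobile partner.
#' Atom counts and ordering must be identical.
#'
#' @param decoy,native `complex_model` (or `atomic_model`) objects with
#'   identical atom ordering.
#' @return RMSD in Angstrom.
#' @export
rmsd_to_native <- function(decoy, native) {
  a <- if (inherits(decoy, "complex_model")) merge_subunits(decoy) else decoy
  b <- if (inherits(native, "complex_model")) merge_subunits(native) else native
  if (n_atoms(a) != n_atoms(b))
    stop("atom counts differ (", n_atoms(a), " vs ", n_atoms(b), ")")
  d <- a$coords - b$coords
  sqrt(mean(rowSums(d^2)))
}

#' Generate rigid-body docking decoys from a native complex
#'
#' Each decoy keeps the fixed subunit untouched and perturbs the mobile
#' subunit by a rotation about its own center of mass (uniform random axis,
#' angle uniform in `[0, rot_max]`) followed by a translation along a uniform
#' random direction with magnitude uniform in `[0, trans_max]`.  This is a
#' seedable sampler giving a controllable spread of structure differences;
#' it is deliberately *not* a physical docking sampler (no energy, no clash
#' checking).  Per-decoy RMSD to the native is recorded.
#'
#' @param native A `complex_model`.
#' @param n Number of decoys.
#' @param rot_max Maximum rotation angle, degrees.
#' @param trans_max Maximum translation magnitude, Angstrom.
#' @param seed Integer RNG seed.
#' @return A `decoy_set`: list with `native`, `decoys` (list of
#'   `complex_model`), `rmsd`, and a `manifest` data frame.
#' @export
generate_decoys <- function(native, n, rot_max = 30, trans_max = 10,
                            seed = 1L) {
  stopifnot(inherits(native, "complex_model"), n >= 1L,
            rot_max >= 0, trans_max >= 0)
  with_seed(seed, {
    axes <- runif_sphere(n)
    angs <- stats::runif(n, 0, rot_max) * pi / 180
    dirs <- runif_sphere(n)
    mags <- stats::runif(n, 0, trans_max)
    decoys <- vector("list", n)
    rmsd <- numeric(n)
    for (i in seq_len(n)) {
      R <- axis_angle_matrix(axes[i, ], angs[i])
      tf <- rigid_transform(R, dirs[i, ] * mags[i])
      mob <- apply_transform(native$mobile, tf,
                             pivot = center_of_mass(native$mobile))
      decoys[[i]] <- complex_model(native$fixed, mob,
                                   label = sprintf("decoy_%04d", i))
      rmsd[i] <- rmsd_to_native(decoys[[i]], native)
    }
    manifest <- data.frame(decoy_id = sprintf("decoy_%04d", seq_len(n)),
                           rmsd_A = rmsd, seed = seed,
                           rot_deg = angs * 180 / pi, trans_A = mags)
    structure(list(native = native, decoys = decoys, rmsd = rmsd,
                   manifest = manifest),
              class = "decoy_set")
  })
}

#' Graded decoy ladder with prescribed RMSD values
#'
#' Builds decoys whose full-complex RMSD to the native equals each requested
#' value exactly.  Because a rotation of the mobile subunit about its own
#' center of mass preserves that center, rotational and translational
#' displacements are orthogonal in the mean-square sense and
#' `RMSD^2 = w * (rot_ms + |t|^2)` with `w` the mobile atom fraction — so
#' exact targets can be hit in closed form.
#'
#' Two ladder styles:
#' \describe{
#'   \item{`"translation"`}{pure translations along random directions with
#'     magnitude `target / sqrt(w)`; maximal simplicity, but an increasing
#'     subunit separation that the rotationally averaged (SAXS) profile
#'     tracks directly.}
#'   \item{`"rigid"`}{pose-style decoys emulating docking output: the mobile
#'     subunit is first rotated about its center of mass (random axis, the
#'     angle solved so the rotation alone meets the target when it can) and
#'     translated along a random direction only for the remainder the
#'     rotation cannot reach.  Small and mid-ladder decoys are then pure
#'     pose changes at constant separation.}
#' }
#'
#' @param native A `complex_model`.
#' @param rmsd_targets Numeric vector of non-negative target RMSDs, Angstrom.
#' @param seed Integer RNG seed.
#' @param mode `"translation"` (default) or `"rigid"`.
#' @return A `decoy_set`.
#' @export
make_decoy_ladder <- function(native, rmsd_targets, seed = 1L,
                              mode = c("translation", "rigid")) {
  stopifnot(inherits(native, "complex_model"), all(rmsd_targets >= 0))
  mode <- match.arg(mode)
  n <- length(rmsd_targets)
  w <- n_atoms(native$mobile) / n_atoms(native)
  # pivot at the unweighted centroid: RMSD weights atoms equally, and only
  # about this point are rotational and translational displacements exactly
  # orthogonal in the mean square
  com <- colMeans(native$mobile$coords)
  xc <- sweep(native$mobile$coords, 2L, com)
  with_seed(seed, {
    dirs <- runif_sphere(n)
    axes <- runif_sphere(n)
    decoys <- vector("list", n)
    rmsd <- numeric(n)
    rot_deg <- numeric(n)
    trans_A <- numeric(n)
    for (i in seq_len(n)) {
      d <- rmsd_targets[i] / sqrt(w)   # required mobile-subunit RMS
      if (mode == "translation") {
        R <- diag(3); t_mag <- d
      } else {
        # mean squared displacement of a rotation by theta about this axis
        # is 2 (1 - cos theta) * c_ax, with c_ax the mean squared distance
        # from the axis; saturates at 4 c_ax for theta = 180 deg
        a <- axes[i, ]
        c_ax <- mean(rowSums(xc^2) - as.numeric(xc %*% a)^2)
        if (d^2 <= 4 * c_ax) {
          theta <- acos(1 - d^2 / (2 * c_ax))
          t_mag <- 0
        } else {
          theta <- pi
          t_mag <- sqrt(d^2 - 4 * c_ax)
        }
        R <- axis_angle_matrix(a, theta)
        rot_deg[i] <- theta * 180 / pi
      }
      trans_A[i] <- t_mag
      tf <- rigid_transform(R, dirs[i, ] * t_mag)
      mob <- apply_transform(native$mobile, tf, pivot = com)
      decoys[[i]] <- complex_model(native$fixed, mob,
                                   label = sprintf("decoy_%04d", i))
      rmsd[i] <- rmsd_to_native(decoys[[i]], native)
    }
    manifest <- data.frame(decoy_id = sprintf("decoy_%04d", seq_len(n)),
                           rmsd_A = rmsd, seed = seed,
                           rot_deg = rot_deg, trans_A = trans_A)
    structure(list(native = native, decoys = decoys, rmsd = rmsd,
                   manifest = manifest),
              class = "decoy_set")
  })
}

#' @export
print.decoy_set <- function(x, ...) {
  cat(sprintf("decoy_set: %d decoys, RMSD %.2f - %.2f A\n",
              length(x$decoys), min(x$rmsd), max(x$rmsd)))
  invisible(x)
}

#' Persist a decoy set as numbered PDB files plus a TSV manifest
#'
#' @param ds A `decoy_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_decoy_set <- function(ds, dir) {
  stopifnot(inherits(ds, "decoy_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pdb(ds$native, file.path(dir, "native.pdb"))
  for (i in seq_along(ds$decoys))
    write_pdb(ds$decoys[[i]], file.path(dir, paste0(ds$manifest$decoy_id[i],
                                                    ".pdb")))
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(ds$manifest, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mp)
}

#' Load a decoy set written by [write_decoy_set()]
#'
#' @param dir Directory containing `native.pdb`, decoy PDBs and
#'   `manifest.tsv`.
#' @return A `decoy_set` (RMSDs recomputed from the coordinates).
#' @export
read_decoy_set <- function(dir) {
  mp <- file.path(dir, "manifest.tsv")
  if (!file.exists(mp)) stop("no manifest.tsv under ", dir)
  manifest <- utils::read.table(mp, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  native <- read_complex_pdb(file.path(dir, "native.pdb"))
  decoys <- lapply(manifest$decoy_id, function(id)
    read_complex_pdb(file.path(dir, paste0(id, ".pdb")), label = id))
  rmsd <- vapply(decoys, rmsd_to_native, numeric(1), native = native)
  manifest$rmsd_A <- rmsd
  structure(list(native = native, decoys = decoys, rmsd = rmsd,
                 manifest = manifest),
            class = "decoy_set")
}
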